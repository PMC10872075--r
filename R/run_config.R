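# YAML run configuration: schema validation, per-stage seed derivation, and
# config fingerprinting for artifact stamping.

RUN_CONFIG_SCHEMA <- list(
  paths = c("omics", "drug_catalog", "responses", "predictions", "model"),
  model = c("omic_types", "drug_encoder", "fusion", "use_lds", "d_omic_latent",
            "d_drug_latent", "lmf_rank", "d_fused", "head_hidden", "ecfp_bits",
            "ecfp_radius", "lr", "weight_decay", "epochs", "patience", "ae_epochs",
            "ae_activation", "freeze_encoders", "preset"),
  lds = c("n_bins", "kernel", "kernel_size", "kernel_sigma", "density_floor",
          "normalize_mean_to_one"),
  synthetic = c("n_cell_lines", "n_lineages", "features_per_omic", "n_drugs",
                "beta", "noise_sd", "causal_omic", "causal_feature", "smarts",
                "block_size", "block_rho", "missing_cell_frac"),
  attribution = c("steps", "rule", "baseline", "cell_line", "drug", "target"),
  evaluate = c("window", "margin", "mae_threshold"),
  top = c("scheme", "k_folds", "seed", "output_dir", "paths", "model", "lds",
          "synthetic", "attribution", "evaluate", "complete_profiles_only")
)

check_keys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown)) {
    stop("unknown config key(s) in ", where, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys are rejected by name before any computation.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, RUN_CONFIG_SCHEMA$top, "top level")
  for (block in c("paths", "model", "lds", "synthetic", "attribution",
                  "evaluate")) {
    if (!is.null(cfg[[block]])) {
      check_keys(cfg[[block]], RUN_CONFIG_SCHEMA[[block]], block)
    }
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$scheme)) cfg$scheme <- "cell_line"
  if (is.null(cfg$k_folds)) cfg$k_folds <- 5L
  if (is.null(cfg$output_dir)) cfg$output_dir <- "drpfuse_out"
  structure(cfg, class = "run_config")
}

#' Derive a stage-specific seed from the global seed
#'
#' Deterministic and stable across sessions, so each pipeline stage is
#' independently reproducible from the single global seed.
#'
#' @param seed global integer seed.
#' @param stage stage name string.
#' @return Integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Fingerprint a configuration for artifact stamping
#'
#' @param cfg any serializable configuration list.
#' @return MD5 hex string of the YAML serialization.
#' @export
config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(cfg, f)
  unname(tools::md5sum(f))
}

stamp_run <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamped <- c(unclass(cfg), list(config_hash = config_hash(unclass(cfg))))
  yaml::write_yaml(stamped, file.path(dir, "resolved_config.yaml"))
  invisible(stamped)
}
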