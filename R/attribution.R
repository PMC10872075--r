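# Integrated gradients: path-integral attribution of a prediction to omic
# feature inputs and drug-graph atom features, with the completeness
# residual reported (attributions should sum to the prediction difference
# from the baseline).

#' Attribution configuration
#'
#' @param steps number of path integration steps m (default 64).
#' @param rule integration rule: `"trapezoid"` (default) or
#'   `"riemann_right"`.
#' @param baseline `"zeros"` (for standardized omics this is the
#'   training-mean profile) or `"custom"`.
#' @param baseline_values named list of custom baseline matrices (only with
#'   `baseline = "custom"`).
#' @return An `attribution_config` list.
#' @export
attribution_config <- function(steps = 64L,
                               rule = c("trapezoid", "riemann_right"),
                               baseline = c("zeros", "custom"),
                               baseline_values = NULL) {
  rule <- match.arg(rule)
  baseline <- match.arg(baseline)
  stopifnot(steps >= 1L)
  structure(list(steps = as.integer(steps), rule = rule, baseline = baseline,
                 baseline_values = baseline_values),
            class = "attribution_config")
}

ig_path <- function(config) {
  m <- config$steps
  if (config$rule == "trapezoid") {
    list(alpha = seq(0, 1, length.out = m + 1L),
         weight = c(0.5, rep(1, m - 1L), 0.5) / m)
  } else {
    list(alpha = seq_len(m) / m, weight = rep(1 / m, m))
  }
}

#' Integrated gradients for an arbitrary scalar function
#'
#' Core path-integral routine: attributes `f`'s output at `x` relative to
#' `baseline` along the straight path.  `f(tape, node)` must build the
#' forward pass from the gradient-tracked input node and return a scalar
#' tape node.
#'
#' @param f forward function `(tape, input_node) -> scalar ad node`.
#' @param x numeric input matrix.
#' @param baseline baseline matrix (default all zeros).
#' @param config an [attribution_config()].
#' @return A list with `attributions` (same shape as `x`), `completeness`
#'   (residual `|sum(attr) - (f(x) - f(baseline))|`), `fx`, `f0`.
#' @export
ig_attribute <- function(f, x, baseline = 0 * x,
                         config = attribution_config()) {
  x <- as.matrix(x); baseline <- as.matrix(baseline)
  stopifnot(identical(dim(x), dim(baseline)))
  path <- ig_path(config)
  grad_acc <- 0 * x
  for (j in seq_along(path$alpha)) {
    tape <- ad_tape()
    xn <- ad_input(tape, baseline + path$alpha[j] * (x - baseline))
    out <- f(tape, xn)
    if (length(ad_value(out)) != 1L) stop("f must return a scalar", call. = FALSE)
    g <- ad_backward(out)(xn)
    grad_acc <- grad_acc + path$weight[j] * g
  }
  attributions <- (x - baseline) * grad_acc
  eval_at <- function(v) {
    tape <- ad_tape()
    ad_value(f(tape, ad_input(tape, v)))[1L]
  }
  fx <- eval_at(x); f0 <- eval_at(baseline)
  list(attributions = attributions,
       completeness = abs(sum(attributions) - (fx - f0)),
       fx = fx, f0 = f0)
}

single_record_data <- function(model, cell_line, drug) {
  data <- model$data
  cl_row <- match(cell_line, data$panel)
  drug_row <- match(drug, data$drugs)
  if (is.na(cl_row)) stop("unknown cell line: ", cell_line, call. = FALSE)
  if (is.na(drug_row)) stop("unknown drug: ", drug, call. = FALSE)
  sdata <- data
  sdata$X <- lapply(data$X, function(m) m[cl_row, , drop = FALSE])
  sdata$drugs <- data$drugs[drug_row]
  if (model$config$drug_encoder == "gnn") {
    sdata$graphs <- data$graphs[drug_row]
    sdata$batch <- batch_graphs(sdata$graphs)
  } else {
    sdata$fp <- data$fp[drug_row, , drop = FALSE]
  }
  sdata
}

#' Integrated gradients for one model prediction
#'
#' Attributes the model's predicted AAC for a single (cell line, drug) pair
#' to its omic feature inputs and, for the graph drug encoder, the drug's
#' atom features (bond features are excluded; their gradient path is
#' ambiguous).  Unselected modalities are held at their actual input, so
#' the completeness residual compares against the prediction change from
#' moving only the selected modalities to baseline.  For standardized
#' omics the zeros baseline equals the training-mean profile.
#'
#' @param model a trained `drp_model`.
#' @param cell_line,drug identifiers of the prediction to explain.
#' @param target modalities to attribute: subset of the model's omic types
#'   plus `"drug"`; default all.
#' @param config an [attribution_config()].
#' @return An object of class `attribution_map`: `scores` (modality,
#'   feature, score), `atom_scores` (per-atom sums, graph encoder only),
#'   `completeness`, `prediction`, `baseline_prediction`.
#' @export
integrated_gradients <- function(model, cell_line, drug,
                                 target = NULL,
                                 config = attribution_config()) {
  stopifnot(inherits(model, "drp_model"))
  mc <- model$config
  modalities <- c(mc$omic_types, "drug")
  if (is.null(target)) target <- modalities
  stopifnot(all(target %in% modalities))
  sdata <- single_record_data(model, cell_line, drug)
  rows <- list(cl_row = 1L, drug_row = 1L)

  inputs <- list()
  for (ot in intersect(target, mc$omic_types)) inputs[[ot]] <- sdata$X[[ot]]
  if ("drug" %in% target) {
    inputs$drug <- if (mc$drug_encoder == "gnn") sdata$batch$atom_features
                   else sdata$fp
  }
  baselines <- lapply(inputs, function(x) {
    0 * x
  })
  if (config$baseline == "custom") {
    for (nm in names(config$baseline_values)) {
      baselines[[nm]] <- as.matrix(config$baseline_values[[nm]])
    }
  }

  forward_value <- function(point, track = FALSE) {
    tape <- ad_tape()
    P <- lapply(model$params, function(p) ad_const(tape, p))
    nodes <- list()
    overrides <- list()
    atom_override <- NULL
    fp_override <- NULL
    for (nm in names(inputs)) {
      node <- if (track) ad_input(tape, point[[nm]])
              else ad_const(tape, point[[nm]])
      nodes[[nm]] <- node
      if (nm == "drug") {
        if (mc$drug_encoder == "gnn") atom_override <- node
        else fp_override <- node
      } else {
        overrides[[nm]] <- node
      }
    }
    fw <- drp_forward(tape, P, sdata, rows, mc, model$meta,
                      omic_overrides = overrides,
                      atom_override = atom_override,
                      fp_override = fp_override,
                      batch = if (mc$drug_encoder == "gnn") sdata$batch)
    list(pred = fw$pred, nodes = nodes, tape = tape)
  }

  path <- ig_path(config)
  grad_acc <- lapply(inputs, function(x) 0 * x)
  for (j in seq_along(path$alpha)) {
    point <- lapply(names(inputs), function(nm) {
      baselines[[nm]] + path$alpha[j] * (inputs[[nm]] - baselines[[nm]])
    })
    names(point) <- names(inputs)
    fv <- forward_value(point, track = TRUE)
    gf <- ad_backward(fv$pred)
    for (nm in names(inputs)) {
      g <- gf(fv$nodes[[nm]])
      if (!is.null(g)) grad_acc[[nm]] <- grad_acc[[nm]] + path$weight[j] * g
    }
  }
  attr_mats <- lapply(names(inputs), function(nm) {
    (inputs[[nm]] - baselines[[nm]]) * grad_acc[[nm]]
  })
  names(attr_mats) <- names(inputs)

  fx <- ad_value(forward_value(inputs)$pred)[1L]
  f0 <- ad_value(forward_value(baselines)$pred)[1L]
  completeness <- abs(sum(vapply(attr_mats, sum, numeric(1))) - (fx - f0))

  scores <- NULL
  for (ot in intersect(names(attr_mats), mc$omic_types)) {
    scores <- rbind(scores, data.frame(
      modality = ot,
      feature = colnames(model$data$X[[ot]]),
      score = as.vector(attr_mats[[ot]]),
      stringsAsFactors = FALSE))
  }
  atom_scores <- NULL
  if ("drug" %in% names(attr_mats)) {
    if (mc$drug_encoder == "gnn") {
      am <- attr_mats$drug
      fn <- colnames(am)
      scores <- rbind(scores, data.frame(
        modality = "drug",
        feature = paste0("atom", rep(seq_len(nrow(am)), times = ncol(am)),
                         ":", rep(fn, each = nrow(am))),
        score = as.vector(am),
        stringsAsFactors = FALSE))
      atom_scores <- data.frame(atom = seq_len(nrow(am)),
                                element = sdata$graphs[[1L]]$elements,
                                score = rowSums(am),
                                stringsAsFactors = FALSE)
    } else {
      scores <- rbind(scores, data.frame(
        modality = "drug",
        feature = paste0("fp_bit", seq_len(ncol(attr_mats$drug))),
        score = as.vector(attr_mats$drug),
        stringsAsFactors = FALSE))
    }
  }
  structure(list(cell_line = cell_line, drug = drug, scores = scores,
                 atom_scores = atom_scores, completeness = completeness,
                 prediction = fx, baseline_prediction = f0,
                 config = config),
            class = "attribution_map")
}

#' @export
print.attribution_map <- function(x, ...) {
  cat(sprintf("<attribution_map %s x %s: %d features, completeness residual %.3g>\n",
              x$cell_line, x$drug, nrow(x$scores), x$completeness))
  invisible(x)
}

#' Top-k features by absolute attribution
#'
#' @param attr an `attribution_map` (or its `scores` data frame).
#' @param k number of features to return; the full ranked list if `k`
#'   exceeds the feature count.
#' @param modality optional modality filter.
#' @return Ranked data frame (ties broken by feature name for
#'   reproducibility).
#' @export
top_features <- function(attr, k, modality = NULL) {
  stopifnot(k >= 1L)
  scores <- if (inherits(attr, "attribution_map")) attr$scores else attr
  if (!is.null(modality)) {
    scores <- scores[scores$modality %in% modality, , drop = FALSE]
  }
  ord <- order(-abs(scores$score), scores$feature)
  scores[ord[seq_len(min(k, nrow(scores)))], , drop = FALSE]
}

#' Write attribution scores as TSV
#' @param attr an `attribution_map`.
#' @param path feature score output path.
#' @param atom_path optional per-atom score output path.
#' @return `path`, invisibly.
#' @export
write_attributions <- function(attr, path, atom_path = NULL) {
  utils::write.table(attr$scores, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(atom_path) && !is.null(attr$atom_scores)) {
    utils::write.table(attr$atom_scores, atom_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
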