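# Synthetic cohort generator: multi-omic matrices, a drug catalog drawn from
# a built-in fixture of real drug structures, and a right-skewed AAC response
# table with a planted, recoverable omic-feature x drug-substructure
# interaction signal.  Every downstream stage of the package is testable on
# this cohort without external data.

# Built-in drug fixture: 51 marketed/clinical compounds covering a wide
# scaffold range, with targeted-therapy flags.  Hard-coded (no random
# molecule generation) so scaffold splitting is deterministic and every
# structure is chemically valid.
DRUG_FIXTURE <- local({
  raw <- c(
    "fluorouracil|O=C1NC(=O)NC=C1F|0",
    "gemcitabine|NC1=NC(=O)N(C=C1)C1OC(CO)C(O)C1(F)F|0",
    "cytarabine|NC1=NC(=O)N(C=C1)C1OC(CO)C(O)C1O|0",
    "hydroxyurea|NC(=O)NO|0",
    "busulfan|CS(=O)(=O)OCCCCOS(=O)(=O)C|0",
    "chlorambucil|OC(=O)CCCc1ccc(N(CCCl)CCCl)cc1|0",
    "melphalan|NC(Cc1ccc(cc1)N(CCCl)CCCl)C(=O)O|0",
    "mercaptopurine|S=C1N=CNC2=C1NC=N2|0",
    "vorinostat|ONC(=O)CCCCCCC(=O)Nc1ccccc1|1",
    "imatinib|Cc1ccc(NC(=O)c2ccc(CN3CCN(C)CC3)cc2)cc1Nc1nccc(-c2cccnc2)n1|1",
    "gefitinib|COc1cc2ncnc(Nc3ccc(F)c(Cl)c3)c2cc1OCCCN1CCOCC1|1",
    "erlotinib|COCCOc1cc2ncnc(Nc3cccc(C#C)c3)c2cc1OCCOC|1",
    "sunitinib|CCN(CC)CCNC(=O)C1=C(C)NC(C=C2C(=O)Nc3ccc(F)cc23)=C1C|1",
    "sorafenib|CNC(=O)c1cc(Oc2ccc(NC(=O)Nc3ccc(Cl)c(C(F)(F)F)c3)cc2)ccn1|1",
    "dasatinib|Cc1nc(Nc2ncc(s2)C(=O)Nc2c(C)cccc2Cl)cc(n1)N1CCN(CCO)CC1|1",
    "ibrutinib|C=CC(=O)N1CCCC(C1)n1nc(-c2ccc(Oc3ccccc3)cc2)c2c(N)ncnc12|1",
    "afatinib|CN(C)CC=CC(=O)Nc1cc2c(Nc3ccc(F)c(Cl)c3)ncnc2cc1OC1CCOC1|1",
    "osimertinib|C=CC(=O)Nc1cc(Nc2nccc(-c3cn(C)c4ccccc34)n2)c(OC)cc1N(C)CCN(C)C|1",
    "palbociclib|CC(=O)C1=C(C)C2=CN=C(NC3=CC=C(N4CCNCC4)C=N3)N=C2N(C3CCCC3)C1=O|1",
    "crizotinib|CC(OC1=CC(=CN=C1N)C1=CN(N=C1)C1CCNCC1)C1=C(Cl)C=CC(F)=C1Cl|1",
    "vemurafenib|CCCS(=O)(=O)Nc1ccc(F)c(C(=O)c2c[nH]c3ncc(-c4ccc(Cl)cc4)cc23)c1F|1",
    "lapatinib|CS(=O)(=O)CCNCc1ccc(-c2ccc3ncnc(Nc4ccc(OCc5cccc(F)c5)c(Cl)c4)c3c2)o1|1",
    "nilotinib|Cc1cn(-c2cc(NC(=O)c3ccc(C)c(Nc4nccc(-c5cccnc5)n4)c3)cc(C(F)(F)F)c2)cn1|1",
    "ruxolitinib|N#CCC(C1CCCC1)n1cc(-c2ncnc3[nH]ccc23)cn1|1",
    "tofacitinib|CC1CCN(C(=O)CC#N)CC1N(C)c1ncnc2[nH]ccc12|1",
    "bortezomib|CC(C)CC(NC(=O)C(Cc1ccccc1)NC(=O)c1cnccn1)B(O)O|1",
    "azacitidine|NC1=NC(=O)N(C=N1)C1OC(CO)C(O)C1O|0",
    "carmustine|ClCCNC(=O)N(CCCl)N=O|0",
    "lomustine|O=NN(CCCl)C(=O)NC1CCCCC1|0",
    "procarbazine|CNNCc1ccc(C(=O)NC(C)C)cc1|0",
    "dacarbazine|CN(C)N=Nc1[nH]cnc1C(N)=O|0",
    "thioguanine|Nc1nc(S)c2nc[nH]c2n1|0",
    "methotrexate|CN(Cc1cnc2nc(N)nc(N)c2n1)c1ccc(cc1)C(=O)NC(CCC(O)=O)C(O)=O|0",
    "axitinib|CNC(=O)c1ccccc1Sc1ccc2c(C=Cc3ccccn3)n[nH]c2c1|1",
    "bosutinib|COc1cc(Nc2c(C#N)cnc3cc(OCCCN4CCN(C)CC4)c(OC)cc23)c(Cl)cc1Cl|1",
    "dabrafenib|CC(C)(C)c1nc(-c2cccc(NS(=O)(=O)c3c(F)cccc3F)c2F)c(-c2ccnc(N)n2)s1|1",
    "olaparib|O=C1NN=C(CC2=CC=C(F)C(C(=O)N3CCN(C(=O)C4CC4)CC3)=C2)C2=CC=CC=C12|1",
    "tamoxifen|CCC(=C(c1ccccc1)c1ccc(OCCN(C)C)cc1)c1ccccc1|1",
    "raloxifene|Oc1ccc2c(c1)sc(-c1ccc(O)cc1)c2C(=O)c1ccc(OCCN2CCCCC2)cc1|1",
    "letrozole|N#Cc1ccc(C(c2ccc(C#N)cc2)n2cncn2)cc1|1",
    "belinostat|ONC(=O)C=Cc1cccc(S(=O)(=O)Nc2ccccc2)c1|1",
    "panobinostat|ONC(=O)C=Cc1ccc(CNCCc2c[nH]c3ccccc23)cc1|1",
    "regorafenib|CNC(=O)c1cc(Oc2ccc(NC(=O)Nc3ccc(Cl)c(C(F)(F)F)c3)c(F)c2)ccn1|1",
    "cabozantinib|COc1cc2nccc(Oc3ccc(NC(=O)C4(C(=O)Nc5ccc(F)cc5)CC4)cc3)c2cc1OC|1",
    "ponatinib|Cc1ccc(C(=O)Nc2ccc(CN3CCN(C)CC3)c(C(F)(F)F)c2)cc1C#Cc1cnc2cccnn12|1",
    "ifosfamide|ClCCNP1(=O)OCCCN1CCCl|0",
    "cyclophosphamide|ClCCN(CCCl)P1(=O)NCCCO1|0",
    "thiotepa|S=P(N1CC1)(N1CC1)N1CC1|0",
    "tretinoin|CC1=C(C=CC(C)=CC=CC(C)=CC(O)=O)C(C)(C)CCC1|0",
    "temozolomide|CN1N=NC2=CN=CN2C1=O|0",
    "camptothecin|CCC1(O)C(=O)OCC2=C1C=C1N(Cc3cc4ccccc4nc13)C2=O|0")
  f <- strsplit(raw, "|", fixed = TRUE)
  data.frame(name = vapply(f, `[`, "", 1L),
             smiles = vapply(f, `[`, "", 2L),
             targeted = vapply(f, `[`, "", 3L) == "1",
             stringsAsFactors = FALSE)
})

#' Built-in drug fixture catalog
#'
#' 51 real drug structures (SMILES) with targeted-therapy flags, spanning
#' more than 40 distinct Bemis-Murcko scaffolds, used by the synthetic
#' cohort generator.
#'
#' @return Data frame with columns `name`, `smiles`, `targeted`.
#' @export
drug_fixture_catalog <- function() DRUG_FIXTURE

#' Default AAC skew model
#'
#' Two-component Beta mixture calibrated (by moment/quantile matching; see
#' `scripts/calibrate_aac_mixture.R`) so that draws have mean 0.145 and
#' median 0.091, the published summary of the CTRPv2 AAC distribution that
#' the generator emulates.
#'
#' @return A list with `weights`, `shape1`, `shape2` (per component).
#' @export
default_aac_skew <- function() {
  list(weights = c(0.87, 0.13),
       shape1 = c(0.978670, 1.348482),
       shape2 = c(8.439953, 1.862189))
}

check_skew <- function(skew) {
  if (!is.list(skew) || !all(c("weights", "shape1", "shape2") %in% names(skew))) {
    stop("skew model needs weights, shape1, shape2", call. = FALSE)
  }
  k <- length(skew$weights)
  if (length(skew$shape1) != k || length(skew$shape2) != k) {
    stop("skew model component lengths differ", call. = FALSE)
  }
  if (any(skew$weights < 0) || abs(sum(skew$weights) - 1) > 1e-8) {
    stop("mixture weights must be nonnegative and sum to 1", call. = FALSE)
  }
  if (any(skew$shape1 <= 0) || any(skew$shape2 <= 0)) {
    stop("Beta shapes must be positive", call. = FALSE)
  }
  invisible(skew)
}

#' Draw baseline AAC values from the skew model
#'
#' Uses the current RNG stream (seed with [set.seed()]).
#'
#' @param n number of draws.
#' @param skew mixture parameters, default [default_aac_skew()].
#' @return Numeric vector of `n` values in `[0, 1]`.
#' @export
sample_aac_base <- function(n, skew = default_aac_skew()) {
  check_skew(skew)
  comp <- sample.int(length(skew$weights), n, replace = TRUE,
                     prob = skew$weights)
  stats::rbeta(n, skew$shape1[comp], skew$shape2[comp])
}

#' Synthetic cohort configuration
#'
#' Defaults define the reference desk-scale study conditions: 120 cell lines
#' over 6 lineages, all eight omic types at modest feature counts, 40 drugs
#' from the built-in fixture, the calibrated AAC skew model, and a planted
#' interaction between one expression feature and the acryloyl substructure
#' `C=CC(=O)N` (the warhead of covalent kinase inhibitors) with effect size
#' `beta`.
#'
#' @param n_cell_lines number of cell lines.
#' @param n_lineages number of cancer lineages.
#' @param features_per_omic named integer vector, features per omic type.
#' @param n_drugs number of drugs sampled from the fixture catalog.
#' @param skew baseline AAC mixture, see [default_aac_skew()].
#' @param beta planted interaction effect size (>= 0).
#' @param noise_sd response noise standard deviation.
#' @param causal_omic omic type carrying the planted signal.
#' @param causal_feature column index of the causal feature.
#' @param smarts SMARTS pattern whose presence gates the signal.
#' @param block_size,block_rho co-regulation block structure: features are
#'   organized into blocks of `block_size` sharing a latent factor that
#'   accounts for a fraction `block_rho` of each feature's residual
#'   variance (block-diagonal covariance, emulating co-expression modules).
#' @param missing_cell_frac fraction of cell lines absent from each
#'   non-causal omic matrix (emulates incomplete profiling coverage).
#' @param seed RNG seed; fully determines the cohort.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_cell_lines = 120L, n_lineages = 6L,
                             features_per_omic = c(MUT = 40L, CNV = 40L,
                                                   EXP = 60L, PROT = 30L,
                                                   MIRNA = 20L, METAB = 20L,
                                                   HIST = 15L, RPPA = 25L),
                             n_drugs = 40L,
                             skew = default_aac_skew(),
                             beta = 0.3, noise_sd = 0.05,
                             causal_omic = "EXP", causal_feature = 1L,
                             smarts = "C=CC(=O)N",
                             block_size = 10L, block_rho = 0.5,
                             missing_cell_frac = 0.1,
                             seed = 1L) {
  stopifnot(n_cell_lines >= 1L, n_lineages >= 1L, n_drugs >= 1L,
            all(features_per_omic >= 1L), beta >= 0, noise_sd >= 0,
            missing_cell_frac >= 0, missing_cell_frac < 1,
            block_size >= 1L, block_rho >= 0, block_rho < 1)
  check_skew(skew)
  if (!causal_omic %in% names(features_per_omic)) {
    stop("causal_omic must be one of the generated omic types", call. = FALSE)
  }
  if (n_drugs > nrow(DRUG_FIXTURE)) {
    stop("n_drugs exceeds the fixture catalog size (", nrow(DRUG_FIXTURE), ")",
         call. = FALSE)
  }
  structure(list(n_cell_lines = as.integer(n_cell_lines),
                 n_lineages = as.integer(n_lineages),
                 features_per_omic = features_per_omic,
                 n_drugs = as.integer(n_drugs), skew = skew, beta = beta,
                 noise_sd = noise_sd, causal_omic = causal_omic,
                 causal_feature = as.integer(causal_feature), smarts = smarts,
                 block_size = as.integer(block_size), block_rho = block_rho,
                 missing_cell_frac = missing_cell_frac,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic multi-omic drug-response cohort
#'
#' All omic matrices share one cell-line panel partitioned into lineages
#' (lineage-specific feature shifts give block structure); each non-causal
#' omic matrix is missing a seeded subset of cell lines to emulate
#' incomplete profiling.  The response is
#' `AAC = clip(base + beta * score(cell line) * substructure(drug) + noise)`
#' where `base` is a draw from the skew mixture, `score` is the standard
#' normal CDF of the standardized causal feature value (so it lies in
#' `(0, 1)`), and `substructure` indicates presence of the configured SMARTS
#' pattern in the drug.
#'
#' @param config a [synthetic_config()].
#' @return A list with `omics` (list of [omic_matrix()]), `catalog` (drug
#'   data frame with `approved_lineages`), `responses` (response records),
#'   and `truth` (ground-truth signal description).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_cell_lines
  cell_lines <- sprintf("CL_%03d", seq_len(n))
  lineage_names <- paste0("lineage_", LETTERS[seq_len(config$n_lineages)])
  lineage <- sample(rep_len(lineage_names, n))
  names(lineage) <- cell_lines

  omics <- list()
  for (ot in names(config$features_per_omic)) {
    p <- config$features_per_omic[[ot]]
    feats <- sprintf("%s_f%03d", ot, seq_len(p))
    keep <- cell_lines
    if (ot != config$causal_omic && config$missing_cell_frac > 0) {
      drop <- sample(n, size = floor(n * config$missing_cell_frac))
      if (length(drop)) keep <- cell_lines[-drop]
    }
    shift <- matrix(stats::rnorm(config$n_lineages * p, sd = 0.7),
                    config$n_lineages, p,
                    dimnames = list(lineage_names, feats))
    # block-diagonal covariance: features within a block share a latent
    # factor (co-regulation module) carrying block_rho of residual variance
    block_of <- ceiling(seq_len(p) / config$block_size)
    fac <- matrix(stats::rnorm(length(keep) * max(block_of)),
                  length(keep), max(block_of))
    resid <- sqrt(config$block_rho) * fac[, block_of, drop = FALSE] +
      sqrt(1 - config$block_rho) *
        matrix(stats::rnorm(length(keep) * p), length(keep), p)
    if (ot == "MUT") {
      base_logit <- stats::qlogis(stats::rbeta(p, 1.5, 6))
      pr <- stats::plogis(sweep(shift[lineage[keep], , drop = FALSE] + resid,
                                2L, base_logit, "+"))
      vals <- matrix(stats::rbinom(length(pr), 1L, pr), nrow(pr), p)
    } else {
      vals <- shift[lineage[keep], , drop = FALSE] + resid
    }
    omics[[ot]] <- omic_matrix(vals, ot, cell_lines = keep,
                               feature_names = feats)
  }

  idx <- sort(sample(nrow(DRUG_FIXTURE), config$n_drugs))
  catalog <- DRUG_FIXTURE[idx, , drop = FALSE]
  rownames(catalog) <- NULL
  # approved lineages: one cognate lineage per drug (two for untargeted)
  catalog$approved_lineages <- lapply(seq_len(nrow(catalog)), function(i) {
    k <- if (catalog$targeted[i]) 1L else min(2L, config$n_lineages)
    sample(lineage_names, k)
  })
  substruct <- vapply(catalog$smiles,
                      function(s) smarts_matches(s, config$smarts) > 0L,
                      logical(1))
  names(substruct) <- catalog$name

  causal <- omics[[config$causal_omic]]
  x <- causal$values[, config$causal_feature]
  score <- stats::pnorm((x - mean(x)) / stats::sd(x))
  names(score) <- causal$cell_lines

  grid <- expand.grid(cell_line = cell_lines, drug = catalog$name,
                      stringsAsFactors = FALSE)
  m <- nrow(grid)
  base <- sample_aac_base(m, config$skew)
  signal <- config$beta * score[grid$cell_line] *
    as.numeric(substruct[grid$drug])
  aac <- pmin(1, pmax(0, base + signal + stats::rnorm(m, sd = config$noise_sd)))
  responses <- data.frame(cell_line = grid$cell_line, drug = grid$drug,
                          aac = aac, lineage = unname(lineage[grid$cell_line]),
                          stringsAsFactors = FALSE)

  truth <- list(causal_omic = config$causal_omic,
                causal_feature = causal$feature_names[config$causal_feature],
                smarts = config$smarts,
                beta = config$beta,
                flagged_drugs = catalog$name[substruct],
                score = score,
                substructure = substruct)
  list(omics = omics, catalog = catalog, responses = responses, truth = truth)
}

#' Planted-signal covariate for a set of response records
#'
#' Recomputes the generator's interaction covariate
#' `score(cell line) * substructure(drug)` for each record, e.g. to verify
#' by regression that the planted effect size is recoverable.
#'
#' @param cohort output of [generate_cohort()].
#' @param records response records (default: the cohort's own).
#' @return Numeric covariate vector aligned to `records`.
#' @export
signal_covariate <- function(cohort, records = cohort$responses) {
  cohort$truth$score[records$cell_line] *
    as.numeric(cohort$truth$substructure[records$drug])
}

#' Hill dose-response curve and its AAC
#'
#' Viability follows a descending Hill curve
#' `v(d) = 1 / (1 + (d / ec50)^hill)`; the area above the curve is one
#' minus the trapezoidal mean viability over the log10-dose range, so a
#' completely inert drug has AAC 0 and total kill across the range has
#' AAC 1.
#'
#' @param ec50 half-maximal effective concentration (same units as doses).
#' @param hill Hill coefficient (> 0).
#' @param doses strictly increasing dose vector, length >= 2.
#' @return A list with `viability` and `aac`.
#' @export
generate_dose_response <- function(ec50, hill, doses) {
  stopifnot(ec50 > 0, hill > 0)
  if (length(doses) < 2L) stop("need at least 2 doses", call. = FALSE)
  if (any(diff(doses) <= 0) || any(doses <= 0)) {
    stop("doses must be positive and strictly increasing", call. = FALSE)
  }
  v <- 1 / (1 + (doses / ec50)^hill)
  list(viability = v, aac = aac_from_viability(v, doses))
}

#' @rdname generate_dose_response
#' @param viability viability values in `[0, 1]` at each dose.
#' @export
aac_from_viability <- function(viability, doses) {
  if (length(doses) < 2L) stop("need at least 2 doses", call. = FALSE)
  stopifnot(length(viability) == length(doses))
  x <- log10(doses)
  w <- diff(x)
  mean_v <- sum(w * (utils::head(viability, -1) + utils::tail(viability, -1)) / 2) /
    (max(x) - min(x))
  1 - mean_v
}

#' Write a synthetic cohort to disk in the package's standard formats
#'
#' One CSV per omic matrix, a drug catalog CSV (`approved_lineages` joined
#' with `;`), and a response table CSV.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ot in names(cohort$omics)) {
    write_omic_matrix(cohort$omics[[ot]],
                      file.path(dir, paste0("omic_", ot, ".csv")))
  }
  cat_df <- data.frame(name = cohort$catalog$name,
                       smiles = cohort$catalog$smiles,
                       targeted = as.integer(cohort$catalog$targeted),
                       approved_lineages = vapply(cohort$catalog$approved_lineages,
                                                  paste, "", collapse = ";"),
                       stringsAsFactors = FALSE)
  utils::write.csv(cat_df, file.path(dir, "drug_catalog.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$responses, file.path(dir, "responses.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
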