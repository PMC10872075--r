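# Range-resolved and subgroup evaluation of combined validation predictions,
# and the drug-repurposing screen.  A single score over the whole AAC range
# is misleading under heavy label skew, so accuracy is additionally reported
# as a trailing moving average of the absolute error along the sorted AAC
# range; note the RMSE of a single prediction equals its MAE.

#' Trailing moving-average MAE along the AAC range
#'
#' Records are sorted by true AAC ascending (stable; ties keep input
#' order), absolute errors are computed, and a trailing window mean is
#' reported at each position from `window` onward.
#'
#' @param predictions prediction records (`true_aac`, `pred_aac`).
#' @param window trailing window size (default 500); clipped to the number
#'   of records.
#' @return Data frame with `true_aac` (at window end) and `mae`.
#' @export
moving_average_mae <- function(predictions, window = 500L) {
  n <- nrow(predictions)
  if (is.null(n) || n == 0L) stop("moving_average_mae: empty input", call. = FALSE)
  window <- min(as.integer(window), n)
  ord <- order(predictions$true_aac)   # stable: ties by record order
  true_s <- predictions$true_aac[ord]
  err <- abs(predictions$true_aac - predictions$pred_aac)[ord]
  cs <- cumsum(err)
  mae <- (cs[window:n] - c(0, cs)[seq.int(1L, n - window + 1L)]) / window
  data.frame(true_aac = true_s[window:n], mae = mae)
}

#' Subgroup RMSE of prediction records
#'
#' Unweighted RMSE over the records passing the filters, with the subgroup
#' size.  An empty subgroup yields an explicit empty result (`n = 0`,
#' `rmse = NA`), never zero.
#'
#' @param predictions prediction records.
#' @param targeted optional logical filter on the drug's targeted flag
#'   (requires `catalog`).
#' @param aac_min,aac_max optional true-AAC range filter (inclusive).
#' @param scheme optional scheme filter (requires a `scheme` column).
#' @param catalog drug catalog supplying the targeted flag.
#' @return A list with `rmse` and `n`.
#' @export
subgroup_rmse <- function(predictions, targeted = NULL, aac_min = NULL,
                          aac_max = NULL, scheme = NULL, catalog = NULL) {
  keep <- rep(TRUE, nrow(predictions))
  if (!is.null(targeted)) {
    if (is.null(catalog)) stop("targeted filter needs a catalog", call. = FALSE)
    flag <- catalog$targeted[match(predictions$drug, catalog$name)]
    keep <- keep & !is.na(flag) & flag == targeted
  }
  if (!is.null(aac_min)) keep <- keep & predictions$true_aac >= aac_min
  if (!is.null(aac_max)) keep <- keep & predictions$true_aac <= aac_max
  if (!is.null(scheme)) keep <- keep & predictions$scheme == scheme
  n <- sum(keep)
  if (n == 0L) return(list(rmse = NA_real_, n = 0L))
  sub <- predictions[keep, , drop = FALSE]
  list(rmse = weighted_rmse(sub$pred_aac, sub$true_aac), n = n)
}

#' Screen for drugs with repurposing potential
#'
#' For each drug with a non-empty approved-lineage set, finds its maximum
#' true AAC among cognate cell lines (those from approved lineages) and
#' emits every noncognate record whose true AAC exceeds that maximum by at
#' least `margin` AND whose prediction is accurate (absolute error at most
#' `mae_threshold`).  Predictions should come from a scheme in which the
#' cell line was unseen during training.
#'
#' @param responses full response table (`cell_line`, `drug`, `aac`,
#'   `lineage`) used to establish cognate response levels.
#' @param predictions prediction records for candidate (noncognate) pairs.
#' @param catalog drug catalog with `approved_lineages`.
#' @param margin required AAC excess over the cognate maximum (default 0.2).
#' @param mae_threshold required prediction accuracy (default 0.2).
#' @return Data frame of repurposing candidates.
#' @export
repurposing_screen <- function(responses, predictions, catalog,
                               margin = 0.2, mae_threshold = 0.2) {
  out <- NULL
  for (i in seq_len(nrow(catalog))) {
    drug <- catalog$name[i]
    approved <- catalog$approved_lineages[[i]]
    if (!length(approved)) {
      warning("drug '", drug, "' has no approved lineages; skipped")
      next
    }
    resp <- responses[responses$drug == drug, , drop = FALSE]
    cognate <- resp[resp$lineage %in% approved, , drop = FALSE]
    if (!nrow(cognate)) next
    max_cognate <- max(cognate$aac)
    cand <- predictions[predictions$drug == drug &
                          !(predictions$lineage %in% approved), , drop = FALSE]
    if (!nrow(cand)) next
    mae <- abs(cand$pred_aac - cand$true_aac)
    hit <- cand$true_aac >= max_cognate + margin & mae <= mae_threshold
    if (any(hit)) {
      out <- rbind(out, data.frame(
        drug = drug,
        cell_line = cand$cell_line[hit],
        lineage = cand$lineage[hit],
        noncognate_aac = cand$true_aac[hit],
        max_cognate_aac = max_cognate,
        pred_aac = cand$pred_aac[hit],
        mae = mae[hit],
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    out <- data.frame(drug = character(0), cell_line = character(0),
                      lineage = character(0), noncognate_aac = numeric(0),
                      max_cognate_aac = numeric(0), pred_aac = numeric(0),
                      mae = numeric(0), stringsAsFactors = FALSE)
  }
  out[order(-out$noncognate_aac + out$max_cognate_aac, out$drug), ,
      drop = FALSE]
}
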