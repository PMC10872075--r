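pred_df <- function(true, pred, ...) {
  data.frame(cell_line = sprintf("c%d", seq_along(true)),
             drug = "d", true_aac = true, pred_aac = pred,
             lineage = "x", ..., stringsAsFactors = FALSE)
}

test_that("moving-average MAE matches hand computations", {
  p <- pred_df(c(0.2, 0.2, 0.5), c(0.1, 0.2, 0.3))
  curve <- moving_average_mae(p, window = 3)
  expect_equal(nrow(curve), 1L)
  expect_equal(curve$mae, mean(c(0.1, 0, 0.2)))
  expect_equal(curve$true_aac, 0.5)

  # window 1: per-sample absolute errors in sorted order
  set.seed(1)
  p2 <- pred_df(runif(20), runif(20))
  c1 <- moving_average_mae(p2, window = 1)
  ord <- order(p2$true_aac)
  expect_equal(c1$mae, abs(p2$true_aac - p2$pred_aac)[ord])

  # window n equals the global MAE
  cn <- moving_average_mae(p2, window = 20)
  expect_equal(cn$mae, mean(abs(p2$true_aac - p2$pred_aac)))
  # oversize window is clipped
  expect_equal(moving_average_mae(p2, window = 500)$mae, cn$mae)
  expect_error(moving_average_mae(p2[0, ]), "empty")
})

test_that("single-prediction MAE equals its RMSE", {
  p <- pred_df(0.658, 0.595)
  expect_equal(moving_average_mae(p, 1)$mae, 0.063)
  expect_equal(subgroup_rmse(p)$rmse, 0.063)
})

test_that("subgroup RMSE filters and reports sizes correctly", {
  p <- pred_df(c(0.1, 0.75, 0.9, 0.3), c(0.4, 0.45, 0.9, 0.3))
  expect_equal(subgroup_rmse(p)$n, 4L)
  # records with true AAC >= 0.7: errors 0.30 and 0
  expect_equal(subgroup_rmse(p, aac_min = 0.7),
               list(rmse = sqrt(0.09 / 2), n = 2L))
  expect_equal(subgroup_rmse(p, aac_min = 0.95), list(rmse = NA_real_, n = 0L))
  cat <- data.frame(name = "d", smiles = "CCO", targeted = TRUE)
  cat$approved_lineages <- list(character(0))
  expect_equal(subgroup_rmse(p, targeted = TRUE, catalog = cat)$n, 4L)
  expect_equal(subgroup_rmse(p, targeted = FALSE, catalog = cat)$n, 0L)
})

test_that("subgroup RMSE of a union lies between subgroup extremes", {
  set.seed(2)
  p <- pred_df(runif(50), runif(50))
  lo <- subgroup_rmse(p, aac_max = 0.5)$rmse
  hi <- subgroup_rmse(p, aac_min = 0.5)$rmse
  all <- subgroup_rmse(p)$rmse
  expect_gte(all, min(lo, hi))
  expect_lte(all, max(lo, hi))
})

repurposing_fixture <- function() {
  catalog <- data.frame(name = c("dA", "dB"), smiles = c("CCO", "CCN"),
                        targeted = c(TRUE, TRUE), stringsAsFactors = FALSE)
  catalog$approved_lineages <- list("lineA", "lineA")
  responses <- data.frame(
    cell_line = c("c1", "c2", "c3", "c1", "c2", "c3"),
    drug = rep(c("dA", "dB"), each = 3),
    aac = c(0.30, 0.55, 0.10, 0.30, 0.45, 0.62),
    lineage = c("lineA", "lineB", "lineA", "lineA", "lineB", "lineA"),
    stringsAsFactors = FALSE)
  list(catalog = catalog, responses = responses)
}

test_that("repurposing screen applies both margin and accuracy criteria", {
  fx <- repurposing_fixture()
  # dA: cognate max 0.30 (c1, c3 are lineA); c2 (lineB) has 0.55, margin 0.25
  preds <- data.frame(cell_line = "c2", drug = "dA", true_aac = 0.55,
                      pred_aac = 0.50, lineage = "lineB",
                      stringsAsFactors = FALSE)
  hits <- repurposing_screen(fx$responses, preds, fx$catalog)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$drug, "dA")
  expect_equal(hits$max_cognate_aac, 0.30)
  expect_equal(hits$mae, 0.05)

  # margin below 0.2 fails criterion (i)
  preds2 <- preds; preds2$true_aac <- 0.45
  resp2 <- fx$responses; resp2$aac[2] <- 0.45
  expect_equal(nrow(repurposing_screen(resp2, preds2, fx$catalog)), 0L)

  # inaccurate prediction fails criterion (ii)
  preds3 <- preds; preds3$pred_aac <- 0.10
  expect_equal(nrow(repurposing_screen(fx$responses, preds3, fx$catalog)), 0L)
})

test_that("raising the margin never adds candidates", {
  co <- tiny_cohort()
  set.seed(5)
  preds <- co$responses
  preds$true_aac <- preds$aac
  preds$pred_aac <- pmin(1, pmax(0, preds$aac + rnorm(nrow(preds), 0, 0.05)))
  counts <- vapply(c(0.05, 0.1, 0.2, 0.3), function(m) {
    nrow(suppressWarnings(
      repurposing_screen(co$responses, preds, co$catalog, margin = m)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("drugs without approved lineages are skipped with a warning", {
  fx <- repurposing_fixture()
  fx$catalog$approved_lineages[[2]] <- character(0)
  preds <- data.frame(cell_line = "c2", drug = "dB", true_aac = 0.45,
                      pred_aac = 0.45, lineage = "lineB")
  expect_warning(out <- repurposing_screen(fx$responses, preds, fx$catalog),
                 "no approved lineages")
  expect_equal(nrow(out), 0L)
})
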