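# Toy forwards for the core path-integral routine.
linear_f <- function(w) {
  force(w)
  function(tape, xn) {
    drpfuse:::ad_sum(drpfuse:::ad_mul(xn, drpfuse:::ad_const(tape, w)))
  }
}

two_layer_f <- function(W1, b1, W2) {
  function(tape, xn) {
    h <- drpfuse:::ad_tanh(drpfuse:::ad_dense(xn, drpfuse:::ad_const(tape, W1),
                                              drpfuse:::ad_const(tape, b1)))
    drpfuse:::ad_sum(drpfuse:::ad_matmul(h, drpfuse:::ad_const(tape, W2)))
  }
}

test_that("linear models get the closed-form attribution at any step count", {
  set.seed(1)
  w <- matrix(rnorm(6), 1, 6)
  x <- matrix(rnorm(6), 1, 6)
  for (m in c(1L, 3L, 64L)) {
    for (rule in c("trapezoid", "riemann_right")) {
      out <- ig_attribute(linear_f(w), x,
                          config = attribution_config(steps = m, rule = rule))
      expect_equal(out$attributions, w * x, tolerance = 1e-10)
      expect_lt(out$completeness, 1e-10)
    }
  }
})

test_that("baseline-equal input yields zero attributions", {
  set.seed(2)
  W1 <- matrix(rnorm(12), 4, 3); b1 <- matrix(0, 1, 3)
  W2 <- matrix(rnorm(3), 3, 1)
  x <- matrix(rnorm(4), 1, 4)
  out <- ig_attribute(two_layer_f(W1, b1, W2), x, baseline = x)
  expect_equal(out$attributions, 0 * x)
  expect_equal(out$completeness, 0)
})

test_that("completeness residual is small and tightens with more steps", {
  set.seed(3)
  W1 <- matrix(rnorm(15), 5, 3); b1 <- matrix(rnorm(3), 1, 3)
  W2 <- matrix(rnorm(3), 3, 1)
  f <- two_layer_f(W1, b1, W2)
  x <- matrix(rnorm(5), 1, 5)
  res <- vapply(c(8L, 64L, 512L), function(m) {
    ig_attribute(f, x, config = attribution_config(steps = m))$completeness
  }, numeric(1))
  out <- ig_attribute(f, x, config = attribution_config(steps = 512L))
  expect_lt(out$completeness, 1e-3 * abs(out$fx - out$f0))
  expect_true(all(diff(res) <= 1e-12))
})

test_that("a weight-zeroed feature receives zero attribution", {
  set.seed(4)
  W1 <- matrix(rnorm(12), 4, 3)
  W1[2, ] <- 0                       # feature 2 provably ignored
  b1 <- matrix(rnorm(3), 1, 3)
  W2 <- matrix(rnorm(3), 3, 1)
  x <- matrix(rnorm(4), 1, 4)
  out <- ig_attribute(two_layer_f(W1, b1, W2), x)
  expect_lt(abs(out$attributions[2]), 1e-9)
})

test_that("top_features ranks by absolute score with stable ties", {
  scores <- data.frame(modality = "EXP", feature = c("a", "b", "c"),
                       score = c(0.5, -0.9, 0.1))
  top <- top_features(scores, 2)
  expect_equal(top$feature, c("b", "a"))
  # k beyond the feature count returns the full list
  expect_equal(nrow(top_features(scores, 10)), 3L)
  # all-zero map: deterministic name order
  z <- data.frame(modality = "EXP", feature = c("x", "m", "a"), score = 0)
  expect_equal(top_features(z, 3)$feature, c("a", "m", "x"))
})

make_trained_model <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    co <- tiny_cohort()
    folds <- split_records(co$responses, "cell_line", 3, seed = 2)
    cfg <- model_config_preset("refined", omic_types = c("EXP", "CNV"),
                               d_omic_latent = 4L, d_drug_latent = 8L,
                               lmf_rank = 2L, d_fused = 8L, head_hidden = 8L,
                               epochs = 15L, patience = 15L, ae_epochs = 15L,
                               seed = 4L)
    out <- suppressMessages(
      train_fold(co$responses, folds[[1]], co$omics, co$catalog, cfg))
    cache <<- list(model = out$model, cohort = co)
    cache
  }
})

test_that("model attributions satisfy completeness and input structure", {
  mt <- make_trained_model()
  model <- mt$model
  cl <- model$data$panel[1]
  drug <- model$data$drugs[2]
  attr <- integrated_gradients(model, cl, drug,
                               config = attribution_config(steps = 32L))
  expect_s3_class(attr, "attribution_map")
  expect_all_finite(attr$scores$score)
  expect_lt(attr$completeness,
            max(1e-3, 5e-3 * abs(attr$prediction - attr$baseline_prediction)))
  expect_setequal(unique(attr$scores$modality), c("EXP", "CNV", "drug"))
  # per-atom summary covers the drug's heavy atoms
  g <- featurize_smiles(model$data$smiles[2])
  expect_equal(nrow(attr$atom_scores), g$n_atoms)
})

test_that("drug-graph attributions are invariant to atom reordering", {
  mt <- make_trained_model()
  model <- mt$model
  cl <- model$data$panel[2]
  drug <- model$data$drugs[1]
  a1 <- integrated_gradients(model, cl, drug, target = "drug",
                             config = attribution_config(steps = 16L))
  # re-featurize the same molecule from its canonical spelling
  model2 <- model
  g <- model$data$graphs[[1]]
  model2$data$smiles[1] <- g$canonical
  model2$data$graphs[[1]] <- featurize_smiles(g$canonical)
  model2$data$batch <- batch_graphs(model2$data$graphs)
  a2 <- integrated_gradients(model2, cl, drug, target = "drug",
                             config = attribution_config(steps = 16L))
  s1 <- sort(a1$atom_scores$score)
  s2 <- sort(a2$atom_scores$score)
  expect_equal(s1, s2, tolerance = 1e-5)
})

test_that("unknown identifiers are rejected", {
  mt <- make_trained_model()
  expect_error(integrated_gradients(mt$model, "nope", mt$model$data$drugs[1]),
               "unknown cell line")
  expect_error(integrated_gradients(mt$model, mt$model$data$panel[1], "nope"),
               "unknown drug")
})
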