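# Shared fixtures, built in code at test time.

# Small cohort reused across tests (cached per test run).
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(synthetic_config(
        n_cell_lines = 30L, n_lineages = 3L,
        features_per_omic = c(EXP = 12L, CNV = 10L, MUT = 8L),
        n_drugs = 12L, missing_cell_frac = 0.1, seed = 7L))
    }
    cache
  }
})

write_tmp_csv <- function(df, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = envir)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Minimal omic CSV: cell line rows x feature columns.
omic_csv <- function(values, cell_lines, features, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = envir)
  df <- data.frame(cell_line = cell_lines, values, check.names = FALSE)
  colnames(df) <- c("cell_line", features)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

expect_all_finite <- function(x) {
  expect_true(all(is.finite(x)))
}

# Brute-force fusion oracle: rebuild the full tensor from the rank factors
# and contract it with the outer product of the 1-augmented latents.
lmf_tensor_oracle <- function(latents, factors, cfg) {
  hhat <- lapply(latents, function(h) c(h, 1))
  r <- cfg$rank; d_out <- cfg$d_out
  out <- numeric(d_out)
  for (k in seq_len(d_out)) {
    cols <- (seq_len(r) - 1L) * d_out + k
    for (i in seq_len(r)) {
      term <- 1
      for (m in seq_along(hhat)) {
        term <- term * sum(hhat[[m]] * factors[[m]][, cols[i]])
      }
      out[k] <- out[k] + term
    }
  }
  out
}
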