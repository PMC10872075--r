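make_records <- function(n_cl, n_drug, n_lin = 3L, seed = 1L) {
  set.seed(seed)
  cl <- sprintf("CL%02d", seq_len(n_cl))
  # guarantee all n_lin lineages are realized
  lin <- c(paste0("lin", seq_len(n_lin)),
           sample(paste0("lin", seq_len(n_lin)), n_cl - n_lin, replace = TRUE))
  grid <- expand.grid(cell_line = cl, drug = sprintf("D%02d", seq_len(n_drug)),
                      stringsAsFactors = FALSE)
  data.frame(grid, aac = runif(nrow(grid)),
             lineage = lin[match(grid$cell_line, cl)],
             stringsAsFactors = FALSE)
}

test_that("cell-line folds partition cell lines across validation sets", {
  rec <- make_records(17, 6)
  folds <- split_records(rec, "cell_line", 5, seed = 2)
  val_cl <- lapply(folds, function(f) unique(rec$cell_line[f$validation]))
  expect_equal(sort(unlist(val_cl)), sort(unique(rec$cell_line)))
  expect_equal(sum(lengths(val_cl)), length(unique(rec$cell_line)))
  for (f in folds) {
    expect_length(intersect(rec$cell_line[f$train],
                            rec$cell_line[f$validation]), 0)
  }
  # validation sets partition the records
  expect_equal(sort(unlist(lapply(folds, `[[`, "validation"))),
               seq_len(nrow(rec)))
})

test_that("scaffold folds keep each scaffold on one side", {
  rec <- make_records(6, 10)
  smap <- setNames(rep(paste0("S", 1:5), each = 2), sprintf("D%02d", 1:10))
  folds <- split_records(rec, "drug_scaffold", 5, seed = 3, scaffold_map = smap)
  for (f in folds) {
    expect_length(intersect(smap[rec$drug[f$train]],
                            smap[rec$drug[f$validation]]), 0)
    expect_length(unique(smap[rec$drug[f$validation]]), 1L)
  }
  expect_error(split_records(rec, "drug_scaffold", 5, seed = 1,
                             scaffold_map = smap[1:5]), "unresolvable")
  expect_error(split_records(rec, "drug_scaffold", 5), "scaffold_map")
})

test_that("split-by-both validates on jointly unseen pairs and discards mixed", {
  rec <- make_records(4, 4)
  smap <- setNames(paste0("S", 1:4), sprintf("D%02d", 1:4))
  folds <- split_records(rec, "both", 2, seed = 4, scaffold_map = smap)
  for (f in folds) {
    vcl <- unique(rec$cell_line[f$validation])
    vsc <- unique(smap[rec$drug[f$validation]])
    tcl <- unique(rec$cell_line[f$train])
    tsc <- unique(smap[rec$drug[f$train]])
    expect_length(intersect(vcl, tcl), 0)
    expect_length(intersect(vsc, tsc), 0)
    # quadrant structure: every record is exactly one of train/val/discard
    expect_equal(sort(c(f$train, f$validation, f$discarded)),
                 seq_len(nrow(rec)))
    # discarded records mix a validation cell line with a training scaffold
    # or vice versa
    for (i in f$discarded) {
      in_vcl <- rec$cell_line[i] %in% vcl
      in_vsc <- smap[rec$drug[i]] %in% vsc
      expect_true(xor(in_vcl, in_vsc))
    }
  }
  # validation sets are disjoint across folds
  v <- unlist(lapply(folds, `[[`, "validation"))
  expect_equal(anyDuplicated(v), 0L)
})

test_that("no grouping key leaks across many random fixtures", {
  set.seed(99)
  for (i in 1:250) {
    n_cl <- sample(6:15, 1); n_drug <- sample(5:12, 1)
    rec <- make_records(n_cl, n_drug, n_lin = sample(4:6, 1), seed = i)
    k <- sample(2:3, 1)
    # guarantee at least k distinct scaffolds
    smap <- setNames(c(paste0("S", seq_len(k)),
                       sample(paste0("S", 1:5), n_drug - k, replace = TRUE)),
                     sprintf("D%02d", seq_len(n_drug)))
    for (scheme in c("cell_line", "drug_scaffold", "both", "cancer_type")) {
      key <- switch(scheme, cell_line = rec$cell_line,
                    drug_scaffold = unname(smap[rec$drug]),
                    cancer_type = rec$lineage, both = NA)
      folds <- split_records(rec, scheme, k, seed = i, scaffold_map = smap)
      for (f in folds) {
        if (scheme == "both") {
          expect_length(intersect(rec$cell_line[f$train],
                                  rec$cell_line[f$validation]), 0)
          expect_length(intersect(smap[rec$drug[f$train]],
                                  smap[rec$drug[f$validation]]), 0)
        } else {
          expect_length(intersect(key[f$train], key[f$validation]), 0)
        }
      }
      if (scheme != "both") {
        expect_equal(sort(unlist(lapply(folds, `[[`, "validation"))),
                     seq_len(nrow(rec)))
      }
    }
  }
})

test_that("splits are seed-deterministic and fail on too few groups", {
  rec <- make_records(10, 4)
  a <- split_records(rec, "cell_line", 5, seed = 7)
  b <- split_records(rec, "cell_line", 5, seed = 7)
  expect_identical(a, b)
  c <- split_records(rec, "cell_line", 5, seed = 8)
  expect_false(identical(a, c))
  expect_error(split_records(make_records(3, 4), "cell_line", 5),
               "fewer groups")
})

test_that("complete-profile filtering keeps fully profiled cell lines", {
  co <- tiny_cohort()
  out <- complete_profile_filter(co$responses, co$omics)
  complete <- Reduce(intersect, lapply(co$omics, function(m) m$cell_lines))
  expect_setequal(unique(out$records$cell_line), complete)
  expect_equal(out$summary$n_cell_lines_complete, length(complete))
  expect_equal(out$summary$pct_records,
               100 * nrow(out$records) / nrow(co$responses))
  # all cell lines complete -> unchanged
  out2 <- complete_profile_filter(co$responses, co$omics["EXP"])
  expect_equal(nrow(out2$records), nrow(co$responses))
  # a cell line missing from one matrix loses all its records
  dropped <- setdiff(co$omics$EXP$cell_lines, co$omics$CNV$cell_lines)
  if (length(dropped)) {
    expect_false(any(out$records$cell_line %in% dropped))
  }
})

test_that("hand-counted retention percentage is reported", {
  m1 <- omic_matrix(matrix(0, 10, 2,
                           dimnames = list(paste0("c", 1:10), c("f1", "f2"))),
                    "EXP")
  m2 <- omic_matrix(matrix(0, 4, 2,
                           dimnames = list(paste0("c", 1:4), c("f1", "f2"))),
                    "CNV")
  rec <- data.frame(cell_line = rep(paste0("c", 1:10), 2),
                    drug = "d", aac = 0.1, lineage = "x")
  out <- complete_profile_filter(rec, list(m1, m2))
  expect_equal(out$summary$pct_cell_lines, 40)
  expect_equal(nrow(out$records), 8L)
})
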