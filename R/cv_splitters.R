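# Leakage-free k-fold splitting of response records.  Four schemes: by cell
# line, by drug scaffold, by both simultaneously, and by cancer type.  In
# every scheme the grouping key sets of train and validation are disjoint
# within each fold, and the validation sets across folds partition the
# records (minus, for the "both" scheme, the mixed pairs that are discarded
# to keep cell line AND scaffold simultaneously unseen).

SPLIT_SCHEMES <- c("cell_line", "drug_scaffold", "both", "cancer_type")

# Deterministic balanced grouping: groups (named record counts) are ordered
# lexically, shuffled with the seed, then greedily dealt to the fold with
# the fewest records so far (ties broken by lowest fold index).
assign_groups <- function(group_sizes, k, seed) {
  groups <- sort(names(group_sizes))
  if (length(groups) < k) {
    stop(sprintf("fewer groups (%d) than folds (%d)", length(groups), k),
         call. = FALSE)
  }
  set.seed(seed)
  groups <- sample(groups)
  load <- numeric(k)
  fold_of <- integer(length(groups))
  names(fold_of) <- groups
  for (g in groups) {
    f <- which.min(load)
    fold_of[[g]] <- f
    load[f] <- load[f] + group_sizes[[g]]
  }
  fold_of
}

record_group_key <- function(records, scheme, scaffold_map = NULL) {
  switch(scheme,
         cell_line = records$cell_line,
         cancer_type = records$lineage,
         drug_scaffold = ,
         both = {
           if (is.null(scaffold_map)) {
             stop("scheme '", scheme, "' needs a scaffold_map (drug -> scaffold)",
                  call. = FALSE)
           }
           sc <- scaffold_map[records$drug]
           if (anyNA(sc)) {
             stop("unresolvable scaffold for drug(s): ",
                  paste(unique(records$drug[is.na(sc)]), collapse = ", "),
                  call. = FALSE)
           }
           unname(sc)
         })
}

#' Scaffold map for a drug catalog
#'
#' @param catalog drug catalog data frame (`name`, `smiles`).
#' @return Named character vector: drug name -> scaffold identifier.
#' @export
scaffold_map <- function(catalog) {
  out <- vapply(catalog$smiles, murcko_scaffold, "")
  names(out) <- catalog$name
  out
}

#' Split response records into leakage-free cross-validation folds
#'
#' Grouping keys (cell lines, drug scaffolds, or lineages) are dealt into
#' `k_folds` balanced groups; fold `i`'s validation set is the records of
#' group `i` and its training set the rest.  For `scheme = "both"`, cell
#' lines and scaffolds are partitioned independently; fold `i` validates on
#' records whose cell line AND scaffold both fall in group `i`, trains on
#' records where neither does, and discards the mixed records (reported per
#' fold) -- the construction that keeps both entities simultaneously unseen.
#'
#' @param records response record data frame (`cell_line`, `drug`, `aac`,
#'   `lineage`).
#' @param scheme one of `"cell_line"`, `"drug_scaffold"`, `"both"`,
#'   `"cancer_type"`.
#' @param k_folds number of folds (default 5).
#' @param seed RNG seed controlling the group shuffle.
#' @param scaffold_map named drug -> scaffold vector (see [scaffold_map()]);
#'   required for the scaffold-based schemes.
#' @return List of `fold_assignment` objects with `train`, `validation`,
#'   `discarded` integer record indices.
#' @export
split_records <- function(records, scheme = SPLIT_SCHEMES, k_folds = 5L,
                          seed = 1L, scaffold_map = NULL) {
  scheme <- match.arg(scheme, SPLIT_SCHEMES)
  stopifnot(k_folds >= 2L, nrow(records) >= 1L)
  if (scheme == "both") {
    cl_key <- records$cell_line
    sc_key <- record_group_key(records, "drug_scaffold", scaffold_map)
    cl_fold <- assign_groups(table(cl_key), k_folds, seed)
    sc_fold <- assign_groups(table(sc_key), k_folds, seed + 1L)
    a <- unname(cl_fold[cl_key]); b <- unname(sc_fold[sc_key])
    folds <- lapply(seq_len(k_folds), function(i) {
      structure(list(scheme = scheme, fold = i,
                     train = which(a != i & b != i),
                     validation = which(a == i & b == i),
                     discarded = which(xor(a == i, b == i))),
                class = "fold_assignment")
    })
  } else {
    key <- record_group_key(records, scheme, scaffold_map)
    fold_of <- assign_groups(table(key), k_folds, seed)
    f <- unname(fold_of[key])
    folds <- lapply(seq_len(k_folds), function(i) {
      structure(list(scheme = scheme, fold = i,
                     train = which(f != i),
                     validation = which(f == i),
                     discarded = integer(0)),
                class = "fold_assignment")
    })
  }
  folds
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold %d (%s): %d train, %d validation, %d discarded>\n",
              x$fold, x$scheme, length(x$train), length(x$validation),
              length(x$discarded)))
  invisible(x)
}

#' Restrict records to cell lines with complete omic profiles
#'
#' Keeps only records whose cell line is present in every supplied omic
#' matrix, mirroring the restricted complete-profile analysis subset.
#'
#' @param records response record data frame.
#' @param omics list of [omic_matrix()] objects.
#' @return A list with `records` (filtered) and `summary` (cell lines and
#'   records retained, with percentages).
#' @export
complete_profile_filter <- function(records, omics) {
  stopifnot(length(omics) >= 1L)
  panels <- lapply(omics, function(m) m$cell_lines)
  complete <- Reduce(intersect, panels)
  all_cl <- unique(records$cell_line)
  keep <- records$cell_line %in% complete
  summary <- list(
    n_cell_lines = length(all_cl),
    n_cell_lines_complete = sum(all_cl %in% complete),
    pct_cell_lines = 100 * sum(all_cl %in% complete) / length(all_cl),
    n_records = nrow(records),
    n_records_complete = sum(keep),
    pct_records = 100 * sum(keep) / nrow(records))
  if (!any(keep)) warning("no cell line has a complete profile")
  list(records = records[keep, , drop = FALSE], summary = summary)
}

#' Write a fold-assignment audit table
#'
#' @param folds output of [split_records()].
#' @param path output TSV path.
#' @return The table, invisibly.
#' @export
write_fold_table <- function(folds, path) {
  rows <- do.call(rbind, lapply(folds, function(f) {
    rbind(data.frame(record = f$train, fold = f$fold, role = "train"),
          data.frame(record = f$validation, fold = f$fold, role = "validation"),
          if (length(f$discarded)) {
            data.frame(record = f$discarded, fold = f$fold, role = "discarded")
          })
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(rows)
}
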