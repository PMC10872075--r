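# Domain containers and file I/O: omic matrices, drug catalogs, response
# tables, and training-split-only standardization.

#' Recognized omic data types
#'
#' MUT: single nucleotide variation (binary per-gene indicators),
#' CNV: copy number variation, EXP: gene expression, PROT: MS-based
#' quantitative proteomics, MIRNA: miRNA expression, METAB: metabolite
#' abundance, HIST: histone H3 modification, RPPA: reverse-phase protein
#' array protein quantification.
#'
#' @return Character vector of the eight omic type codes.
#' @export
omic_types <- function() {
  c("MUT", "CNV", "EXP", "PROT", "MIRNA", "METAB", "HIST", "RPPA")
}

#' Construct an omic matrix
#'
#' A cell-line-by-feature numeric matrix tagged with its omic data type.
#' Feature names are retained throughout the pipeline so that attribution
#' scores can be reported per named feature.
#'
#' @param values numeric matrix, rows = cell lines, columns = features.
#' @param omic_type one of [omic_types()].
#' @param cell_lines,feature_names optional identifier vectors; default to
#'   the dimnames of `values`.
#' @return An object of class `omic_matrix`.
#' @export
omic_matrix <- function(values, omic_type,
                        cell_lines = rownames(values),
                        feature_names = colnames(values)) {
  omic_type <- match.arg(omic_type, omic_types())
  values <- as.matrix(values)
  if (is.null(cell_lines) || is.null(feature_names)) {
    stop("omic_matrix: cell line and feature names are required", call. = FALSE)
  }
  cell_lines <- as.character(cell_lines)
  feature_names <- as.character(feature_names)
  if (nrow(values) != length(cell_lines) || ncol(values) != length(feature_names)) {
    stop("omic_matrix: dimensions do not match identifier lists", call. = FALSE)
  }
  if (anyDuplicated(cell_lines)) {
    stop("omic_matrix: duplicate cell line identifiers: ",
         paste(unique(cell_lines[duplicated(cell_lines)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(values)) stop("omic_matrix: values must be numeric", call. = FALSE)
  if (omic_type == "MUT") {
    ok <- is.na(values) | values == 0 | values == 1
    if (!all(ok)) {
      bad <- which(!ok, arr.ind = TRUE)[1L, ]
      stop(sprintf("MUT matrix must be binary; value %g at row '%s', column '%s'",
                   values[bad[1L], bad[2L]], cell_lines[bad[1L]],
                   feature_names[bad[2L]]), call. = FALSE)
    }
  }
  dimnames(values) <- list(cell_lines, feature_names)
  structure(list(omic_type = omic_type, cell_lines = cell_lines,
                 feature_names = feature_names, values = values),
            class = "omic_matrix")
}

#' @export
print.omic_matrix <- function(x, ...) {
  cat(sprintf("<omic_matrix %s: %d cell lines x %d features>\n",
              x$omic_type, length(x$cell_lines), length(x$feature_names)))
  invisible(x)
}

#' @export
dim.omic_matrix <- function(x) dim(x$values)

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0L) "\t" else ","
}

normalize_id <- function(x) toupper(trimws(x))

#' Load an omic matrix from delimited text
#'
#' Expects a header row of feature names and a first column of cell-line
#' identifiers.  In strict mode any missing cell is an error naming the
#' offending row and column; otherwise missing cells are imputed with the
#' column mean and the imputation count is reported via a message.
#'
#' @param path file path to a CSV/TSV file.
#' @param omic_type one of [omic_types()].
#' @param strict error on missing values (default TRUE).
#' @param delim field delimiter; sniffed from the header when NULL.
#' @param normalize_ids opt-in identifier normalization (trim + uppercase);
#'   matching elsewhere is exact and case-sensitive.
#' @return An [omic_matrix()].
#' @export
load_omic_matrix <- function(path, omic_type, strict = TRUE, delim = NULL,
                             normalize_ids = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(delim)) delim <- sniff_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("omic matrix needs >= 1 feature column", call. = FALSE)
  ids <- df[[1L]]
  if (normalize_ids) ids <- normalize_id(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate cell line rows: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  raw <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  bad_parse <- which(is.na(num) & !is.na(raw) & trimws(raw) != "" &
                       toupper(trimws(raw)) != "NA", arr.ind = TRUE)
  if (nrow(bad_parse)) {
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                 raw[bad_parse[1L, 1L], bad_parse[1L, 2L]],
                 ids[bad_parse[1L, 1L]],
                 colnames(df)[-1L][bad_parse[1L, 2L]]), call. = FALSE)
  }
  missing <- which(is.na(num), arr.ind = TRUE)
  if (nrow(missing)) {
    if (strict) {
      stop(sprintf("missing value at row '%s', column '%s' (strict mode)",
                   ids[missing[1L, 1L]], colnames(df)[-1L][missing[1L, 2L]]),
           call. = FALSE)
    }
    for (j in unique(missing[, 2L])) {
      mu <- mean(num[, j], na.rm = TRUE)
      num[is.na(num[, j]), j] <- mu
    }
    message(sprintf("imputed %d missing value(s) with column means", nrow(missing)))
  }
  omic_matrix(num, omic_type, cell_lines = ids,
              feature_names = colnames(df)[-1L])
}

#' Load a drug catalog
#'
#' Delimited text with columns `name`, `smiles`, and optionally `targeted`
#' (logical or 0/1) and `approved_lineages` (semicolon-separated lineage
#' strings; may be empty).  Every SMILES must parse to a valid molecule and
#' names must be unique.
#'
#' @inheritParams load_omic_matrix
#' @return A data frame with columns `name`, `smiles`, `targeted`
#'   (logical) and `approved_lineages` (list column of character vectors).
#' @export
load_drug_catalog <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(delim)) delim <- sniff_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  req <- c("name", "smiles")
  if (!all(req %in% names(df))) {
    stop("drug catalog needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$name)) {
    stop("duplicate drug names: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "),
         call. = FALSE)
  }
  for (s in df$smiles) validate_smiles(s)
  parse_flag <- function(x) {
    if (is.logical(x)) return(x)
    if (is.numeric(x)) return(x != 0)
    toupper(trimws(as.character(x))) %in% c("TRUE", "T", "1", "YES")
  }
  targeted <- if ("targeted" %in% names(df)) parse_flag(df$targeted)
              else rep(NA, nrow(df))
  lineages <- if ("approved_lineages" %in% names(df)) {
    lapply(strsplit(as.character(df$approved_lineages), ";", fixed = TRUE),
           function(x) x[nzchar(trimws(x))])
  } else rep(list(character(0)), nrow(df))
  out <- data.frame(name = as.character(df$name),
                    smiles = as.character(df$smiles),
                    targeted = targeted, stringsAsFactors = FALSE)
  out$approved_lineages <- lineages
  out
}

#' Load a drug-response table
#'
#' Delimited text with columns `cell_line`, `drug`, `aac` and `lineage`.
#' AAC is the area above the dose-response curve, a `[0,1]` efficacy summary
#' where higher values mean a stronger response.
#'
#' @inheritParams load_omic_matrix
#' @return A data frame of response records.
#' @export
load_response_table <- function(path, delim = NULL, normalize_ids = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(delim)) delim <- sniff_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  req <- c("cell_line", "drug", "aac", "lineage")
  if (!all(req %in% names(df))) {
    stop("response table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  df$aac <- as.numeric(df$aac)
  if (anyNA(df$aac) || any(df$aac < 0 | df$aac > 1)) {
    stop("aac values must lie in [0, 1]", call. = FALSE)
  }
  if (normalize_ids) df$cell_line <- normalize_id(df$cell_line)
  df[, req]
}

#' Fit a standardizer on training rows only
#'
#' Per-feature means and standard deviations are computed exclusively from
#' the supplied training rows so that no information from validation rows
#' leaks into the transformation.  Constant training columns are assigned
#' a standard deviation of 1 (the feature becomes a centered zero) rather
#' than being dropped, keeping feature indices aligned for attribution.
#'
#' @param matrix an [omic_matrix()].
#' @param train_rows integer or logical index of training rows, or a
#'   character vector of training cell-line identifiers.
#' @return An object of class `standardizer` with fields `mean`, `sd`,
#'   `feature_names`.
#' @export
fit_standardizer <- function(matrix, train_rows) {
  stopifnot(inherits(matrix, "omic_matrix"))
  if (is.character(train_rows)) {
    train_rows <- match(train_rows, matrix$cell_lines)
    if (anyNA(train_rows)) stop("unknown training cell lines", call. = FALSE)
  }
  sub <- matrix$values[train_rows, , drop = FALSE]
  if (nrow(sub) == 0L) stop("fit_standardizer: empty training rows", call. = FALSE)
  mu <- colMeans(sub)
  sd <- apply(sub, 2L, stats::sd)
  sd[is.na(sd) | sd == 0] <- 1
  structure(list(mean = mu, sd = sd, feature_names = matrix$feature_names),
            class = "standardizer")
}

#' Apply (or invert) a standardizer
#'
#' Applies `(x - mean) / sd` per feature, identically to training and
#' validation rows.
#'
#' @param matrix an [omic_matrix()].
#' @param stats a `standardizer` from [fit_standardizer()].
#' @return A standardized [omic_matrix()].
#' @export
apply_standardizer <- function(matrix, stats) {
  stopifnot(inherits(matrix, "omic_matrix"), inherits(stats, "standardizer"))
  if (!identical(matrix$feature_names, stats$feature_names)) {
    stop("standardizer feature names do not match the matrix", call. = FALSE)
  }
  v <- sweep(sweep(matrix$values, 2L, stats$mean, "-"), 2L, stats$sd, "/")
  out <- matrix
  out$values <- v
  # standardized MUT columns are no longer binary; bypass the constructor check
  structure(out, class = "omic_matrix")
}

#' @rdname apply_standardizer
#' @export
invert_standardizer <- function(matrix, stats) {
  stopifnot(inherits(matrix, "omic_matrix"), inherits(stats, "standardizer"))
  if (!identical(matrix$feature_names, stats$feature_names)) {
    stop("standardizer feature names do not match the matrix", call. = FALSE)
  }
  v <- sweep(sweep(matrix$values, 2L, stats$sd, "*"), 2L, stats$mean, "+")
  out <- matrix
  out$values <- v
  structure(out, class = "omic_matrix")
}

#' Write an omic matrix as CSV
#' @param matrix an [omic_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_omic_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "omic_matrix"))
  df <- data.frame(cell_line = matrix$cell_lines, matrix$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
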