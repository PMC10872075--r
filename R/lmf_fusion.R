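# Low-rank multimodal fusion.  Each modality latent h_m is augmented with a
# constant 1 and projected through per-modality factor matrices W_m of a
# rank-r decomposed fusion tensor; the fused vector is the sum over rank
# indices of the elementwise product of the per-modality projections:
#
#   fused = sum_{i=1..r}  prod_m  (hhat_m %*% W_m^{(i)})
#
# which equals the contraction of the outer product of the augmented latents
# with the rank-r reconstructed weight tensor.  The constant-1 augmentation
# makes additive (concatenation-then-linear) fusion a special case.

#' LMF configuration
#'
#' @param modality_dims named integer vector of latent dims per modality.
#' @param rank decomposition rank r >= 1 (default 4).
#' @param d_out fused output dimension (default 32).
#' @param seed RNG seed for factor initialization.
#' @return An `lmf_config` list.
#' @export
lmf_config <- function(modality_dims, rank = 4L, d_out = 32L, seed = 1L) {
  stopifnot(rank >= 1L, d_out >= 1L, length(modality_dims) >= 1L,
            all(modality_dims >= 1L))
  if (is.null(names(modality_dims))) {
    names(modality_dims) <- paste0("mod", seq_along(modality_dims))
  }
  structure(list(modality_dims = modality_dims, rank = as.integer(rank),
                 d_out = as.integer(d_out), seed = as.integer(seed)),
            class = "lmf_config")
}

#' Initialize LMF factor matrices
#'
#' One `(d_m + 1) x (rank * d_out)` matrix per modality, columns grouped by
#' rank index; entries drawn small and symmetric around zero.
#'
#' @param config an [lmf_config()].
#' @return Named list of factor matrices.
#' @export
lmf_init_factors <- function(config) {
  stopifnot(inherits(config, "lmf_config"))
  set.seed(config$seed)
  lapply(config$modality_dims, function(d) {
    matrix(stats::rnorm((d + 1L) * config$rank * config$d_out, sd = 0.2),
           d + 1L, config$rank * config$d_out)
  })
}

as_latent_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

check_latents <- function(latents, config) {
  if (!length(latents)) stop("empty modality list", call. = FALSE)
  if (length(latents) != length(config$modality_dims)) {
    stop("expected one latent per configured modality", call. = FALSE)
  }
  latents <- lapply(latents, as_latent_matrix)
  for (m in seq_along(latents)) {
    if (ncol(latents[[m]]) != config$modality_dims[[m]]) {
      stop(sprintf("modality %d: latent dim %d but configured dim %d",
                   m, ncol(latents[[m]]), config$modality_dims[[m]]),
           call. = FALSE)
    }
  }
  n <- unique(vapply(latents, nrow, integer(1)))
  if (length(n) != 1L) stop("latents disagree on sample count", call. = FALSE)
  latents
}

rank_sum_matrix <- function(rank, d_out) {
  do.call(rbind, replicate(rank, diag(d_out), simplify = FALSE))
}

#' Fuse modality latents by low-rank multimodal fusion
#'
#' @param latents list of per-modality latent vectors (or n-row matrices).
#' @param factors factor matrices from [lmf_init_factors()] (or trained).
#' @param config an [lmf_config()].
#' @return Fused vector of length `d_out` (or an n x d_out matrix).
#' @export
lmf_fuse <- function(latents, factors, config) {
  stopifnot(inherits(config, "lmf_config"))
  vec_in <- !is.matrix(latents[[1L]])
  latents <- check_latents(latents, config)
  stopifnot(length(factors) == length(latents))
  n <- nrow(latents[[1L]])
  P <- NULL
  for (m in seq_along(latents)) {
    hhat <- cbind(latents[[m]], rep(1, n))
    if (!identical(dim(factors[[m]]),
                   c(ncol(hhat), config$rank * config$d_out))) {
      stop("factor matrix shape mismatch for modality ", m, call. = FALSE)
    }
    proj <- hhat %*% factors[[m]]
    P <- if (is.null(P)) proj else P * proj
  }
  fused <- P %*% rank_sum_matrix(config$rank, config$d_out)
  if (vec_in) as.vector(fused) else fused
}

# Tape version used inside the trainable model: latents and factors are ad
# nodes; the rank-block summation is a matmul with a constant 0/1 matrix.
ad_lmf_fuse <- function(tape, latents, factors, config) {
  n <- nrow(ad_value(latents[[1L]]))
  ones <- ad_const(tape, matrix(1, n, 1L))
  P <- NULL
  for (m in seq_along(latents)) {
    hhat <- ad_cbind(latents[[m]], ones)
    proj <- ad_matmul(hhat, factors[[m]])
    P <- if (is.null(P)) proj else ad_mul(P, proj)
  }
  ad_matmul(P, ad_const(tape, rank_sum_matrix(config$rank, config$d_out)))
}

#' Concatenation fusion (ablation baseline)
#'
#' @param latents list of latent vectors or aligned n-row matrices.
#' @return Concatenated vector/matrix preserving modality order.
#' @export
concat_fuse <- function(latents) {
  if (!length(latents)) stop("empty modality list", call. = FALSE)
  vec_in <- !is.matrix(latents[[1L]])
  out <- do.call(cbind, lapply(latents, as_latent_matrix))
  if (vec_in) as.vector(out) else out
}

#' Elementwise-sum fusion (ablation baseline)
#'
#' @param latents list of equal-dimension latent vectors or matrices.
#' @return Elementwise sum.
#' @export
sum_fuse <- function(latents) {
  if (!length(latents)) stop("empty modality list", call. = FALSE)
  vec_in <- !is.matrix(latents[[1L]])
  mats <- lapply(latents, as_latent_matrix)
  dims <- vapply(mats, ncol, integer(1))
  if (length(unique(dims)) != 1L) {
    stop("sum_fuse requires equal latent dimensions", call. = FALSE)
  }
  out <- Reduce(`+`, mats)
  if (vec_in) as.vector(out) else out
}
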