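# Label Distribution Smoothing: per-sample training weights inversely
# proportional to the kernel-smoothed density of the AAC target.  Weights
# are applied as loss multipliers (not sampling probabilities), so training
# stays deterministic.

#' LDS configuration
#'
#' @param n_bins number of histogram bins over `[0, 1]` (default 100).
#' @param kernel smoothing kernel: "gaussian", "triangular", or "none".
#' @param kernel_size odd kernel width in bins (default 5).
#' @param kernel_sigma Gaussian kernel standard deviation in bins (default 2).
#' @param density_floor lower bound on the smoothed density used for the
#'   inverse weight, preventing unbounded weights in near-empty bins.
#' @param normalize_mean_to_one rescale weights to mean 1 so the weighted
#'   loss stays on the scale of the unweighted loss (default TRUE).
#' @return An `lds_config` list.
#' @export
lds_config <- function(n_bins = 100L, kernel = c("gaussian", "triangular", "none"),
                       kernel_size = 5L, kernel_sigma = 2,
                       density_floor = 1e-4, normalize_mean_to_one = TRUE) {
  kernel <- match.arg(kernel)
  stopifnot(n_bins >= 2L, kernel_size >= 1L, density_floor > 0)
  if (kernel_size %% 2L == 0L) stop("kernel_size must be odd", call. = FALSE)
  structure(list(n_bins = as.integer(n_bins), kernel = kernel,
                 kernel_size = as.integer(kernel_size),
                 kernel_sigma = kernel_sigma, density_floor = density_floor,
                 normalize_mean_to_one = normalize_mean_to_one),
            class = "lds_config")
}

lds_kernel <- function(config) {
  half <- (config$kernel_size - 1L) / 2L
  x <- seq(-half, half)
  k <- switch(config$kernel,
              none = { out <- numeric(length(x)); out[half + 1L] <- 1; out },
              gaussian = exp(-x^2 / (2 * config$kernel_sigma^2)),
              triangular = pmax(0, 1 - abs(x) / (half + 1)))
  k / sum(k)
}

#' Compute label-distribution-smoothing sample weights
#'
#' Histograms the targets over `n_bins` bins of `[0, 1]`, convolves the bin
#' counts with the kernel (mass falling outside the range is truncated and
#' the kernel renormalized per bin, avoiding boundary down-weighting), then
#' assigns each sample the inverse of its bin's smoothed density, floored
#' at `density_floor` and normalized to mean 1.
#'
#' @param aacs numeric vector of targets in `[0, 1]`.
#' @param config an [lds_config()].
#' @return Numeric weight vector aligned to `aacs` (all positive; mean 1
#'   when `normalize_mean_to_one`).
#' @export
compute_lds_weights <- function(aacs, config = lds_config()) {
  stopifnot(inherits(config, "lds_config"))
  if (!length(aacs)) stop("compute_lds_weights: empty target vector", call. = FALSE)
  if (anyNA(aacs) || any(aacs < 0 | aacs > 1)) {
    stop("targets must lie in [0, 1]", call. = FALSE)
  }
  nb <- config$n_bins
  bin <- pmin(nb, floor(aacs * nb) + 1L)   # value 1.0 falls in the last bin
  counts <- tabulate(bin, nbins = nb)
  dens <- counts / length(aacs)
  if (config$kernel != "none") {
    k <- lds_kernel(config)
    half <- (config$kernel_size - 1L) / 2L
    sm <- numeric(nb)
    for (b in seq_len(nb)) {
      lo <- max(1L, b - half); hi <- min(nb, b + half)
      kk <- k[(lo - b + half + 1L):(hi - b + half + 1L)]
      kk <- kk / sum(kk)                   # edge-truncated, renormalized
      sm[b] <- sum(kk * dens[lo:hi])
    }
    dens <- sm
  }
  d_i <- pmax(dens[bin], config$density_floor)
  w <- 1 / d_i
  if (config$normalize_mean_to_one) w <- w / mean(w)
  w
}
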