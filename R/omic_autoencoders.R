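# Per-omic-type autoencoders, pretrained by reconstruction on standardized
# profiles.  The encoder half supplies the omic latent to the fusion stage
# and is fine-tuned jointly with the response head by default (freezable).

#' Autoencoder specification
#'
#' Architecture: input -> hidden -> latent, mirrored decoder.  The default
#' hidden width is `max(64, 2 * latent_dim)`.
#'
#' @param omic_type one of [omic_types()].
#' @param input_dim number of input features.
#' @param latent_dim latent dimension (must not exceed `input_dim`).
#' @param hidden_dim hidden width; default `max(64, 2 * latent_dim)`.
#' @param activation "relu", "tanh", or "linear".
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param seed RNG seed for initialization (training is deterministic).
#' @return An `autoencoder_spec` list.
#' @export
autoencoder_spec <- function(omic_type, input_dim, latent_dim = 8L,
                             hidden_dim = max(64L, 2L * latent_dim),
                             activation = c("relu", "tanh", "linear"),
                             lr = 1e-3, epochs = 100L, seed = 1L) {
  omic_type <- match.arg(omic_type, omic_types())
  activation <- match.arg(activation)
  stopifnot(input_dim >= 1L, latent_dim >= 1L, hidden_dim >= 1L, epochs >= 1L)
  if (latent_dim > input_dim) {
    stop("latent_dim must not exceed input_dim", call. = FALSE)
  }
  structure(list(omic_type = omic_type, input_dim = as.integer(input_dim),
                 latent_dim = as.integer(latent_dim),
                 hidden_dim = as.integer(hidden_dim), activation = activation,
                 lr = lr, epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "autoencoder_spec")
}

ad_activation <- function(x, activation) {
  switch(activation, relu = ad_relu(x), tanh = ad_tanh(x), linear = x)
}

ae_init_params <- function(spec) {
  set.seed(spec$seed)
  list(W1 = init_weight(spec$input_dim, spec$hidden_dim),
       b1 = init_bias(spec$hidden_dim),
       W2 = init_weight(spec$hidden_dim, spec$latent_dim),
       b2 = init_bias(spec$latent_dim),
       W3 = init_weight(spec$latent_dim, spec$hidden_dim),
       b3 = init_bias(spec$hidden_dim),
       W4 = init_weight(spec$hidden_dim, spec$input_dim),
       b4 = init_bias(spec$input_dim))
}

ae_encode_tape <- function(x, P, activation) {
  ad_dense(ad_activation(ad_dense(x, P$W1, P$b1), activation), P$W2, P$b2)
}

ae_decode_tape <- function(z, P, activation) {
  ad_dense(ad_activation(ad_dense(z, P$W3, P$b3), activation), P$W4, P$b4)
}

#' Pretrain an autoencoder by reconstruction
#'
#' Full-batch Adam on the mean-squared reconstruction error; the per-epoch
#' loss history is recorded.  Deterministic given the spec's seed.
#'
#' @param matrix a standardized [omic_matrix()] (or plain numeric matrix).
#' @param spec an [autoencoder_spec()].
#' @return An object of class `autoencoder` with `params`, `spec`,
#'   `loss_history`.
#' @export
pretrain_autoencoder <- function(matrix, spec) {
  stopifnot(inherits(spec, "autoencoder_spec"))
  X <- if (inherits(matrix, "omic_matrix")) matrix$values else as.matrix(matrix)
  if (ncol(X) != spec$input_dim) {
    stop("matrix has ", ncol(X), " features but spec expects ", spec$input_dim,
         call. = FALSE)
  }
  params <- ae_init_params(spec)
  st <- adam_state()
  history <- numeric(spec$epochs)
  for (epoch in seq_len(spec$epochs)) {
    tape <- ad_tape()
    P <- ad_lift_params(tape, params)
    xn <- ad_const(tape, X)
    xhat <- ae_decode_tape(ae_encode_tape(xn, P, spec$activation), P,
                           spec$activation)
    loss <- ad_mean(ad_square(ad_sub(xhat, xn)))
    lv <- ad_value(loss)[1L]
    if (!is.finite(lv)) {
      stop("autoencoder training diverged (non-finite loss) at epoch ", epoch,
           call. = FALSE)
    }
    history[epoch] <- lv
    gf <- ad_backward(loss)
    params <- adam_step(params, ad_param_grads(gf, P), st, lr = spec$lr)
  }
  structure(list(spec = spec, params = params, loss_history = history),
            class = "autoencoder")
}

#' @export
print.autoencoder <- function(x, ...) {
  cat(sprintf("<autoencoder %s: %d -> %d -> %d, final MSE %.4g>\n",
              x$spec$omic_type, x$spec$input_dim, x$spec$hidden_dim,
              x$spec$latent_dim, utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Encode rows into omic latents
#'
#' Deterministic and batch-size independent (a single matrix product).
#'
#' @param ae a trained `autoencoder`.
#' @param values numeric matrix of rows to encode (same feature layout as
#'   the training matrix) or an [omic_matrix()].
#' @return Numeric latent matrix, one row per input row.
#' @export
encode_omic <- function(ae, values) {
  stopifnot(inherits(ae, "autoencoder"))
  X <- if (inherits(values, "omic_matrix")) values$values else as.matrix(values)
  if (ncol(X) != ae$spec$input_dim) {
    stop("feature count mismatch: got ", ncol(X), ", expected ",
         ae$spec$input_dim, call. = FALSE)
  }
  tape <- ad_tape()
  P <- lapply(ae$params, function(p) ad_const(tape, p))
  ad_value(ae_encode_tape(ad_const(tape, X), P, ae$spec$activation))
}

#' Reconstruct rows through the autoencoder
#'
#' @param ae a trained `autoencoder`.
#' @param values rows to reconstruct.
#' @return Reconstruction matrix.
#' @export
reconstruct_omic <- function(ae, values) {
  stopifnot(inherits(ae, "autoencoder"))
  X <- if (inherits(values, "omic_matrix")) values$values else as.matrix(values)
  tape <- ad_tape()
  P <- lapply(ae$params, function(p) ad_const(tape, p))
  ad_value(ae_decode_tape(ae_encode_tape(ad_const(tape, X), P,
                                         ae$spec$activation),
                          P, ae$spec$activation))
}
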