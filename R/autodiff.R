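# Reverse-mode automatic differentiation on dense matrices.
#
# A tape records every operation in topological order; ad_backward() walks it
# once in reverse, accumulating gradients.  All neural components of the
# package (omic autoencoders, the graph attention drug encoder, low-rank
# fusion, the regression head) express their forward pass through these
# primitives, so parameter gradients for training and input gradients for
# integrated gradients come from the same machinery.

#' Create a fresh autodiff tape
#'
#' @return An environment holding the recorded computation graph.
#' @keywords internal
ad_tape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  tape
}

ad_record <- function(tape, value, parents = integer(0), backward = NULL,
                      requires_grad = FALSE) {
  if (!is.matrix(value)) value <- matrix(value, nrow = 1L)
  if (anyNA(value) || any(!is.finite(value))) {
    stop("non-finite value encountered on the autodiff tape", call. = FALSE)
  }
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  rg <- requires_grad
  if (!rg && length(parents)) {
    for (p in parents) if (tape$nodes[[p]]$requires_grad) { rg <- TRUE; break }
  }
  tape$nodes[[n]] <- list(value = value, parents = parents,
                          backward = backward, requires_grad = rg)
  tape$n <- n
  structure(list(tape = tape, id = n), class = "ad")
}

#' @keywords internal
ad_input <- function(tape, value) ad_record(tape, value, requires_grad = TRUE)

#' @keywords internal
ad_const <- function(tape, value) ad_record(tape, value, requires_grad = FALSE)

#' @keywords internal
ad_value <- function(x) x$tape$nodes[[x$id]]$value

stopifnot_ad <- function(...) {
  for (x in list(...)) {
    if (!inherits(x, "ad")) stop("expected an 'ad' tape node", call. = FALSE)
  }
}

# -- elementwise binary ops ---------------------------------------------------

ad_add <- function(a, b) {
  stopifnot_ad(a, b)
  va <- ad_value(a); vb <- ad_value(b)
  if (identical(dim(va), dim(vb))) {
    ad_record(a$tape, va + vb, c(a$id, b$id),
              function(g) list(g, g))
  } else if (nrow(vb) == 1L && ncol(vb) == ncol(va)) {
    # row-vector broadcast (bias addition)
    ad_record(a$tape, sweep(va, 2L, vb, "+"), c(a$id, b$id),
              function(g) list(g, matrix(colSums(g), nrow = 1L)))
  } else {
    stop("ad_add: incompatible shapes", call. = FALSE)
  }
}

ad_sub <- function(a, b) {
  stopifnot_ad(a, b)
  va <- ad_value(a); vb <- ad_value(b)
  if (!identical(dim(va), dim(vb))) stop("ad_sub: incompatible shapes", call. = FALSE)
  ad_record(a$tape, va - vb, c(a$id, b$id), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  stopifnot_ad(a, b)
  va <- ad_value(a); vb <- ad_value(b)
  if (identical(dim(va), dim(vb))) {
    ad_record(a$tape, va * vb, c(a$id, b$id),
              function(g) list(g * vb, g * va))
  } else if (ncol(vb) == 1L && nrow(vb) == nrow(va)) {
    # column-vector broadcast (per-row scaling, e.g. attention weights)
    ad_record(a$tape, va * as.vector(vb), c(a$id, b$id),
              function(g) list(g * as.vector(vb),
                               matrix(rowSums(g * va), ncol = 1L)))
  } else {
    stop("ad_mul: incompatible shapes", call. = FALSE)
  }
}

ad_div <- function(a, b) {
  stopifnot_ad(a, b)
  va <- ad_value(a); vb <- ad_value(b)
  if (identical(dim(va), dim(vb))) {
    ad_record(a$tape, va / vb, c(a$id, b$id),
              function(g) list(g / vb, -g * va / (vb * vb)))
  } else if (ncol(vb) == 1L && nrow(vb) == nrow(va)) {
    v <- as.vector(vb)
    ad_record(a$tape, va / v, c(a$id, b$id),
              function(g) list(g / v,
                               matrix(rowSums(-g * va / (v * v)), ncol = 1L)))
  } else {
    stop("ad_div: incompatible shapes", call. = FALSE)
  }
}

ad_matmul <- function(a, b) {
  stopifnot_ad(a, b)
  va <- ad_value(a); vb <- ad_value(b)
  ad_record(a$tape, va %*% vb, c(a$id, b$id),
            function(g) list(g %*% t(vb), crossprod(va, g)))
}

# -- constant-argument helpers ------------------------------------------------

ad_scale <- function(a, k) {
  stopifnot_ad(a)
  ad_record(a$tape, ad_value(a) * k, a$id, function(g) list(g * k))
}

ad_shift <- function(a, k) {
  stopifnot_ad(a)
  ad_record(a$tape, ad_value(a) + k, a$id, function(g) list(g))
}

# -- unary ops ----------------------------------------------------------------

ad_tanh <- function(a) {
  v <- tanh(ad_value(a))
  ad_record(a$tape, v, a$id, function(g) list(g * (1 - v * v)))
}

ad_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-ad_value(a)))
  ad_record(a$tape, v, a$id, function(g) list(g * v * (1 - v)))
}

ad_relu <- function(a) {
  va <- ad_value(a)
  m <- va > 0
  ad_record(a$tape, va * m, a$id, function(g) list(g * m))
}

ad_leaky_relu <- function(a, alpha = 0.1) {
  va <- ad_value(a)
  m <- ifelse(va > 0, 1, alpha)
  ad_record(a$tape, va * m, a$id, function(g) list(g * m))
}

ad_exp <- function(a) {
  v <- exp(ad_value(a))
  ad_record(a$tape, v, a$id, function(g) list(g * v))
}

ad_square <- function(a) {
  va <- ad_value(a)
  ad_record(a$tape, va * va, a$id, function(g) list(2 * g * va))
}

ad_sqrt <- function(a) {
  v <- sqrt(ad_value(a))
  ad_record(a$tape, v, a$id, function(g) list(g / (2 * v)))
}

ad_sum <- function(a) {
  va <- ad_value(a)
  ad_record(a$tape, matrix(sum(va)), a$id,
            function(g) list(matrix(as.numeric(g), nrow(va), ncol(va))))
}

ad_mean <- function(a) ad_scale(ad_sum(a), 1 / length(ad_value(a)))

# -- structural ops -----------------------------------------------------------

ad_gather <- function(a, idx) {
  stopifnot_ad(a)
  va <- ad_value(a)
  ad_record(a$tape, va[idx, , drop = FALSE], a$id, function(g) {
    out <- matrix(0, nrow(va), ncol(va))
    # accumulate for repeated indices
    agg <- rowsum(g, group = idx)
    out[as.integer(rownames(agg)), ] <- agg
    list(out)
  })
}

ad_scatter_sum <- function(a, groups, n_groups) {
  stopifnot_ad(a)
  va <- ad_value(a)
  out <- matrix(0, n_groups, ncol(va))
  agg <- rowsum(va, group = groups)
  out[as.integer(rownames(agg)), ] <- agg
  ad_record(a$tape, out, a$id, function(g) list(g[groups, , drop = FALSE]))
}

ad_cbind <- function(...) {
  args <- list(...)
  stopifnot(length(args) >= 1L)
  for (x in args) stopifnot_ad(x)
  vals <- lapply(args, ad_value)
  ncols <- vapply(vals, ncol, integer(1))
  ends <- cumsum(ncols)
  starts <- ends - ncols + 1L
  ad_record(args[[1L]]$tape, do.call(cbind, vals),
            vapply(args, function(x) x$id, integer(1)),
            function(g) {
              lapply(seq_along(args), function(i) {
                g[, starts[i]:ends[i], drop = FALSE]
              })
            })
}

# Softmax of a single-column score within segments given by `groups`,
# numerically stabilized by a detached per-segment max.
ad_segment_softmax <- function(scores, groups, n_groups) {
  stopifnot_ad(scores)
  v <- ad_value(scores)
  stopifnot(ncol(v) == 1L)
  mx <- tapply(as.vector(v), groups, max)
  shift <- as.numeric(mx[as.character(groups)])
  e <- ad_exp(ad_shift(scores, -shift))
  tot <- ad_scatter_sum(e, groups, n_groups)
  ad_div(e, ad_gather(tot, groups))
}

# -- backward pass ------------------------------------------------------------

#' Backpropagate from a scalar tape node
#'
#' @param root an `ad` node holding a 1x1 value (typically a loss).
#' @return A function mapping an `ad` node to its gradient matrix (or NULL if
#'   the node does not require gradients).
#' @keywords internal
ad_backward <- function(root) {
  stopifnot_ad(root)
  tape <- root$tape
  rv <- ad_value(root)
  if (length(rv) != 1L) stop("ad_backward: root must be scalar", call. = FALSE)
  grads <- vector("list", tape$n)
  grads[[root$id]] <- matrix(1)
  for (id in seq(root$id, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- tape$nodes[[id]]
    if (is.null(node$backward) || !length(node$parents)) next
    pg <- node$backward(g)
    for (k in seq_along(node$parents)) {
      p <- node$parents[k]
      if (!tape$nodes[[p]]$requires_grad) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  function(x) {
    stopifnot_ad(x)
    grads[[x$id]]
  }
}

# -- parameter containers and optimizer --------------------------------------

# Glorot-uniform initialization; all randomness uses the current RNG stream.
init_weight <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

init_bias <- function(n_out) matrix(0, 1L, n_out)

#' Adam optimizer state
#' @keywords internal
adam_state <- function() {
  st <- new.env(parent = emptyenv())
  st$m <- list(); st$v <- list(); st$t <- 0L
  st
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- 0 * params[[nm]]
      state$v[[nm]] <- 0 * params[[nm]]
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    step <- mhat / (sqrt(vhat) + eps)
    # decoupled weight decay; biases (single-row params) are not decayed
    if (weight_decay > 0 && nrow(params[[nm]]) > 1L) {
      step <- step + weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - lr * step
  }
  params
}

# Dense layer on the tape: x %*% W + b, with params given as ad nodes.
ad_dense <- function(x, W, b) ad_add(ad_matmul(x, W), b)

# Lift a named list of parameter matrices onto a tape as gradient-tracked
# nodes; returns list of ad nodes with the same names.
ad_lift_params <- function(tape, params) {
  lapply(params, function(p) ad_input(tape, p))
}

# Collect gradients for a lifted parameter list after ad_backward().
ad_param_grads <- function(grad_fn, lifted) {
  lapply(lifted, grad_fn)
}
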