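# Graph-attention drug encoder.
#
# Architecture: K atom-level message-passing rounds in which each atom
# attends over its neighbors (attention logits from the concatenated target
# state, source state, and bond features) and updates its state through a
# GRU; then T molecule-level rounds in which a virtual super-node attends
# over the molecule's atoms with the same gated update.  The final
# super-node state is the drug latent.  Deterministic given parameters.

#' Initialize graph encoder parameters
#'
#' @param d_hidden hidden/latent width (default 32).
#' @param n_atom_rounds number of atom-level attention rounds K (default 2).
#' @param n_mol_rounds number of molecule-level rounds T (default 2).
#' @param seed RNG seed for initialization.
#' @return Named list of parameter matrices (class `afp_params`).
#' @export
afp_params <- function(d_hidden = 32L, n_atom_rounds = 2L, n_mol_rounds = 2L,
                       seed = 1L) {
  fn <- graph_feature_names()
  d_atom <- length(fn$atom)
  d_bond <- length(fn$bond)
  set.seed(seed)
  p <- list(init_W = init_weight(d_atom, d_hidden), init_b = init_bias(d_hidden))
  gru <- function(prefix) {
    out <- list()
    for (gate in c("z", "r", "n")) {
      out[[paste0(prefix, "_W", gate)]] <- init_weight(d_hidden, d_hidden)
      out[[paste0(prefix, "_U", gate)]] <- init_weight(d_hidden, d_hidden)
      out[[paste0(prefix, "_b", gate)]] <- init_bias(d_hidden)
    }
    out
  }
  for (k in seq_len(n_atom_rounds)) {
    p[[paste0("att_W", k)]] <- init_weight(2L * d_hidden + d_bond, 1L)
    p[[paste0("att_b", k)]] <- init_bias(1L)
    p[[paste0("msg_W", k)]] <- init_weight(d_hidden + d_bond, d_hidden)
    p[[paste0("msg_b", k)]] <- init_bias(d_hidden)
    p <- c(p, gru(paste0("agru", k)))
  }
  for (t in seq_len(n_mol_rounds)) {
    p[[paste0("matt_W", t)]] <- init_weight(2L * d_hidden, 1L)
    p[[paste0("matt_b", t)]] <- init_bias(1L)
    p[[paste0("mmsg_W", t)]] <- init_weight(d_hidden, d_hidden)
    p[[paste0("mmsg_b", t)]] <- init_bias(d_hidden)
    p <- c(p, gru(paste0("mgru", t)))
  }
  structure(p, class = "afp_params", d_hidden = d_hidden,
            n_atom_rounds = n_atom_rounds, n_mol_rounds = n_mol_rounds)
}

ad_gru <- function(x, h, P, prefix) {
  gate <- function(g, act) {
    act(ad_add(ad_add(ad_matmul(x, P[[paste0(prefix, "_W", g)]]),
                      ad_matmul(h, P[[paste0(prefix, "_U", g)]])),
               P[[paste0(prefix, "_b", g)]]))
  }
  z <- gate("z", ad_sigmoid)
  r <- gate("r", ad_sigmoid)
  n <- ad_tanh(ad_add(ad_add(ad_matmul(x, P[[paste0(prefix, "_Wn")]]),
                             ad_matmul(ad_mul(r, h), P[[paste0(prefix, "_Un")]])),
                      P[[paste0(prefix, "_bn")]]))
  ad_add(h, ad_mul(z, ad_sub(n, h)))
}

#' Combine molecular graphs into one disjoint batch
#'
#' Bonds are expanded to directed edges in both orientations; atoms with no
#' neighbors receive a self-edge with zero bond features so that the
#' attention update is defined for single-atom molecules.
#'
#' @param graphs list of `molecular_graph` objects.
#' @return A list with stacked atom features, directed edge index, stacked
#'   bond features and molecule membership.
#' @export
batch_graphs <- function(graphs) {
  if (inherits(graphs, "molecular_graph")) graphs <- list(graphs)
  stopifnot(length(graphs) >= 1L)
  offs <- 0L
  A <- list(); src <- list(); dst <- list(); BF <- list(); mol_id <- list()
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    stopifnot(inherits(g, "molecular_graph"))
    if (g$n_atoms == 0L) stop("empty molecular graph", call. = FALSE)
    A[[gi]] <- g$atom_features
    mol_id[[gi]] <- rep(gi, g$n_atoms)
    if (nrow(g$bonds)) {
      src[[gi]] <- offs + c(g$bonds$i, g$bonds$j)
      dst[[gi]] <- offs + c(g$bonds$j, g$bonds$i)
      BF[[gi]] <- rbind(g$bond_features, g$bond_features)
    }
    deg <- tabulate(c(g$bonds$i, g$bonds$j), nbins = g$n_atoms)
    iso <- which(deg == 0L)
    if (length(iso)) {
      src[[length(src) + 1L]] <- offs + iso
      dst[[length(dst) + 1L]] <- offs + iso
      BF[[length(BF) + 1L]] <- matrix(0, length(iso), ncol(g$bond_features),
                                      dimnames = list(NULL, colnames(g$bond_features)))
    }
    offs <- offs + g$n_atoms
  }
  list(atom_features = do.call(rbind, A),
       src = unlist(src), dst = unlist(dst),
       bond_features = do.call(rbind, BF),
       mol_id = unlist(mol_id),
       n_atoms = offs, n_mols = length(graphs))
}

# Forward pass on an existing tape.  P is a list of lifted (ad) parameters;
# atom_input optionally overrides the constant atom feature node so that
# gradients with respect to atom features can be taken (attribution).
afp_forward <- function(tape, P, batch, params_meta, atom_input = NULL) {
  K <- attr(params_meta, "n_atom_rounds")
  Tm <- attr(params_meta, "n_mol_rounds")
  x <- if (is.null(atom_input)) ad_const(tape, batch$atom_features) else atom_input
  bf <- ad_const(tape, batch$bond_features)
  h <- ad_relu(ad_dense(x, P$init_W, P$init_b))
  for (k in seq_len(K)) {
    hv <- ad_gather(h, batch$dst)
    hu <- ad_gather(h, batch$src)
    score <- ad_leaky_relu(ad_dense(ad_cbind(hv, hu, bf),
                                    P[[paste0("att_W", k)]],
                                    P[[paste0("att_b", k)]]))
    alpha <- ad_segment_softmax(score, batch$dst, batch$n_atoms)
    msg <- ad_leaky_relu(ad_dense(ad_cbind(hu, bf),
                                  P[[paste0("msg_W", k)]],
                                  P[[paste0("msg_b", k)]]))
    ctx <- ad_scatter_sum(ad_mul(msg, alpha), batch$dst, batch$n_atoms)
    h <- ad_gru(ctx, h, P, paste0("agru", k))
  }
  counts <- tabulate(batch$mol_id, nbins = batch$n_mols)
  s <- ad_mul(ad_scatter_sum(h, batch$mol_id, batch$n_mols),
              ad_const(tape, matrix(1 / counts, ncol = 1L)))
  for (t in seq_len(Tm)) {
    satom <- ad_gather(s, batch$mol_id)
    score <- ad_leaky_relu(ad_dense(ad_cbind(satom, h),
                                    P[[paste0("matt_W", t)]],
                                    P[[paste0("matt_b", t)]]))
    alpha <- ad_segment_softmax(score, batch$mol_id, batch$n_mols)
    msg <- ad_leaky_relu(ad_dense(h, P[[paste0("mmsg_W", t)]],
                                  P[[paste0("mmsg_b", t)]]))
    ctx <- ad_scatter_sum(ad_mul(msg, alpha), batch$mol_id, batch$n_mols)
    s <- ad_gru(ctx, s, P, paste0("mgru", t))
  }
  list(latent = s, atom_states = h, atom_input = x)
}

#' Encode molecules into drug latents
#'
#' @param graphs a `molecular_graph` or list of them.
#' @param params encoder parameters from [afp_params()].
#' @return Numeric matrix, one latent row per molecule.
#' @export
attentivefp_encode <- function(graphs, params) {
  stopifnot(inherits(params, "afp_params"))
  batch <- batch_graphs(graphs)
  tape <- ad_tape()
  P <- lapply(params, function(p) ad_const(tape, p))
  out <- afp_forward(tape, P, batch, params)
  ad_value(out$latent)
}
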