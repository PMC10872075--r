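# Trainable drug-response model: pretrained omic encoders + drug encoder
# (graph attention network or ECFP projection) + fusion (LMF, concatenation
# or summation) + regression head, trained end-to-end with a weighted RMSE
# loss.  Includes the elastic-net linear baseline and a reduced-scale random
# hyperparameter search.

#' Model configuration
#'
#' Two named presets reproduce the ablation endpoints: `"base"` uses ECFP
#' drug fingerprints, concatenation fusion and no label-distribution
#' smoothing; `"refined"` uses the graph drug encoder, low-rank multimodal
#' fusion and LDS weighting.
#'
#' @param omic_types character vector of omic types to use (>= 1).
#' @param drug_encoder `"gnn"` (graph attention) or `"ecfp"` (fingerprint).
#' @param fusion `"lmf"`, `"concat"`, or `"sum"`.
#' @param use_lds weight the training loss by label-distribution-smoothing
#'   weights computed from training-split targets only.
#' @param d_omic_latent omic latent dimension per modality.
#' @param d_drug_latent drug latent dimension.
#' @param lmf_rank,d_fused LMF rank and fused dimension (LMF fusion only).
#' @param head_hidden hidden width of the regression head.
#' @param ecfp_bits,ecfp_radius fingerprint settings (ECFP encoder only).
#' @param lr Adam learning rate.
#' @param weight_decay decoupled L2 weight decay applied to weight matrices
#'   (not biases).
#' @param epochs maximum training epochs (full-batch).
#' @param patience early-stopping patience on validation loss.
#' @param ae_epochs autoencoder pretraining epochs.
#' @param ae_activation autoencoder/encoder activation.
#' @param freeze_encoders if TRUE the pretrained encoders are not fine-tuned.
#' @param lds an [lds_config()].
#' @param seed seed controlling initialization (training is deterministic).
#' @return A `model_config` list.
#' @export
model_config <- function(omic_types, drug_encoder = c("gnn", "ecfp"),
                         fusion = c("lmf", "concat", "sum"), use_lds = TRUE,
                         d_omic_latent = 8L, d_drug_latent = 16L,
                         lmf_rank = 4L, d_fused = 32L, head_hidden = 16L,
                         ecfp_bits = 256L, ecfp_radius = 2L,
                         lr = 1e-3, weight_decay = 1e-4,
                         epochs = 200L, patience = 10L,
                         ae_epochs = 60L,
                         ae_activation = c("relu", "tanh", "linear"),
                         freeze_encoders = FALSE, lds = lds_config(),
                         seed = 1L) {
  drug_encoder <- match.arg(drug_encoder)
  fusion <- match.arg(fusion)
  ae_activation <- match.arg(ae_activation)
  stopifnot(length(omic_types) >= 1L, all(omic_types %in% omic_types()),
            epochs >= 1L, patience >= 1L)
  if (fusion == "sum" && d_omic_latent != d_drug_latent) {
    stop("sum fusion requires equal omic and drug latent dimensions",
         call. = FALSE)
  }
  structure(list(omic_types = omic_types, drug_encoder = drug_encoder,
                 fusion = fusion, use_lds = use_lds,
                 d_omic_latent = as.integer(d_omic_latent),
                 d_drug_latent = as.integer(d_drug_latent),
                 lmf_rank = as.integer(lmf_rank), d_fused = as.integer(d_fused),
                 head_hidden = as.integer(head_hidden),
                 ecfp_bits = as.integer(ecfp_bits),
                 ecfp_radius = as.integer(ecfp_radius),
                 lr = lr, weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 ae_epochs = as.integer(ae_epochs),
                 ae_activation = ae_activation,
                 freeze_encoders = freeze_encoders, lds = lds,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' @rdname model_config
#' @param preset `"base"` or `"refined"`.
#' @param ... overrides passed to [model_config()].
#' @export
model_config_preset <- function(preset = c("refined", "base"), omic_types, ...) {
  preset <- match.arg(preset)
  args <- if (preset == "base") {
    list(drug_encoder = "ecfp", fusion = "concat", use_lds = FALSE)
  } else {
    list(drug_encoder = "gnn", fusion = "lmf", use_lds = TRUE)
  }
  do.call(model_config, utils::modifyList(c(list(omic_types = omic_types), args),
                                          list(...)))
}

#' Weighted root-mean-squared-error loss
#'
#' `sqrt(sum(w * (y - yhat)^2) / sum(w))`; invariant to rescaling all
#' weights, and equal to plain RMSE for unit weights.
#'
#' @param preds,targets numeric vectors of equal length.
#' @param weights positive sample weights (default unit).
#' @return Scalar loss.
#' @export
weighted_rmse <- function(preds, targets, weights = rep(1, length(targets))) {
  n <- length(targets)
  if (n == 0L) stop("weighted_rmse: empty batch", call. = FALSE)
  stopifnot(length(preds) == n, length(weights) == n, all(weights > 0))
  sqrt(sum(weights * (targets - preds)^2) / sum(weights))
}

fused_dim <- function(config) {
  switch(config$fusion,
         lmf = config$d_fused,
         concat = length(config$omic_types) * config$d_omic_latent +
           config$d_drug_latent,
         sum = config$d_omic_latent)
}

# Assemble shared model data: standardized matrices over the common cell
# line panel, drug representations, and record index maps.
build_model_data <- function(omics, catalog, config, standardizers) {
  used <- config$omic_types
  missing <- setdiff(used, names(omics))
  if (length(missing)) {
    stop("omic matrices missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  panel <- Reduce(intersect, lapply(omics[used], function(m) m$cell_lines))
  if (!length(panel)) stop("no cell line is present in every used omic matrix",
                           call. = FALSE)
  X <- lapply(used, function(ot) {
    std <- apply_standardizer(omics[[ot]], standardizers[[ot]])
    std$values[match(panel, std$cell_lines), , drop = FALSE]
  })
  names(X) <- used
  data <- list(X = X, panel = panel, used = used, drugs = catalog$name,
               smiles = catalog$smiles)
  if (config$drug_encoder == "gnn") {
    data$graphs <- lapply(catalog$smiles, featurize_smiles)
    data$batch <- batch_graphs(data$graphs)
  } else {
    fp <- t(vapply(catalog$smiles,
                   function(s) ecfp(s, config$ecfp_radius, config$ecfp_bits),
                   integer(config$ecfp_bits)))
    rownames(fp) <- catalog$name
    data$fp <- fp
  }
  data
}

record_rows <- function(records, data) {
  cl_row <- match(records$cell_line, data$panel)
  drug_row <- match(records$drug, data$drugs)
  if (anyNA(cl_row) || anyNA(drug_row)) {
    stop("records reference cell lines or drugs outside the model data",
         call. = FALSE)
  }
  list(cl_row = cl_row, drug_row = drug_row)
}

init_model_params <- function(config, data, aes) {
  params <- list()
  for (ot in data$used) {
    ap <- aes[[ot]]$params
    params[[paste0("enc_", ot, "_W1")]] <- ap$W1
    params[[paste0("enc_", ot, "_b1")]] <- ap$b1
    params[[paste0("enc_", ot, "_W2")]] <- ap$W2
    params[[paste0("enc_", ot, "_b2")]] <- ap$b2
  }
  set.seed(config$seed + 1000L)
  if (config$drug_encoder == "gnn") {
    afp <- afp_params(d_hidden = config$d_drug_latent, seed = config$seed + 2000L)
    for (nm in names(afp)) params[[paste0("afp_", nm)]] <- afp[[nm]]
    attr(params, "afp_meta") <- afp
  } else {
    set.seed(config$seed + 2000L)
    params$fp_W <- init_weight(config$ecfp_bits, config$d_drug_latent)
    params$fp_b <- init_bias(config$d_drug_latent)
  }
  if (config$fusion == "lmf") {
    dims <- c(stats::setNames(rep(config$d_omic_latent, length(data$used)),
                              data$used),
              drug = config$d_drug_latent)
    lmf_cfg <- lmf_config(dims, rank = config$lmf_rank,
                          d_out = config$d_fused, seed = config$seed + 3000L)
    factors <- lmf_init_factors(lmf_cfg)
    for (nm in names(factors)) params[[paste0("lmf_", nm)]] <- factors[[nm]]
    attr(params, "lmf_cfg") <- lmf_cfg
  }
  set.seed(config$seed + 4000L)
  d_in <- fused_dim(config)
  params$head_W1 <- init_weight(d_in, config$head_hidden)
  params$head_b1 <- init_bias(config$head_hidden)
  params$head_W2 <- init_weight(config$head_hidden, 1L)
  params$head_b2 <- init_bias(1L)
  params
}

# Forward pass for a set of records.  `P` is a named list of ad nodes (one
# per parameter); overrides allow attribution to inject gradient-tracked
# input nodes for one omic matrix or the drug atom features.
drp_forward <- function(tape, P, data, rows, config, meta,
                        omic_overrides = NULL, atom_override = NULL,
                        fp_override = NULL, batch = NULL) {
  lat <- list()
  for (ot in data$used) {
    xn <- if (!is.null(omic_overrides[[ot]])) omic_overrides[[ot]]
          else ad_const(tape, data$X[[ot]])
    encP <- list(W1 = P[[paste0("enc_", ot, "_W1")]],
                 b1 = P[[paste0("enc_", ot, "_b1")]],
                 W2 = P[[paste0("enc_", ot, "_W2")]],
                 b2 = P[[paste0("enc_", ot, "_b2")]])
    Z <- ae_encode_tape(xn, encP, config$ae_activation)
    lat[[ot]] <- ad_gather(Z, rows$cl_row)
  }
  if (config$drug_encoder == "gnn") {
    afp_P <- P[startsWith(names(P), "afp_")]
    names(afp_P) <- sub("^afp_", "", names(afp_P))
    b <- if (is.null(batch)) data$batch else batch
    enc <- afp_forward(tape, afp_P, b, meta$afp_meta, atom_input = atom_override)
    D <- enc$latent
    atom_node <- enc$atom_input
  } else {
    fpn <- if (is.null(fp_override)) ad_const(tape, data$fp) else fp_override
    D <- ad_relu(ad_dense(fpn, P$fp_W, P$fp_b))
    atom_node <- NULL
  }
  lat$drug <- ad_gather(D, rows$drug_row)
  fused <- switch(config$fusion,
                  lmf = {
                    factors <- lapply(names(meta$lmf_cfg$modality_dims),
                                      function(nm) P[[paste0("lmf_", nm)]])
                    ad_lmf_fuse(tape, lat, factors, meta$lmf_cfg)
                  },
                  concat = do.call(ad_cbind, lat),
                  sum = Reduce(ad_add, lat))
  h <- ad_relu(ad_dense(fused, P$head_W1, P$head_b1))
  pred <- ad_dense(h, P$head_W2, P$head_b2)
  list(pred = pred, latents = lat, atom_input = atom_node)
}

ad_weighted_rmse <- function(tape, pred, y, w) {
  e <- ad_sub(pred, ad_const(tape, matrix(y, ncol = 1L)))
  wn <- ad_const(tape, matrix(w, ncol = 1L))
  ad_sqrt(ad_scale(ad_sum(ad_mul(wn, ad_square(e))), 1 / sum(w)))
}

#' Train the response model on one cross-validation fold
#'
#' Standardizers are fitted on the fold's training cell lines only and LDS
#' weights (when enabled) come from training-split targets only, so no
#' validation information reaches the trained weights.  Autoencoders are
#' pretrained by reconstruction on all cell lines of the panel (labels are
#' never seen) and then fine-tuned jointly unless `freeze_encoders`.
#' Training is full-batch Adam with early stopping on the validation RMSE.
#'
#' @param records response record data frame.
#' @param fold a `fold_assignment` from [split_records()].
#' @param omics named list of [omic_matrix()] objects.
#' @param catalog drug catalog data frame.
#' @param config a [model_config()].
#' @param verbose print per-epoch losses.
#' @return A list with `model` (class `drp_model`), `predictions`
#'   (validation prediction records, predicted AAC clipped to `[0, 1]`),
#'   and `history` (per-epoch train/validation losses).
#' @export
train_fold <- function(records, fold, omics, catalog, config, verbose = FALSE) {
  stopifnot(inherits(config, "model_config"),
            inherits(fold, "fold_assignment"))
  train_rec <- records[fold$train, , drop = FALSE]
  val_rec <- records[fold$validation, , drop = FALSE]

  used <- config$omic_types
  panel <- Reduce(intersect, lapply(omics[used], function(m) m$cell_lines))
  usable <- function(r) r$cell_line %in% panel & r$drug %in% catalog$name
  n_drop <- sum(!usable(train_rec)) + sum(!usable(val_rec))
  if (n_drop > 0L) {
    message(sprintf("dropping %d record(s) without complete profiles", n_drop))
  }
  train_rec <- train_rec[usable(train_rec), , drop = FALSE]
  val_rec <- val_rec[usable(val_rec), , drop = FALSE]
  if (!nrow(train_rec) || !nrow(val_rec)) {
    stop("fold has no usable training or validation records", call. = FALSE)
  }

  train_cl <- unique(train_rec$cell_line)
  standardizers <- lapply(omics[used], function(m) {
    fit_standardizer(m, intersect(train_cl, m$cell_lines))
  })
  data <- build_model_data(omics, catalog, config, standardizers)

  aes <- list()
  for (k in seq_along(used)) {
    ot <- used[k]
    spec <- autoencoder_spec(ot, input_dim = ncol(data$X[[ot]]),
                             latent_dim = config$d_omic_latent,
                             activation = config$ae_activation,
                             epochs = config$ae_epochs,
                             seed = config$seed + 100L * k)
    aes[[ot]] <- pretrain_autoencoder(data$X[[ot]], spec)
  }

  params <- init_model_params(config, data, aes)
  meta <- list(afp_meta = attr(params, "afp_meta"),
               lmf_cfg = attr(params, "lmf_cfg"))
  frozen <- if (config$freeze_encoders) {
    grep("^enc_", names(params), value = TRUE)
  } else character(0)

  w <- if (config$use_lds) compute_lds_weights(train_rec$aac, config$lds)
       else rep(1, nrow(train_rec))

  all_rec <- rbind(train_rec, val_rec)
  rows <- record_rows(all_rec, data)
  idx_train <- seq_len(nrow(train_rec))
  idx_val <- nrow(train_rec) + seq_len(nrow(val_rec))

  st <- adam_state()
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  history <- data.frame(epoch = integer(0), train = numeric(0),
                        validation = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    tape <- ad_tape()
    P <- ad_lift_params(tape, params)
    fw <- drp_forward(tape, P, data, rows, config, meta)
    pred_train <- ad_gather(fw$pred, idx_train)
    loss <- ad_weighted_rmse(tape, pred_train, train_rec$aac, w)
    lv <- ad_value(loss)[1L]
    if (!is.finite(lv)) {
      stop("training diverged (non-finite loss) at epoch ", epoch,
           "; config: ", paste(deparse(unclass(config)), collapse = " "),
           call. = FALSE)
    }
    pred_all <- ad_value(fw$pred)
    val_rmse <- weighted_rmse(pred_all[idx_val, 1L], val_rec$aac)
    history <- rbind(history,
                     data.frame(epoch = epoch, train = lv,
                                validation = val_rmse))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch, lv, val_rmse))
    }
    if (val_rmse < best$loss - 1e-6) {
      best <- list(loss = val_rmse, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
    gf <- ad_backward(loss)
    grads <- ad_param_grads(gf, P)
    grads[frozen] <- list(NULL)
    params <- adam_step(params, grads, st, lr = config$lr,
                        weight_decay = config$weight_decay)
  }

  model <- structure(list(params = best$params, config = config, meta = meta,
                          standardizers = standardizers, data = data,
                          aes = aes, best_epoch = best$epoch),
                     class = "drp_model")
  preds <- predict(model, val_rec)
  preds$fold <- fold$fold
  preds$scheme <- fold$scheme
  list(model = model, predictions = preds, history = history)
}

#' @export
print.drp_model <- function(x, ...) {
  cat(sprintf("<drp_model: omics [%s], drug %s, fusion %s, lds %s, best epoch %d>\n",
              paste(x$config$omic_types, collapse = ","),
              x$config$drug_encoder, x$config$fusion, x$config$use_lds,
              x$best_epoch))
  invisible(x)
}

#' Predict AAC for response records
#'
#' Predictions are clipped to `[0, 1]` at report time (training is
#' unclipped); the true AAC column is carried through for evaluation.
#'
#' @param object a trained `drp_model`.
#' @param records response records whose cell lines and drugs are known to
#'   the model.
#' @param ... unused.
#' @return Prediction record data frame.
#' @export
predict.drp_model <- function(object, records, ...) {
  rows <- record_rows(records, object$data)
  tape <- ad_tape()
  P <- lapply(object$params, function(p) ad_const(tape, p))
  fw <- drp_forward(tape, P, object$data, rows, object$config, object$meta)
  pred <- pmin(1, pmax(0, ad_value(fw$pred)[, 1L]))
  data.frame(cell_line = records$cell_line, drug = records$drug,
             true_aac = records$aac, pred_aac = pred,
             lineage = records$lineage, stringsAsFactors = FALSE)
}

#' Elastic-net linear baseline
#'
#' L1+L2-regularized linear regression on the concatenated standardized
#' omic features and ECFP fingerprint bits, under exactly the same fold
#' protocol (training-split-only standardization) as the neural model.
#' The penalty is chosen by internal cross-validation on the training
#' split only.
#'
#' @inheritParams train_fold
#' @param ecfp_bits,ecfp_radius fingerprint settings.
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param seed seed for the internal penalty cross-validation.
#' @return A list with `predictions` and the fitted `fit`.
#' @export
elastic_net_baseline <- function(records, fold, omics, catalog,
                                 ecfp_bits = 256L, ecfp_radius = 2L,
                                 alpha = 0.5, seed = 1L) {
  used <- names(omics)
  train_rec <- records[fold$train, , drop = FALSE]
  val_rec <- records[fold$validation, , drop = FALSE]
  panel <- Reduce(intersect, lapply(omics, function(m) m$cell_lines))
  usable <- function(r) r$cell_line %in% panel & r$drug %in% catalog$name
  train_rec <- train_rec[usable(train_rec), , drop = FALSE]
  val_rec <- val_rec[usable(val_rec), , drop = FALSE]

  train_cl <- unique(train_rec$cell_line)
  Xomic <- do.call(cbind, lapply(omics, function(m) {
    std <- fit_standardizer(m, intersect(train_cl, m$cell_lines))
    apply_standardizer(m, std)$values[match(panel, m$cell_lines), , drop = FALSE]
  }))
  fp <- t(vapply(catalog$smiles, function(s) ecfp(s, ecfp_radius, ecfp_bits),
                 integer(ecfp_bits)))
  feat <- function(recs) {
    cbind(Xomic[match(recs$cell_line, panel), , drop = FALSE],
          fp[match(recs$drug, catalog$name), , drop = FALSE])
  }
  Xtr <- feat(train_rec); Xva <- feat(val_rec)
  if (stats::sd(train_rec$aac) == 0) {
    # degenerate target: the regularized fit is the constant model
    cv <- NULL
    pred <- rep(train_rec$aac[1L], nrow(Xva))
  } else {
    set.seed(seed)
    foldid <- sample(rep_len(1:5, nrow(Xtr)))
    cv <- glmnet::cv.glmnet(Xtr, train_rec$aac, alpha = alpha, foldid = foldid)
    pred <- pmin(1, pmax(0, as.vector(stats::predict(cv, Xva, s = "lambda.min"))))
  }
  preds <- data.frame(cell_line = val_rec$cell_line, drug = val_rec$drug,
                      true_aac = val_rec$aac, pred_aac = pred,
                      lineage = val_rec$lineage, fold = fold$fold,
                      scheme = fold$scheme, stringsAsFactors = FALSE)
  list(predictions = preds, fit = cv)
}

#' Random hyperparameter search over model configurations
#'
#' Samples `n_trials` configurations from the supplied space (a named list
#' of candidate value vectors for [model_config()] arguments), trains each
#' on the supplied folds, and returns the configuration with the lowest
#' mean validation RMSE together with the full trial log.
#'
#' @param space named list, e.g. `list(d_omic_latent = c(4, 8, 16))`.
#' @param n_trials number of sampled configurations.
#' @param records,folds,omics,catalog training inputs.
#' @param base_config configuration whose fields the sampled values override.
#' @param seed seed for configuration sampling.
#' @return A list with `best_config`, `best_loss`, and `log` (one row per
#'   trial).
#' @export
random_search <- function(space, n_trials, records, folds, omics, catalog,
                          base_config, seed = 1L) {
  stopifnot(n_trials >= 1L, length(space) >= 1L, !is.null(names(space)))
  set.seed(seed)
  draws <- lapply(seq_len(n_trials), function(i) {
    lapply(space, function(v) v[[sample.int(length(v), 1L)]])
  })
  log <- NULL
  best <- list(loss = Inf, config = NULL)
  for (i in seq_len(n_trials)) {
    cfg <- do.call(model_config,
                   utils::modifyList(unclass(base_config), draws[[i]]))
    losses <- vapply(folds, function(f) {
      out <- train_fold(records, f, omics, catalog, cfg)
      weighted_rmse(out$predictions$pred_aac, out$predictions$true_aac)
    }, numeric(1))
    row <- data.frame(trial = i, mean_val_rmse = mean(losses))
    for (nm in names(draws[[i]])) row[[nm]] <- draws[[i]][[nm]]
    log <- rbind(log, row)
    if (mean(losses) < best$loss) {
      best <- list(loss = mean(losses), config = cfg)
    }
  }
  list(best_config = best$config, best_loss = best$loss, log = log)
}

#' Write prediction records as TSV
#' @param predictions prediction record data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
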