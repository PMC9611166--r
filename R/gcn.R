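# CocrystalGCN: node embedding -> covalent graph convolution -> noncovalent
# graph convolution (each with a residual connection) -> global pooling ->
# fully connected head -> sigmoid probability of cocrystal formation.
#
# All layers are plain matrix algebra; minibatches concatenate pair graphs
# into one block-diagonal sparse adjacency, which is exactly equivalent to
# masked zero-padding (disconnected blocks cannot exchange messages and the
# pooling indicator touches only real atoms) and lets one sparse product
# drive the whole batch.

#' Training and architecture settings for CocrystalGCN
#'
#' @param embed_dim1,embed_dim2 Widths of the two node-embedding layers.
#' @param fc_dim Width of the hidden fully connected layer.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size (pairs).
#' @param epochs Training epochs; the checkpoint with the best validation
#'   AUC is returned.
#' @param use_covalent,use_noncovalent Ablation switches: disable the
#'   covalent (intramolecular) or noncovalent (intermolecular) convolution.
#'   At least one must stay on. The full model uses both.
#' @param pooling \code{"sum"} (the literal all-ones row vector) or
#'   \code{"mean"}.
#' @param normalize_adjacency If TRUE, symmetrically degree-normalize the
#'   adjacency matrices; default off (the raw 0/1 matrices are used).
#' @param eps_loss Probability clipping for the cross-entropy loss.
#' @return A \code{gcn_control} list.
#' @export
gcn_control <- function(embed_dim1 = 64L, embed_dim2 = 64L, fc_dim = 128L,
                        learning_rate = 1e-3, batch_size = 64L, epochs = 100L,
                        use_covalent = TRUE, use_noncovalent = TRUE,
                        pooling = c("sum", "mean"),
                        normalize_adjacency = FALSE, eps_loss = 1e-7) {
  pooling <- match.arg(pooling)
  if (!use_covalent && !use_noncovalent) {
    stop_ccg("at least one of use_covalent / use_noncovalent must be TRUE")
  }
  structure(list(embed_dim1 = as.integer(embed_dim1),
                 embed_dim2 = as.integer(embed_dim2),
                 fc_dim = as.integer(fc_dim),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 use_covalent = use_covalent,
                 use_noncovalent = use_noncovalent,
                 pooling = pooling,
                 normalize_adjacency = normalize_adjacency,
                 eps_loss = eps_loss),
            class = "gcn_control")
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

init_params <- function(feature_dim, control, seed) {
  with_seed(seed, {
    e1 <- control$embed_dim1; e2 <- control$embed_dim2; f <- control$fc_dim
    list(W1 = glorot(feature_dim, e1), b1 = numeric(e1),
         W2 = glorot(e1, e2), b2 = numeric(e2),
         W_C = glorot(e2, e2),
         W_NC = glorot(e2, e2),
         W_FC1 = glorot(e2, f), b_FC1 = numeric(f),
         W_FC2 = glorot(f, 1L), b_FC2 = numeric(1L))
  })
}

addb <- function(M, b) M + rep(b, each = nrow(M))

sym_normalize <- function(a) {
  d <- rowSums(a)
  s <- ifelse(d > 0, 1 / sqrt(d), 0)
  a * outer(s, s)
}

# ---- individual layer operations (exposed for inspection and testing) ----

#' Node-embedding layer
#'
#' Two dense layers with ReLU activations applied per atom row:
#' \code{h_NE = relu(b2 + relu(b1 + X W1) W2)}.
#'
#' @param x_in Atom feature matrix (rows = atoms).
#' @param params Parameter list with \code{W1, b1, W2, b2}.
#' @return Embedded node matrix, same row count, all entries >= 0.
#' @export
node_embed <- function(x_in, params) {
  if (ncol(x_in) != nrow(params$W1)) stop_ccg("feature dimension mismatch")
  relu(addb(relu(addb(x_in %*% params$W1, params$b1)) %*% params$W2, params$b2))
}

#' One residual graph-convolution step
#'
#' \code{residual_source + relu(a h w)}: neighbor aggregation through the
#' adjacency matrix, linear mixing, ReLU, and an additive residual
#' connection. Used once with the covalent adjacency and once with the
#' noncovalent adjacency.
#'
#' @param h Node matrix (m x dim).
#' @param a Adjacency matrix (m x m).
#' @param w Weight matrix (dim x dim).
#' @param residual_source Matrix added back after the convolution
#'   (defaults to \code{h}).
#' @return Updated node matrix.
#' @export
gc_step <- function(h, a, w, residual_source = h) {
  if (nrow(a) != nrow(h) || ncol(a) != nrow(h) || nrow(w) != ncol(h)) {
    stop_ccg("shape mismatch in gc_step")
  }
  residual_source + relu(as.matrix(a %*% h) %*% w)
}

#' Global pooling of node representations
#'
#' Sums the node rows (the all-ones-vector product \code{1' h}); with
#' \code{pooling = "mean"} divides by the atom count. Permutation-invariant
#' over rows.
#'
#' @param h_nc Node matrix.
#' @param mask Logical/0-1 vector marking real atoms (defaults to all).
#' @param pooling \code{"sum"} or \code{"mean"}.
#' @return Graph-level vector.
#' @export
global_pool <- function(h_nc, mask = NULL, pooling = "sum") {
  if (is.null(mask)) mask <- rep(1, nrow(h_nc))
  mask <- as.numeric(mask)
  if (sum(mask) == 0) stop_ccg("all-zero mask in global_pool")
  out <- as.numeric(crossprod(mask, h_nc))
  if (pooling == "mean") out <- out / sum(mask)
  out
}

#' Fully connected head
#'
#' \code{sigmoid(b_FC2 + relu(b_FC1 + h W_FC1) W_FC2)}: maps a pooled graph
#' vector to the cocrystal probability.
#'
#' @param h_gp Graph vector (or matrix of graph vectors, one per row).
#' @param params Parameter list with \code{W_FC1, b_FC1, W_FC2, b_FC2}.
#' @return Probability in (0, 1) (vector if \code{h_gp} is a matrix).
#' @export
predict_head <- function(h_gp, params) {
  if (is.null(dim(h_gp))) h_gp <- matrix(h_gp, nrow = 1L)
  if (ncol(h_gp) != nrow(params$W_FC1)) stop_ccg("shape mismatch in predict_head")
  z <- addb(relu(addb(h_gp %*% params$W_FC1, params$b_FC1)) %*% params$W_FC2,
            params$b_FC2)
  as.numeric(sigmoid(z))
}

#' Binary cross-entropy loss
#'
#' \code{-(1/N) sum(y log p + (1 - y) log(1 - p))} with probabilities
#' clipped to \code{[eps, 1 - eps]}.
#'
#' @param labels 0/1 vector.
#' @param probs Predicted probabilities, same length.
#' @param eps Clipping constant.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(labels, probs, eps = 1e-7) {
  if (length(labels) == 0L) stop_ccg("empty input to bce_loss")
  if (length(labels) != length(probs)) stop_ccg("length mismatch in bce_loss")
  p <- pmin(pmax(probs, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

# ---- batched forward / backward -------------------------------------------

# Assemble a minibatch of pair graphs into block-diagonal sparse form.
build_batch <- function(pgs, control) {
  sizes <- vapply(pgs, function(p) p$m, integer(1))
  total <- sum(sizes)
  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  if (control$normalize_adjacency) {
    A_C <- methods::as(Matrix::bdiag(lapply(pgs, function(p) sym_normalize(p$a_c))),
                       "generalMatrix")
    A_NC <- methods::as(Matrix::bdiag(lapply(pgs, function(p) sym_normalize(p$a_nc))),
                        "generalMatrix")
  } else {
    stack_idx <- function(field) {
      counts <- vapply(pgs, function(p) nrow(p[[field]]), integer(1))
      idx <- do.call(rbind, lapply(pgs, `[[`, field))
      off <- rep(offs, counts)
      cbind(idx[, 1] + off, idx[, 2] + off)
    }
    aci <- stack_idx("ac_idx")
    nci <- stack_idx("nc_idx")
    A_C <- Matrix::sparseMatrix(i = aci[, 1], j = aci[, 2], x = 1,
                                dims = c(total, total))
    A_NC <- Matrix::sparseMatrix(i = nci[, 1], j = nci[, 2], x = 1,
                                 dims = c(total, total))
  }
  pool_w <- if (control$pooling == "mean") rep(1 / sizes, sizes) else rep(1, total)
  list(
    X = do.call(rbind, lapply(pgs, function(p) p$x_in)),
    A_C = A_C,
    A_NC = A_NC,
    S = Matrix::sparseMatrix(i = rep(seq_along(pgs), sizes),
                             j = seq_len(total), x = pool_w,
                             dims = c(length(pgs), total)),
    sizes = sizes
  )
}

forward_batch <- function(params, batch, control, keep = FALSE) {
  Z1 <- addb(batch$X %*% params$W1, params$b1); H1 <- relu(Z1)
  Z2 <- addb(H1 %*% params$W2, params$b2); H2 <- relu(Z2)
  if (control$use_covalent) {
    PC <- as.matrix(batch$A_C %*% H2)
    MC <- PC %*% params$W_C
    HC <- H2 + relu(MC)
  } else {
    PC <- MC <- NULL
    HC <- H2
  }
  if (control$use_noncovalent) {
    PNC <- as.matrix(batch$A_NC %*% HC)
    MNC <- PNC %*% params$W_NC
    HNC <- HC + relu(MNC)
  } else {
    PNC <- MNC <- NULL
    HNC <- HC
  }
  G <- as.matrix(batch$S %*% HNC)
  ZF1 <- addb(G %*% params$W_FC1, params$b_FC1); F1 <- relu(ZF1)
  z <- as.numeric(addb(F1 %*% params$W_FC2, params$b_FC2))
  p <- sigmoid(z)
  if (!keep) return(list(prob = p, logit = z))
  list(prob = p, logit = z, Z1 = Z1, H1 = H1, Z2 = Z2, H2 = H2,
       PC = PC, MC = MC, HC = HC, PNC = PNC, MNC = MNC, HNC = HNC,
       G = G, ZF1 = ZF1, F1 = F1)
}

backward_batch <- function(params, batch, cache, y, control) {
  n <- length(y)
  dz <- matrix((cache$prob - y) / n, ncol = 1L)
  gW_FC2 <- crossprod(cache$F1, dz)
  gb_FC2 <- sum(dz)
  dF1 <- tcrossprod(dz, params$W_FC2)
  dZF1 <- dF1 * (cache$ZF1 > 0)
  gW_FC1 <- crossprod(cache$G, dZF1)
  gb_FC1 <- colSums(dZF1)
  dG <- tcrossprod(dZF1, params$W_FC1)
  dHNC <- as.matrix(Matrix::crossprod(batch$S, dG))

  if (control$use_noncovalent) {
    dMNC <- dHNC * (cache$MNC > 0)
    gW_NC <- crossprod(cache$PNC, dMNC)
    dPNC <- tcrossprod(dMNC, params$W_NC)
    dHC <- dHNC + as.matrix(batch$A_NC %*% dPNC)  # A_NC symmetric
  } else {
    gW_NC <- params$W_NC * 0
    dHC <- dHNC
  }
  if (control$use_covalent) {
    dMC <- dHC * (cache$MC > 0)
    gW_C <- crossprod(cache$PC, dMC)
    dPC <- tcrossprod(dMC, params$W_C)
    dH2 <- dHC + as.matrix(batch$A_C %*% dPC)  # A_C symmetric
  } else {
    gW_C <- params$W_C * 0
    dH2 <- dHC
  }
  dZ2 <- dH2 * (cache$Z2 > 0)
  gW2 <- crossprod(cache$H1, dZ2)
  gb2 <- colSums(dZ2)
  dH1 <- tcrossprod(dZ2, params$W2)
  dZ1 <- dH1 * (cache$Z1 > 0)
  gW1 <- crossprod(batch$X, dZ1)
  gb1 <- colSums(dZ1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W_C = gW_C, W_NC = gW_NC,
       W_FC1 = gW_FC1, b_FC1 = gb_FC1, W_FC2 = gW_FC2, b_FC2 = gb_FC2)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Build pair graphs for the rows of a pair table, reusing the molecule cache.
pair_graphs_of <- function(ds) {
  mols <- mol_graphs(c(ds$api_smiles, ds$cf_smiles))
  n <- nrow(ds)
  lapply(seq_len(n), function(i) pair_graph(mols[[i]], mols[[n + i]]))
}

predict_graphs <- function(params, control, pgs, chunk = 256L) {
  out_p <- numeric(length(pgs)); out_z <- numeric(length(pgs))
  idx <- split(seq_along(pgs), ceiling(seq_along(pgs) / chunk))
  for (ii in idx) {
    b <- build_batch(pgs[ii], control)
    fw <- forward_batch(params, b, control)
    out_p[ii] <- fw$prob; out_z[ii] <- fw$logit
  }
  list(prob = out_p, logit = out_z)
}

# ---- fitting ---------------------------------------------------------------

#' Fit the CocrystalGCN cocrystal-formation classifier
#'
#' Trains the five-module network (node embedding, covalent and noncovalent
#' graph convolutions with residual connections, sum pooling, fully
#' connected head) on a labeled pair dataset with Adam and binary
#' cross-entropy loss. When a validation set is supplied, the per-epoch
#' validation AUC is logged and the parameters from the best-AUC epoch are
#' returned; otherwise the final-epoch parameters are kept. Training is
#' fully deterministic given \code{seed} (initialization and shuffling).
#'
#' @param data Training \code{pair_dataset}; must contain both classes.
#' @param val Optional validation \code{pair_dataset}.
#' @param control A [gcn_control()] list of hyperparameters.
#' @param seed Integer seed.
#' @param verbose Print per-epoch progress.
#' @return An object of class \code{cocrystal_gcn} with components
#'   \code{params} (best checkpoint), \code{final_params}, \code{history}
#'   (epoch, train_loss, val_auc), \code{best_epoch}, \code{control},
#'   \code{seed}, \code{fitted} (training-set probabilities at the returned
#'   checkpoint) and the training data reference.
#' @seealso [predict.cocrystal_gcn()], [evaluate_model()],
#'   [cross_validate()], [lrp_relevance()], [screen_coformers()]
#' @export
cocrystal_gcn <- function(data, val = NULL, control = gcn_control(),
                          seed = 1L, verbose = FALSE) {
  stopifnot(inherits(control, "gcn_control"))
  if (!inherits(data, "pair_dataset")) data <- as_pair_dataset(data, canonicalize = TRUE)
  if (nrow(data) == 0L) stop_ccg("empty training set")
  if (length(unique(data$label)) < 2L) {
    stop_ccg("training set must contain both classes")
  }
  feature_dim <- atom_feature_dim()
  pgs <- pair_graphs_of(data)
  val_pgs <- if (!is.null(val) && nrow(val) > 0L) pair_graphs_of(val) else NULL

  params <- init_params(feature_dim, control, derive_seed(seed, 1L))
  state <- adam_init(params)
  n <- nrow(data)
  y <- data$label
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_auc = numeric(0))
  best_auc <- -Inf; best_params <- params; best_epoch <- 0L

  for (epoch in seq_len(control$epochs)) {
    ord <- with_seed(derive_seed(seed, 1000L + epoch), sample.int(n))
    batches <- split(ord, ceiling(seq_along(ord) / control$batch_size))
    ep_loss <- 0
    for (bi in batches) {
      b <- build_batch(pgs[bi], control)
      fw <- forward_batch(params, b, control, keep = TRUE)
      ep_loss <- ep_loss + bce_loss(y[bi], fw$prob, control$eps_loss) * length(bi)
      gr <- backward_batch(params, b, fw, y[bi], control)
      upd <- adam_step(params, gr, state, control$learning_rate)
      params <- upd$params; state <- upd$state
    }
    ep_loss <- ep_loss / n
    val_auc <- NA_real_
    if (!is.null(val_pgs)) {
      vp <- predict_graphs(params, control, val_pgs)
      val_auc <- auc_rank(val$label, vp$prob)
      if (!is.na(val_auc) && val_auc > best_auc) {
        best_auc <- val_auc; best_params <- params; best_epoch <- epoch
      }
    }
    history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss,
                                         val_auc = val_auc))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val_auc %s", epoch, ep_loss,
                      ifelse(is.na(val_auc), "-", sprintf("%.4f", val_auc))))
    }
  }
  if (is.null(val_pgs)) { best_params <- params; best_epoch <- control$epochs }
  fitted <- predict_graphs(best_params, control, pgs)$prob
  structure(list(params = best_params, final_params = params,
                 control = control, history = history,
                 best_epoch = best_epoch, seed = as.integer(seed),
                 feature_dim = feature_dim, data = data, val = val,
                 fitted = fitted, call = match.call()),
            class = "cocrystal_gcn")
}

#' Predict cocrystal probabilities for molecule pairs
#'
#' @param object A fitted \code{cocrystal_gcn}.
#' @param newdata A \code{pair_dataset}, a data frame with columns
#'   \code{api_smiles} and \code{cf_smiles}, or a list of
#'   \code{pair_graph}s. Defaults to the training data.
#' @param type \code{"prob"} (default), \code{"logit"} (pre-sigmoid score)
#'   or \code{"class"} (0/1 at \code{threshold}).
#' @param threshold Classification cutoff for \code{type = "class"}.
#' @param ... Unused.
#' @return Numeric (or integer, for \code{"class"}) vector.
#' @export
predict.cocrystal_gcn <- function(object, newdata = NULL,
                                  type = c("prob", "logit", "class"),
                                  threshold = 0.5, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  pgs <- if (is.list(newdata) && length(newdata) > 0L &&
             inherits(newdata[[1]], "pair_graph")) {
    newdata
  } else if (inherits(newdata, "pair_graph")) {
    list(newdata)
  } else {
    pair_graphs_of(newdata)
  }
  out <- predict_graphs(object$params, object$control, pgs)
  switch(type,
         prob = out$prob,
         logit = out$logit,
         class = as.integer(out$prob >= threshold))
}

#' @export
print.cocrystal_gcn <- function(x, ...) {
  cc <- class_counts(x$data)
  cat("CocrystalGCN classifier\n")
  cat("  training pairs: ", nrow(x$data), " (", cc["n_pos"], " pos / ",
      cc["n_neg"], " neg)\n", sep = "")
  cat("  convolutions: ",
      paste(c("covalent", "noncovalent")[c(x$control$use_covalent,
                                           x$control$use_noncovalent)],
            collapse = " + "), "\n", sep = "")
  cat("  epochs: ", x$control$epochs, "; checkpoint from epoch ",
      x$best_epoch, sep = "")
  if (any(!is.na(x$history$val_auc))) {
    cat(sprintf(" (val AUC %.4f)", max(x$history$val_auc, na.rm = TRUE)))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.cocrystal_gcn <- function(object, ...) {
  n_par <- sum(vapply(object$params, length, integer(1)))
  structure(list(fit = object, n_parameters = n_par,
                 final_loss = utils::tail(object$history$train_loss, 1),
                 best_val_auc = if (any(!is.na(object$history$val_auc)))
                   max(object$history$val_auc, na.rm = TRUE) else NA_real_),
            class = "summary.cocrystal_gcn")
}

#' @export
print.summary.cocrystal_gcn <- function(x, ...) {
  print(x$fit)
  cat("  trainable parameters: ", x$n_parameters, "\n", sep = "")
  cat(sprintf("  final training loss: %.4f\n", x$final_loss))
  if (!is.na(x$best_val_auc)) {
    cat(sprintf("  best validation AUC: %.4f\n", x$best_val_auc))
  }
  invisible(x)
}

#' @export
coef.cocrystal_gcn <- function(object, ...) object$params

#' @export
plot.cocrystal_gcn <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  plot(x$history$epoch, x$history$train_loss, type = "l",
       xlab = "epoch", ylab = "training loss", main = "Loss")
  if (any(!is.na(x$history$val_auc))) {
    plot(x$history$epoch, x$history$val_auc, type = "l",
         xlab = "epoch", ylab = "validation AUC", main = "Validation AUC")
    graphics::abline(v = x$best_epoch, lty = 2)
  }
  invisible(x)
}

#' @export
residuals.cocrystal_gcn <- function(object, ...) {
  object$data$label - object$fitted
}

#' @export
simulate.cocrystal_gcn <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- as.data.frame(replicate(nsim, rbinom(length(object$fitted), 1L,
                                              object$fitted)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

# ---- checkpoint I/O --------------------------------------------------------

#' Save / load a fitted model
#'
#' Checkpoints are a single JSON file holding the weights, the
#' hyperparameters and the training seed, so a saved model reloads
#' bit-identically on any platform.
#'
#' @param object A \code{cocrystal_gcn}.
#' @param path File path (JSON).
#' @return \code{save_gcn}: \code{path} invisibly; \code{load_gcn}: a
#'   \code{cocrystal_gcn} (without training data or history).
#' @export
save_gcn <- function(object, path) {
  payload <- list(
    package = "cocrystalgcn", format = 1L,
    control = unclass(object$control),
    seed = object$seed,
    feature_dim = object$feature_dim,
    best_epoch = object$best_epoch,
    params = object$params
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_gcn
#' @export
load_gcn <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  ctl <- do.call(gcn_control, payload$control)
  params <- lapply(payload$params, function(p) {
    if (is.matrix(p)) p else as.numeric(p)
  })
  # vectors serialized as 1-column matrices come back as matrices already;
  # biases must be plain numeric
  for (nm in c("b1", "b2", "b_FC1", "b_FC2")) params[[nm]] <- as.numeric(params[[nm]])
  structure(list(params = params, final_params = params, control = ctl,
                 history = NULL, best_epoch = payload$best_epoch,
                 seed = payload$seed, feature_dim = payload$feature_dim,
                 data = NULL, val = NULL, fitted = NULL,
                 call = quote(load_gcn())),
            class = "cocrystal_gcn")
}
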