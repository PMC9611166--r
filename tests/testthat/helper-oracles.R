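# Independent brute-force oracles and shared fixtures. Oracles are written
# as explicit elementwise loops so they share no code path with the package
# implementation they check.

# small molecules (<= 6 heavy atoms) for forward-pass oracle tests
small_mols <- c("C", "CC", "CCC", "CCO", "CCN", "CC=O", "O", "N", "OCC=O",
                "c1ccccc1", "C1CCCC1", "CC(C)O")

# deterministic random parameters for a given control, without touching the
# global RNG state
rand_params <- function(control = gcn_control(), seed = 1L) {
  cocrystalgcn:::init_params(atom_feature_dim(), control, seed)
}

# wrap bare parameters as a model object accepted by lrp_relevance/predict
fake_fit <- function(params, control = gcn_control()) {
  structure(list(params = params, control = control,
                 feature_dim = atom_feature_dim()),
            class = "cocrystal_gcn")
}

oracle_relu <- function(x) if (x > 0) x else 0

# entry-by-entry evaluation of the full forward pass on one pair graph
oracle_forward <- function(params, pg, control = gcn_control()) {
  m <- pg$m
  X <- pg$x_in
  matmul <- function(A, B) {
    out <- matrix(0, nrow(A), ncol(B))
    for (i in seq_len(nrow(A))) {
      for (j in seq_len(ncol(B))) {
        s <- 0
        for (k in seq_len(ncol(A))) s <- s + A[i, k] * B[k, j]
        out[i, j] <- s
      }
    }
    out
  }
  act <- function(M, b = NULL) {
    for (i in seq_len(nrow(M))) {
      for (j in seq_len(ncol(M))) {
        v <- M[i, j] + if (is.null(b)) 0 else b[j]
        M[i, j] <- oracle_relu(v)
      }
    }
    M
  }
  h1 <- act(matmul(X, params$W1), params$b1)
  h2 <- act(matmul(h1, params$W2), params$b2)
  hc <- h2
  if (control$use_covalent) {
    conv <- act(matmul(matmul(pg$a_c, h2), params$W_C))
    hc <- h2 + conv
  }
  hnc <- hc
  if (control$use_noncovalent) {
    conv <- act(matmul(matmul(pg$a_nc, hc), params$W_NC))
    hnc <- hc + conv
  }
  g <- numeric(ncol(hnc))
  for (j in seq_along(g)) for (i in seq_len(m)) g[j] <- g[j] + hnc[i, j]
  if (control$pooling == "mean") g <- g / m
  f1 <- act(matmul(matrix(g, 1), params$W_FC1), params$b_FC1)
  z <- matmul(f1, params$W_FC2)[1, 1] + params$b_FC2[1]
  list(prob = 1 / (1 + exp(-z)), logit = z)
}

# brute-force confusion counts and Mann-Whitney AUC
oracle_metrics <- function(labels, probs, threshold = 0.5) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(labels)) {
    pred <- if (probs[i] >= threshold) 1L else 0L
    if (pred == 1L && labels[i] == 1L) tp <- tp + 1L
    if (pred == 1L && labels[i] == 0L) fp <- fp + 1L
    if (pred == 0L && labels[i] == 0L) tn <- tn + 1L
    if (pred == 0L && labels[i] == 1L) fn <- fn + 1L
  }
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  auc <- NA_real_
  if (length(pos) > 0L && length(neg) > 0L) {
    s <- 0
    for (i in pos) {
      for (j in neg) {
        if (probs[i] > probs[j]) s <- s + 1
        else if (probs[i] == probs[j]) s <- s + 0.5
      }
    }
    auc <- s / (length(pos) * length(neg))
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn, auc = auc,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       acc = (tp + tn) / length(labels))
}

# independent greedy MaxMin reimplementation (loop form, first-item start,
# lowest-index tie break)
oracle_maxmin <- function(dmat, k) {
  n <- nrow(dmat)
  sel <- 1L
  while (length(sel) < k) {
    best <- NA_integer_; best_d <- -Inf
    for (i in seq_len(n)) {
      if (i %in% sel) next
      mind <- Inf
      for (s in sel) if (dmat[i, s] < mind) mind <- dmat[i, s]
      if (mind > best_d) { best_d <- mind; best <- i }
    }
    sel <- c(sel, best)
  }
  sel
}

# small shared synthetic dataset, built once per test run
.test_cache <- new.env(parent = emptyenv())

small_dataset <- function() {
  if (is.null(.test_cache$ds)) {
    spec <- synthetic_spec(n_molecules = 40L, n_pos = 80L, n_neg = 80L,
                           label_noise = 0, seed = 101L)
    .test_cache$ds <- generate_dataset(spec)
  }
  .test_cache$ds
}

random_test_pairs <- function(n, seed = 7L, mols = NULL) {
  ds <- small_dataset()
  lib <- if (is.null(mols)) attr(ds, "library") else mols
  picks <- cocrystalgcn:::with_seed(seed, {
    t(replicate(n, sample(seq_along(lib), 2L)))
  })
  lapply(seq_len(n), function(i) pair_graph(lib[picks[i, 1]], lib[picks[i, 2]]))
}
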