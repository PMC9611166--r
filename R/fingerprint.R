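# Molecular fingerprints and chemical-space embedding.

.fp_cache <- new.env(parent = emptyenv())

#' 1024-bit molecular fingerprints
#'
#' Computes OpenBabel 1024-bit path fingerprints (FP2) for a set of
#' molecules. These are the package's similarity currency: Tanimoto
#' distances on them drive MaxMin diversity selection and the
#' chemical-space embedding.
#'
#' @param smiles Character vector of SMILES.
#' @return 0/1 matrix with one row per unique canonical SMILES (rownames)
#'   and 1024 columns.
#' @export
molecule_fingerprints <- function(smiles) {
  canon <- unique(canonicalize_smiles(smiles))
  missing <- canon[!vapply(canon, exists, logical(1), envir = .fp_cache)]
  if (length(missing) > 0L) {
    sdfs <- suppressWarnings(ChemmineR::smiles2sdf(missing))
    fp <- suppressWarnings(ChemmineR::fingerprintOB(sdfs, "FP2"))
    m <- ChemmineR::as.matrix(fp)
    for (i in seq_along(missing)) {
      assign(missing[i], as.numeric(m[i, ]), envir = .fp_cache)
    }
  }
  out <- do.call(rbind, lapply(canon, get, envir = .fp_cache))
  rownames(out) <- canon
  out
}

#' Tanimoto similarity between fingerprint rows
#'
#' @param fps 0/1 fingerprint matrix (rows = molecules).
#' @return Symmetric similarity matrix in [0, 1].
#' @export
tanimoto_similarity <- function(fps) {
  inter <- tcrossprod(fps)
  ones <- rowSums(fps)
  union <- outer(ones, ones, "+") - inter
  out <- ifelse(union > 0, inter / union, 1)
  dimnames(out) <- list(rownames(fps), rownames(fps))
  out
}

# ---- exact t-SNE (small n) -------------------------------------------------
# Gaussian affinities with per-point precision calibrated to a target
# perplexity by bisection; Student-t low-dimensional kernel; gradient descent
# with momentum and early exaggeration. Quadratic in n, intended for the
# library-sized molecule sets used here.

.tsne_probs <- function(D2, perplexity) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 0 } else {
        p <- p / sp
        H <- -sum(ifelse(p > 0, p * log(p), 0))
      }
      if (abs(H - target) < 1e-5) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

.tsne <- function(D2, seed, perplexity = 30, n_iter = 400) {
  n <- nrow(D2)
  perplexity <- max(2, min(perplexity, floor((n - 1) / 3)))
  P <- .tsne_probs(D2, perplexity)
  with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  })
  gain <- matrix(1, n, 2); inc <- matrix(0, n, 2)
  eta <- 100
  for (it in seq_len(n_iter)) {
    ex <- if (it <= 100) 4 else 1
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (it <= 100) 0.5 else 0.8
    gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    inc <- mom * inc - eta * gain * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Embed molecule sets into a 2-D chemical space
#'
#' Fingerprints every molecule (1024-bit) and embeds the Tanimoto distance
#' structure into two dimensions with t-SNE, so the chemical-space coverage
#' of different pair sources (e.g. positives vs. generated vs. experimental
#' negatives) can be compared visually.
#'
#' @param smiles_sets Named list of character vectors of SMILES, one entry
#'   per labeled set.
#' @param seed Integer seed; the embedding is deterministic given the seed.
#' @param perplexity t-SNE perplexity (capped at \code{(n - 1) / 3}).
#' @return Data frame with columns \code{set}, \code{smiles}, \code{x},
#'   \code{y}; one row per valid unique molecule per set. Invalid SMILES are
#'   skipped with a warning.
#' @export
chemspace_embedding <- function(smiles_sets, seed = 1L, perplexity = 30) {
  stopifnot(is.list(smiles_sets), !is.null(names(smiles_sets)))
  rows <- do.call(rbind, lapply(names(smiles_sets), function(nm) {
    smi <- unique(smiles_sets[[nm]])
    ok <- vapply(smi, function(s) {
      !inherits(tryCatch(canonicalize_smiles(s), error = identity), "error")
    }, logical(1))
    if (any(!ok)) {
      warning("skipping ", sum(!ok), " invalid SMILES in set '", nm, "'")
    }
    if (!any(ok)) return(NULL)
    data.frame(set = nm, smiles = canonicalize_smiles(smi[ok]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows) || nrow(rows) < 3L) stop_ccg("need at least 3 valid molecules")
  fps <- molecule_fingerprints(rows$smiles)
  D2 <- (1 - tanimoto_similarity(fps))^2
  Y <- .tsne(D2[rows$smiles, rows$smiles], seed = seed, perplexity = perplexity)
  rows$x <- Y[, 1]; rows$y <- Y[, 2]
  rows
}

#' Plot a chemical-space embedding
#'
#' @param emb Output of [chemspace_embedding()].
#' @param path Output image path (PNG).
#' @return \code{path}, invisibly.
#' @export
plot_chemspace <- function(emb, path) {
  sets <- unique(emb$set)
  cols <- grDevices::hcl.colors(max(3, length(sets)), "Dark 3")[seq_along(sets)]
  grDevices::png(path, width = 800, height = 700)
  on.exit(grDevices::dev.off())
  plot(emb$x, emb$y, col = cols[match(emb$set, sets)], pch = 19,
       xlab = "t-SNE 1", ylab = "t-SNE 2", main = "Chemical space (1024-bit fingerprints)")
  graphics::legend("topright", legend = sets, col = cols, pch = 19, bty = "n")
  invisible(path)
}
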