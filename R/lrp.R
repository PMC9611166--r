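# Layer-wise relevance propagation (LRP) through the trained network.
#
# The pre-sigmoid logit is decomposed into per-atom contributions with the
# epsilon rule: at each linear step, relevance is redistributed to inputs in
# proportion to their contributions z_ij = x_i w_ij, with the denominator
# being the bias-free contribution sum (so relevance is conserved exactly
# when epsilon = 0). Residual additions split relevance between the two
# branches in proportion to their forward activations; adjacency products
# are treated as fixed-weight linear layers, so relevance flows along graph
# edges back to the atoms.

.stab <- function(d, eps) ifelse(d >= 0, d + eps, d - eps)

.safe_ratio <- function(r, d) ifelse(d == 0, 0, r / d)

# relevance through a row-wise linear map out = inp %*% W (no bias in the
# denominator): returns relevance on inp
.rel_linear <- function(inp, W, r_out, eps) {
  d <- inp %*% W
  inp * (.safe_ratio(r_out, .stab(d, eps)) %*% t(W))
}

# relevance through out = A %*% inp (A symmetric 0/1 adjacency)
.rel_adjacency <- function(inp, A, out, r_out, eps) {
  inp * as.matrix(A %*% .safe_ratio(r_out, .stab(out, eps)))
}

#' Per-atom relevance of a cocrystal prediction
#'
#' Decomposes the pre-sigmoid logit of the network for one API/coformer
#' pair into one relevance value per atom by backward propagation with the
#' epsilon rule. Positive relevance marks atoms pushing the prediction
#' toward cocrystal formation, negative relevance against it. With
#' \code{epsilon = 0} the relevances sum exactly to the logit
#' (conservation); a small positive epsilon stabilizes near-zero
#' denominators at the cost of absorbing a little relevance.
#'
#' @param object A fitted \code{cocrystal_gcn}.
#' @param pair A \code{pair_graph} (or the pair as \code{c(api, cf)} SMILES).
#' @param epsilon Stabilizer constant (default 1e-6).
#' @return A \code{relevance_map}: \code{pair}, \code{relevances} (length
#'   \code{pair$m}, pair atom order), \code{explained_value} (the logit),
#'   \code{epsilon}, and the full input-feature relevance matrix.
#' @seealso [render_heatmap()] to draw the atom-colored structure.
#' @export
lrp_relevance <- function(object, pair, epsilon = 1e-6) {
  stopifnot(inherits(object, "cocrystal_gcn"))
  if (is.character(pair)) {
    stopifnot(length(pair) == 2L)
    pair <- pair_graph(pair[1], pair[2])
  }
  stopifnot(inherits(pair, "pair_graph"))
  params <- object$params
  control <- object$control
  if (any(!vapply(params, function(p) all(is.finite(p)), logical(1)))) {
    stop_ccg("model parameters contain non-finite values")
  }
  batch <- build_batch(list(pair), control)
  cache <- forward_batch(params, batch, control, keep = TRUE)
  z <- cache$logit
  m <- pair$m

  # fully connected head
  r_f1 <- .rel_linear(matrix(cache$F1, 1L), params$W_FC2, matrix(z, 1L), epsilon)
  r_g <- .rel_linear(matrix(cache$G, 1L), params$W_FC1, r_f1, epsilon)

  # pooling: contributions are the (possibly mean-scaled) node rows
  w_pool <- if (control$pooling == "mean") rep(1 / m, m) else rep(1, m)
  contrib <- cache$HNC * w_pool
  ratio <- .safe_ratio(as.numeric(r_g), .stab(as.numeric(cache$G), epsilon))
  r_hnc <- contrib * rep(ratio, each = m)

  # noncovalent convolution with residual split
  if (control$use_noncovalent) {
    branch <- relu(cache$MNC)
    rr <- .safe_ratio(r_hnc, .stab(cache$HC + branch, epsilon))
    r_hc <- cache$HC * rr
    r_branch <- branch * rr
    r_pnc <- .rel_linear(cache$PNC, params$W_NC, r_branch, epsilon)
    r_hc <- r_hc + .rel_adjacency(cache$HC, batch$A_NC, cache$PNC, r_pnc, epsilon)
  } else {
    r_hc <- r_hnc
  }

  # covalent convolution with residual split
  if (control$use_covalent) {
    branch <- relu(cache$MC)
    rr <- .safe_ratio(r_hc, .stab(cache$H2 + branch, epsilon))
    r_h2 <- cache$H2 * rr
    r_branch <- branch * rr
    r_pc <- .rel_linear(cache$PC, params$W_C, r_branch, epsilon)
    r_h2 <- r_h2 + .rel_adjacency(cache$H2, batch$A_C, cache$PC, r_pc, epsilon)
  } else {
    r_h2 <- r_hc
  }

  # node-embedding layers back to the input features
  r_h1 <- .rel_linear(cache$H1, params$W2, r_h2, epsilon)
  r_x <- .rel_linear(batch$X, params$W1, r_h1, epsilon)

  structure(list(pair = pair,
                 relevances = rowSums(r_x),
                 explained_value = z,
                 epsilon = epsilon,
                 input_relevance = r_x),
            class = "relevance_map")
}

#' @export
print.relevance_map <- function(x, ...) {
  cat("<relevance_map> ", x$pair$api$smiles, " | ", x$pair$coformer$smiles,
      "\n  logit ", sprintf("%.4f", x$explained_value),
      "; sum of atom relevances ", sprintf("%.4f", sum(x$relevances)),
      " (epsilon ", format(x$epsilon), ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.relevance_map <- function(x, ...) {
  roles <- ifelse(pair_api_mask(x$pair), "API", "CF")
  data.frame(atom_index = seq_len(x$pair$m),
             molecule_role = roles,
             element = c(x$pair$api$elements, x$pair$coformer$elements),
             relevance = x$relevances,
             stringsAsFactors = FALSE)
}

#' Write a per-atom relevance table to CSV
#'
#' @param rel A \code{relevance_map}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_relevance_table <- function(rel, path) {
  write.csv(as.data.frame(rel), path, row.names = FALSE)
  invisible(path)
}

# map relevances to diverging colors (blue = negative, white = 0, red =
# positive); intensity proportional to |relevance| / max |relevance|
relevance_colors <- function(relevances) {
  pal <- grDevices::colorRampPalette(c("#2166AC", "#FFFFFF", "#B2182B"))(201)
  mx <- max(abs(relevances))
  scaled <- if (mx == 0) rep(0, length(relevances)) else relevances / mx
  pal[round(scaled * 100) + 101]
}

#' Render an atomic-contribution heat map
#'
#' Draws the API and coformer side by side in 2-D with each atom shaded on
#' a symmetric diverging scale centered at zero: red for positive
#' contributions to the cocrystal score, blue for negative, white for zero;
#' color intensity is proportional to |relevance| normalized by the pair
#' maximum.
#'
#' @param pair A \code{pair_graph}.
#' @param rel The matching \code{relevance_map}.
#' @param out_path Output image path (\code{.png} or \code{.svg}).
#' @param width,height Image size in pixels (PNG) or inches (SVG).
#' @return \code{out_path}, invisibly.
#' @export
render_heatmap <- function(pair, rel, out_path, width = 900, height = 500) {
  stopifnot(inherits(pair, "pair_graph"), inherits(rel, "relevance_map"))
  if (!all(is.finite(rel$relevances))) stop_ccg("non-finite relevances")
  api_xy <- pair$api$coords
  cf_xy <- pair$coformer$coords
  gap <- 2.0
  shift <- max(api_xy[, 1]) - min(cf_xy[, 1]) + gap
  cf_xy[, 1] <- cf_xy[, 1] + shift
  xy <- rbind(api_xy, cf_xy)
  cols <- relevance_colors(rel$relevances)

  if (grepl("\\.svg$", out_path)) {
    grDevices::svg(out_path, width = width / 100, height = height / 100)
  } else {
    grDevices::png(out_path, width = width, height = height)
  }
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(1, 1, 3, 1)); on.exit(graphics::par(op), add = TRUE)
  plot(xy, type = "n", asp = 1, axes = FALSE, xlab = "", ylab = "",
       main = sprintf("Atomic contributions (logit %.3f)", rel$explained_value))
  draw_bonds <- function(bonds, offset) {
    if (nrow(bonds) > 0L) {
      graphics::segments(xy[bonds[, 1] + offset, 1], xy[bonds[, 1] + offset, 2],
                         xy[bonds[, 2] + offset, 1], xy[bonds[, 2] + offset, 2],
                         col = "grey40")
    }
  }
  draw_bonds(pair$api$bonds, 0L)
  draw_bonds(pair$coformer$bonds, pair$api$atom_count)
  graphics::points(xy, pch = 21, bg = cols, cex = 3, col = "grey30")
  graphics::text(xy, labels = c(pair$api$elements, pair$coformer$elements),
                 cex = 0.7)
  graphics::mtext(c("API", "coformer"), side = 1,
                  at = c(mean(api_xy[, 1]), mean(cf_xy[, 1])), line = -1)
  invisible(out_path)
}

#' @export
plot.relevance_map <- function(x, out_path = tempfile(fileext = ".png"), ...) {
  render_heatmap(x$pair, x, out_path, ...)
}
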