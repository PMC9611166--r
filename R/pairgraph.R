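# Paired API/coformer graph with covalent and noncovalent block adjacency.
#
# For m = m_API + m_CF atoms, the full adjacency splits into four blocks
# (API:API, API:CF, CF:API, CF:CF). The covalent matrix A_C keeps only the
# intramolecular bond blocks; the noncovalent matrix A_NC fills the two
# cross blocks with 1, encoding every possible intermolecular contact.

#' Build the paired cocrystal graph for an API/coformer pair
#'
#' Stacks the two molecules' atom feature matrices (API atoms first) and
#' builds the covalent adjacency \code{a_c} (block-diagonal: bonds within
#' each molecule, zero cross blocks) and the noncovalent adjacency
#' \code{a_nc} (block-anti-diagonal: all intermolecular atom pairs set to 1,
#' zero within-molecule blocks). Both matrices are symmetric, zero-diagonal
#' and have disjoint supports.
#'
#' @param api,coformer \code{mol_graph} objects or SMILES strings.
#' @return A \code{pair_graph}: \code{api}, \code{coformer} (mol_graphs),
#'   \code{m} (total atom count), \code{x_in} (\code{m x feature_dim}
#'   feature matrix), \code{a_c}, \code{a_nc} (\code{m x m} 0/1 matrices).
#' @examples
#' pg <- pair_graph("CC", "O")
#' pg$a_c   # ethane bond only, water atom isolated
#' pg$a_nc  # the two cross blocks filled with 1
#' @export
pair_graph <- function(api, coformer) {
  if (is.character(api)) api <- mol_graph(api)
  if (is.character(coformer)) coformer <- mol_graph(coformer)
  stopifnot(inherits(api, "mol_graph"), inherits(coformer, "mol_graph"))
  na <- api$atom_count
  nc <- coformer$atom_count
  if (na == 0L || nc == 0L) stop_ccg("empty molecule in pair_graph")
  m <- na + nc

  a_c <- matrix(0, m, m)
  if (nrow(api$bonds) > 0L) {
    a_c[api$bonds] <- 1
    a_c[api$bonds[, 2:1, drop = FALSE]] <- 1
  }
  if (nrow(coformer$bonds) > 0L) {
    cb <- coformer$bonds + na
    a_c[cb] <- 1
    a_c[cb[, 2:1, drop = FALSE]] <- 1
  }

  a_nc <- matrix(0, m, m)
  a_nc[seq_len(na), na + seq_len(nc)] <- 1
  a_nc[na + seq_len(nc), seq_len(na)] <- 1

  # sparse index lists (both directions) reused by the batched network
  ac_idx <- which(a_c == 1, arr.ind = TRUE)
  nc_idx <- which(a_nc == 1, arr.ind = TRUE)
  dimnames(ac_idx) <- dimnames(nc_idx) <- NULL

  structure(list(
    api = api, coformer = coformer, m = m,
    x_in = rbind(api$features, coformer$features),
    a_c = a_c, a_nc = a_nc,
    ac_idx = ac_idx, nc_idx = nc_idx
  ), class = "pair_graph")
}

#' @export
print.pair_graph <- function(x, ...) {
  cat("<pair_graph> API ", x$api$smiles, " (", x$api$atom_count,
      " atoms) + CF ", x$coformer$smiles, " (", x$coformer$atom_count,
      " atoms)\n", sep = "")
  invisible(x)
}

# Role of each atom row: TRUE for API atoms, FALSE for coformer atoms.
pair_api_mask <- function(pg) {
  c(rep(TRUE, pg$api$atom_count), rep(FALSE, pg$coformer$atom_count))
}

#' Write a plain-text debug dump of a pair graph
#'
#' Emits the atom table and the dense 0/1 covalent and noncovalent
#' adjacency matrices in a stable, diff-friendly text format.
#'
#' @param pg A \code{pair_graph}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_pair_graph <- function(pg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  roles <- ifelse(pair_api_mask(pg), "API", "CF")
  elems <- c(pg$api$elements, pg$coformer$elements)
  writeLines(sprintf("pair %s | %s", pg$api$smiles, pg$coformer$smiles), con)
  writeLines(sprintf("m %d", pg$m), con)
  writeLines("atoms", con)
  writeLines(sprintf("%d %s %s", seq_len(pg$m), roles, elems), con)
  writeLines("A_C", con)
  writeLines(apply(pg$a_c, 1, paste, collapse = " "), con)
  writeLines("A_NC", con)
  writeLines(apply(pg$a_nc, 1, paste, collapse = " "), con)
  invisible(path)
}
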