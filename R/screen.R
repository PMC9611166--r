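# Coformer virtual screening: score a candidate list against one API and
# rank by predicted cocrystal probability.

#' Screen coformer candidates against an API
#'
#' Scores every candidate with the trained network (full forward pass on
#' the API/candidate pair graph), ranks candidates by descending
#' probability (ties broken by input order) and returns the top \code{k}.
#' Unparseable candidates are excluded with a warning and noted in the
#' result's \code{excluded} attribute.
#'
#' @param object A fitted \code{cocrystal_gcn}.
#' @param api SMILES of the API.
#' @param candidates Either a character vector of SMILES or a data frame
#'   with columns \code{id} and \code{smiles}.
#' @param top_k Number of top-ranked coformers to return (default: all).
#' @return A \code{ranked_coformers} data frame with columns \code{rank},
#'   \code{coformer_id}, \code{smiles}, \code{score}; the full ranking is
#'   attached as attribute \code{full_table}.
#' @export
screen_coformers <- function(object, api, candidates, top_k = NULL) {
  stopifnot(inherits(object, "cocrystal_gcn"))
  if (is.character(candidates)) {
    candidates <- data.frame(id = paste0("cand_", seq_along(candidates)),
                             smiles = candidates, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "smiles") %in% names(candidates)))
  if (nrow(candidates) == 0L) stop_ccg("empty candidate list")

  parsed <- lapply(candidates$smiles, function(s) {
    tryCatch(mol_graph(s), error = function(e) NULL)
  })
  ok <- !vapply(parsed, is.null, logical(1))
  if (any(!ok)) {
    warning("excluded ", sum(!ok), " unparseable candidate(s): ",
            paste(candidates$id[!ok], collapse = ", "))
  }
  if (!any(ok)) stop_ccg("no parseable candidates")
  api_mol <- mol_graph(api)
  pgs <- lapply(parsed[ok], function(m) pair_graph(api_mol, m))
  scores <- predict_graphs(object$params, object$control, pgs)$prob

  kept <- candidates[ok, , drop = FALSE]
  ord <- order(-scores, seq_along(scores))
  n <- length(ord)
  if (is.null(top_k)) top_k <- n
  if (top_k > n) stop_ccg("top_k exceeds the number of scored candidates (", n, ")")
  full <- data.frame(rank = seq_len(n),
                     coformer_id = kept$id[ord],
                     smiles = kept$smiles[ord],
                     score = scores[ord],
                     stringsAsFactors = FALSE)
  out <- full[seq_len(top_k), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "full_table") <- full
  attr(out, "excluded") <- candidates$id[!ok]
  attr(out, "api") <- api_mol$smiles
  class(out) <- c("ranked_coformers", "data.frame")
  out
}

#' @export
print.ranked_coformers <- function(x, ...) {
  cat("Coformer ranking for API ", attr(x, "api"), "\n", sep = "")
  print.data.frame(head(as.data.frame(x), 15), digits = 4, row.names = FALSE)
  if (nrow(x) > 15L) cat("... ", nrow(x) - 15L, " more rows\n", sep = "")
  excl <- attr(x, "excluded")
  if (length(excl) > 0L) {
    cat("excluded (unparseable): ", paste(excl, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
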