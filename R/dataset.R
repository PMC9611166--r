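# Labeled pair datasets: construction, deduplication, negative generation,
# frequency-difference rebalancing with MaxMin diversity selection, and
# stratified splitting / k-fold resplits.

.SOURCES <- c("csd_pos", "gen_neg", "exp_neg", "synthetic")

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Construct a labeled pair dataset
#'
#' A \code{pair_dataset} is a data frame with columns \code{api_smiles},
#' \code{cf_smiles}, \code{label} (0/1) and \code{source} (one of
#' \code{csd_pos}, \code{gen_neg}, \code{exp_neg}, \code{synthetic}).
#' Pair identity is unordered and based on canonical SMILES: cocrystal
#' formation is symmetric in its two components.
#'
#' @param api_smiles,cf_smiles Character vectors of SMILES.
#' @param label Integer vector of 0/1 labels.
#' @param source Source tag(s); recycled. Must be consistent with the label
#'   (\code{csd_pos} pairs are positive, \code{gen_neg}/\code{exp_neg}
#'   negative).
#' @param canonicalize If TRUE (default), canonicalize the SMILES columns.
#' @return A \code{pair_dataset}.
#' @export
pair_dataset <- function(api_smiles, cf_smiles, label,
                         source = "synthetic", canonicalize = TRUE) {
  stopifnot(length(api_smiles) == length(cf_smiles),
            length(label) == length(api_smiles))
  if (canonicalize && length(api_smiles) > 0L) {
    api_smiles <- canonicalize_smiles(api_smiles)
    cf_smiles <- canonicalize_smiles(cf_smiles)
  }
  label <- as.integer(label)
  source <- rep_len(as.character(source), length(label))
  if (!all(label %in% c(0L, 1L))) stop_ccg("labels must be 0 or 1")
  if (!all(source %in% .SOURCES)) {
    stop_ccg("unknown source tag; expected one of ",
             paste(.SOURCES, collapse = ", "))
  }
  if (any(source == "csd_pos" & label != 1L) ||
      any(source %in% c("gen_neg", "exp_neg") & label != 0L)) {
    stop_ccg("source tag inconsistent with label")
  }
  if (any(api_smiles == cf_smiles)) {
    stop_ccg("a pair must join two different molecules")
  }
  ds <- data.frame(api_smiles = api_smiles, cf_smiles = cf_smiles,
                   label = label, source = source,
                   stringsAsFactors = FALSE)
  class(ds) <- c("pair_dataset", "data.frame")
  ds
}

as_pair_dataset <- function(df, canonicalize = FALSE) {
  pair_dataset(df$api_smiles, df$cf_smiles, df$label,
               df$source %||% "synthetic", canonicalize = canonicalize)
}

#' Class counts of a pair dataset
#' @param ds A \code{pair_dataset}.
#' @return Named integer vector \code{c(n_pos, n_neg)}.
#' @export
class_counts <- function(ds) {
  c(n_pos = sum(ds$label == 1L), n_neg = sum(ds$label == 0L))
}

#' @export
print.pair_dataset <- function(x, ...) {
  cc <- class_counts(x)
  cat("<pair_dataset> ", nrow(x), " pairs (", cc["n_pos"], " positive, ",
      cc["n_neg"], " negative)\n", sep = "")
  if (nrow(x) > 0L) print.data.frame(head(x, 6))
  if (nrow(x) > 6L) cat("... ", nrow(x) - 6L, " more rows\n", sep = "")
  invisible(x)
}

#' Remove duplicate pairs
#'
#' Pairs are compared as unordered canonical-SMILES sets within each label
#' class; the first occurrence wins and input order is otherwise preserved.
#'
#' @param pairs A \code{pair_dataset} (or data frame with its columns).
#' @return A deduplicated \code{pair_dataset}.
#' @export
deduplicate_pairs <- function(pairs) {
  if (!inherits(pairs, "pair_dataset")) pairs <- as_pair_dataset(pairs, canonicalize = TRUE)
  key <- paste(pair_key(pairs$api_smiles, pairs$cf_smiles), pairs$label)
  out <- pairs[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Randomly generate negative molecule pairs
#'
#' Draws \code{n} distinct unordered pairs from a molecule pool, excluding a
#' forbidden set (typically the known positive pairs), and labels them 0
#' with source \code{gen_neg}. This emulates the construction of artificial
#' negatives by random recombination of cocrystal components.
#'
#' @param pool Character vector of SMILES (canonicalized internally).
#' @param n Number of pairs to generate.
#' @param forbidden A \code{pair_dataset} or 2-column data frame of pairs to
#'   avoid; NULL for none.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A \code{pair_dataset} of \code{n} negative pairs.
#' @export
generate_negative_pairs <- function(pool, n, forbidden = NULL, seed = 1L) {
  pool <- unique(canonicalize_smiles(pool))
  if (length(pool) < 2L) stop_ccg("pool must contain at least 2 distinct molecules")
  idx <- utils::combn(length(pool), 2L)
  a <- pool[idx[1, ]]; b <- pool[idx[2, ]]
  keys <- pair_key(a, b)
  if (!is.null(forbidden) && nrow(forbidden) > 0L) {
    fkeys <- pair_key(canonicalize_smiles(forbidden$api_smiles),
                      canonicalize_smiles(forbidden$cf_smiles))
    keep <- !(keys %in% fkeys)
    a <- a[keep]; b <- b[keep]
  }
  if (length(a) < n) {
    stop_ccg("only ", length(a), " distinct pairs available outside the ",
             "forbidden set; cannot generate ", n)
  }
  sel <- with_seed(seed, sample.int(length(a), n))
  pair_dataset(a[sel], b[sel], rep(0L, n), "gen_neg", canonicalize = FALSE)
}

#' Count how often each compound occurs in a dataset
#'
#' Each pair contributes one occurrence to each of its two molecules, so the
#' counts sum to twice the number of pairs.
#'
#' @param ds A \code{pair_dataset}.
#' @return Named integer vector: canonical SMILES -> occurrence count.
#' @export
compound_frequency <- function(ds) {
  if (nrow(ds) == 0L) return(setNames(integer(0), character(0)))
  tab <- table(c(ds$api_smiles, ds$cf_smiles))
  setNames(as.integer(tab), names(tab))
}

#' Greedy MaxMin diversity selection
#'
#' Picks \code{k} items maximizing diversity: starting from the first item
#' (input order), repeatedly adds the item whose minimum distance to the
#' already-selected set is largest, breaking ties by lowest input index.
#'
#' @param items A list or vector of items (only their indices matter here).
#' @param k Number of items to select, \code{1 <= k <= length(items)}.
#' @param distance Either an \code{n x n} symmetric distance matrix or a
#'   function \code{f(i, j)} returning the distance between items i and j.
#' @param seed Unused by the deterministic start rule; kept for interface
#'   stability.
#' @return Integer vector of selected indices, in selection order.
#' @export
maxmin_select <- function(items, k, distance, seed = 1L) {
  n <- if (is.matrix(distance)) nrow(distance) else length(items)
  if (k < 1L || k > n) stop_ccg("k must be in [1, ", n, "]")
  dist_fun <- if (is.matrix(distance)) {
    function(i, j) distance[i, j]
  } else {
    distance
  }
  selected <- 1L
  if (k > 1L) {
    mind <- vapply(seq_len(n), function(i) dist_fun(i, 1L), numeric(1))
    mind[1L] <- -Inf
    for (step in seq_len(k - 1L)) {
      nxt <- which.max(mind)  # which.max returns the lowest index on ties
      selected <- c(selected, nxt)
      mind[nxt] <- -Inf
      for (i in which(is.finite(mind))) {
        d <- dist_fun(i, nxt)
        if (d < mind[i]) mind[i] <- d
      }
    }
  }
  selected
}

# 1 - Tanimoto distance matrix between pairs, each pair fingerprinted as the
# concatenation of its two molecules' 1024-bit fingerprints in canonical
# (sorted-SMILES) order.
.pair_distance_matrix <- function(api, cf) {
  mols <- unique(c(api, cf))
  fps <- molecule_fingerprints(mols)
  first <- pmin(api, cf); second <- pmax(api, cf)
  pf <- cbind(fps[first, , drop = FALSE], fps[second, , drop = FALSE])
  inter <- tcrossprod(pf)
  ones <- rowSums(pf)
  union <- outer(ones, ones, "+") - inter
  sim <- ifelse(union > 0, inter / union, 1)
  1 - sim
}

#' Rebalance generated negatives against over-represented compounds
#'
#' Implements the frequency-difference removal procedure used to make room
#' for experimentally confirmed negatives: compounds are ranked by how much
#' more often they occur in the generated negatives (\code{gen_neg}) than in
#' the positives (\code{csd_pos}); for each compound with gen_neg frequency
#' M exceeding positive frequency N, the M pairs containing it are reduced
#' to the N most diverse ones (greedy MaxMin over 1 - Tanimoto distances of
#' concatenated pair fingerprints) and the rest deleted, until exactly
#' \code{remove_total} pairs have been removed (the final compound may be
#' truncated to hit the exact total). The experimental negatives are then
#' appended.
#'
#' @param gen_neg,csd_pos,exp_neg \code{pair_dataset}s. \code{exp_neg} must
#'   be disjoint from \code{gen_neg} (as unordered canonical pairs).
#' @param remove_total Number of gen_neg pairs to remove; typically
#'   \code{nrow(exp_neg)} so the class stays balanced.
#' @param seed Integer seed (passed to [maxmin_select()]).
#' @return A \code{pair_dataset} of the surviving gen_neg pairs followed by
#'   all exp_neg pairs; size \code{nrow(gen_neg) - remove_total + nrow(exp_neg)}.
#' @export
rebalance_negatives <- function(gen_neg, csd_pos, exp_neg, remove_total,
                                seed = 1L) {
  stopifnot(inherits(gen_neg, "pair_dataset"), inherits(csd_pos, "pair_dataset"))
  if (remove_total > nrow(gen_neg)) {
    stop_ccg("remove_total exceeds the number of generated negatives")
  }
  if (!is.null(exp_neg) && nrow(exp_neg) > 0L) {
    gkeys <- pair_key(gen_neg$api_smiles, gen_neg$cf_smiles)
    ekeys <- pair_key(exp_neg$api_smiles, exp_neg$cf_smiles)
    if (any(ekeys %in% gkeys)) {
      stop_ccg("exp_neg must be disjoint from gen_neg")
    }
  }

  freq_g <- compound_frequency(gen_neg)
  freq_p <- compound_frequency(csd_pos)
  pos_of <- function(s) {
    v <- freq_p[s]; v[is.na(v)] <- 0L; unname(v)
  }
  diffs <- freq_g - pos_of(names(freq_g))
  # rank compounds by descending frequency difference; ties resolved
  # alphabetically for determinism
  ord <- order(-diffs, names(freq_g))
  compounds <- names(freq_g)[ord]

  alive <- rep(TRUE, nrow(gen_neg))
  removed <- 0L
  for (cmp in compounds) {
    if (removed >= remove_total) break
    rows <- which(alive & (gen_neg$api_smiles == cmp | gen_neg$cf_smiles == cmp))
    M <- length(rows)
    N <- pos_of(cmp)
    if (M <= N) next
    quota <- min(M - N, remove_total - removed)
    keep_n <- M - quota
    if (keep_n > 0L) {
      dm <- .pair_distance_matrix(gen_neg$api_smiles[rows], gen_neg$cf_smiles[rows])
      keep_idx <- maxmin_select(rows, keep_n, dm, seed = seed)
      drop_rows <- rows[-keep_idx]
    } else {
      drop_rows <- rows
    }
    alive[drop_rows] <- FALSE
    removed <- removed + length(drop_rows)
  }
  if (removed < remove_total) {
    stop_ccg("only ", removed, " pairs removable under the M > N rule; ",
             "cannot remove ", remove_total)
  }
  out <- gen_neg[alive, , drop = FALSE]
  if (!is.null(exp_neg) && nrow(exp_neg) > 0L) {
    out <- rbind(as.data.frame(out), as.data.frame(exp_neg))
  }
  out <- as_pair_dataset(out)
  rownames(out) <- NULL
  out
}

# largest-remainder allocation of n into shares proportional to ratios
.largest_remainder <- function(n, ratios) {
  raw <- n * ratios / sum(ratios)
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0L) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Stratified random train/validation/test split
#'
#' Partitions a dataset into three disjoint subsets with sizes given by
#' largest-remainder rounding of the ratios, stratified by label so each
#' split's class balance matches the whole dataset to within one pair per
#' class.
#'
#' @param ds A \code{pair_dataset}.
#' @param ratios Numeric length-3 vector (train, validation, test) summing
#'   to 1; default \code{c(0.8, 0.1, 0.1)}.
#' @param seed Integer seed; the partition is deterministic given the seed.
#' @return Named list of three \code{pair_dataset}s: \code{train},
#'   \code{val}, \code{test}.
#' @export
split_dataset <- function(ds, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(ratios) == 3L, all(ratios > 0))
  if (abs(sum(ratios) - 1) > 1e-6) stop_ccg("ratios must sum to 1")
  assign_split <- integer(nrow(ds))
  with_seed(seed, {
    for (lab in c(0L, 1L)) {
      rows <- which(ds$label == lab)
      if (length(rows) == 0L) next
      sizes <- .largest_remainder(length(rows), ratios)
      shuffled <- sample(rows)
      assign_split[shuffled] <- rep(1:3, times = sizes)
    }
  })
  parts <- lapply(1:3, function(k) {
    out <- ds[assign_split == k, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  names(parts) <- c("train", "val", "test")
  if (any(vapply(parts, nrow, integer(1)) == 0L)) {
    stop_ccg("dataset too small: a split would be empty")
  }
  parts
}

#' Repeated random resplits for k-fold cross-validation
#'
#' Each fold is an independent random train/validation/test resplit of the
#' whole dataset (the cross-validation protocol re-randomizes the 8:1:1
#' partition in every repetition), with per-fold seeds derived
#' deterministically from the master seed.
#'
#' @param ds A \code{pair_dataset}.
#' @param k Number of folds (>= 2).
#' @param ratios Split ratios per fold; default \code{c(0.8, 0.1, 0.1)}.
#' @param seed Master integer seed.
#' @return List of \code{k} named lists (\code{train}, \code{val},
#'   \code{test}).
#' @export
kfold_splits <- function(ds, k = 10L, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(k >= 2L)
  lapply(seq_len(k), function(i) {
    split_dataset(ds, ratios, seed = derive_seed(seed, i))
  })
}

#' Read / write pair tables
#'
#' Pair tables are plain CSV files with header
#' \code{api_smiles, cf_smiles, label, source}.
#'
#' @param path CSV file path.
#' @return \code{read_pair_table}: a \code{pair_dataset}.
#' @export
read_pair_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("api_smiles", "cf_smiles", "label")
  if (!all(need %in% names(df))) {
    stop_ccg("pair table must have columns ", paste(need, collapse = ", "))
  }
  as_pair_dataset(df, canonicalize = FALSE)
}

#' @rdname read_pair_table
#' @param ds A \code{pair_dataset} to write.
#' @export
write_pair_table <- function(ds, path) {
  write.csv(as.data.frame(ds), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
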