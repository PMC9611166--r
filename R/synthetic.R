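# Synthetic molecule libraries and labeled pair datasets.
#
# A fragment grammar assembles small organic molecules in three classes:
# hydrogen-bond donors (carboxylic acid, hydroxyl, amide N-H), acceptors
# (pyridine/pyrazine-type aromatic N, ester) and motif-free hydrocarbons.
# The planted pairing rule is donor/acceptor complementarity — the
# heterosynthon logic of cocrystal design — so labels are a deterministic
# function of substructure and a graph classifier can in principle reach
# perfect ranking at zero label noise.

#' Specification of a synthetic cocrystal study
#'
#' @param n_molecules Library size.
#' @param donor_fraction,acceptor_fraction Fractions of the library carrying
#'   donor / acceptor motifs (the remainder is motif-free). Defaults mirror a
#'   screening library rich in hydrogen-bonding chemistry.
#' @param n_pos,n_neg Numbers of positive / negative pairs to generate.
#' @param label_noise Probability in [0, 0.5) that a label is flipped.
#' @param frequency_skew Non-negative; 0 draws molecules uniformly, larger
#'   values reuse early library molecules more often (Zipf-like weights
#'   \code{rank^-skew}), producing the over-represented compounds that
#'   negative-set rebalancing targets.
#' @param seed Integer seed.
#' @return A \code{synthetic_spec} list.
#' @export
synthetic_spec <- function(n_molecules = 60L, donor_fraction = 0.4,
                           acceptor_fraction = 0.4, n_pos = 500L,
                           n_neg = 500L, label_noise = 0,
                           frequency_skew = 0, seed = 1L) {
  stopifnot(donor_fraction >= 0, acceptor_fraction >= 0,
            donor_fraction + acceptor_fraction <= 1,
            label_noise >= 0, label_noise < 0.5,
            n_molecules > 0, n_pos > 0, n_neg > 0, frequency_skew >= 0)
  structure(list(n_molecules = as.integer(n_molecules),
                 donor_fraction = donor_fraction,
                 acceptor_fraction = acceptor_fraction,
                 n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 label_noise = label_noise,
                 frequency_skew = frequency_skew,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# fragment grammar ----------------------------------------------------------

.grammar_candidates <- function() {
  alkyl <- c("CC", "CCC", "CCCC", "CCCCC", "CCCCCC", "CCCCCCC", "CCCCCCCC",
             "CC(C)C", "CC(C)CC", "CCC(C)C", "CC(C)(C)C", "CCCCC(C)C")
  cyclic <- c("C1CCCCC1", "C1CCCC1", "CC1CCCCC1", "CCC1CCCCC1")
  aryl <- c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "CCCc1ccccc1",
            "Cc1ccccc1C", "Cc1ccc(C)cc1")
  scaffolds <- c(alkyl, cyclic, aryl)
  spacers <- c("", "C", "CC", "CCC")

  donors <- c("O", "C(=O)O", "NC(C)=O", "C(N)=O", "CO", "N")
  donor_smiles <- as.vector(outer(scaffolds, paste0(spacers, rep(donors, each = length(spacers))),
                                  paste0))

  n_rings <- c("c1ccncc1", "c1cnccn1", "c1cncnc1",
               "Cc1ccncc1", "Cc1cnccn1", "CCc1ccncc1", "CCCc1ccncc1",
               "Cc1ccncc1C", "CCc1cnccn1", "CCCCc1ccncc1", "CC(C)c1ccncc1",
               "CCCCCc1ccncc1", "Cc1cncnc1", "CCc1cncnc1")
  esters <- c("C(=O)OC", "C(=O)OCC", "OC(C)=O")
  acceptor_smiles <- c(n_rings,
                       as.vector(outer(scaffolds, paste0(spacers, rep(esters, each = length(spacers))),
                                       paste0)))

  neutral_smiles <- c(scaffolds,
                      as.vector(outer(c("CC", "CCC", "CCCC"), c("C1CCCCC1", "c1ccccc1"), paste0)),
                      "CCCCCCCCC", "CCCCCCCCCC", "CC(C)CC(C)C", "CCC(CC)CC")
  list(donor = donor_smiles, acceptor = acceptor_smiles, neutral = neutral_smiles)
}

# Canonicalize, deduplicate and verify motif-class purity of the grammar
# output. Cached per session: the grammar is fixed.
.grammar_env <- new.env(parent = emptyenv())

.grammar_library <- function() {
  if (!is.null(.grammar_env$lib)) return(.grammar_env$lib)
  cand <- .grammar_candidates()
  classify <- function(smi, want) {
    canon <- unique(canonicalize_smiles(smi))
    keep <- vapply(canon, function(s) {
      g <- mol_graph(s)
      d <- has_donor(g); a <- has_acceptor(g)
      switch(want,
             donor = d && !a,
             acceptor = a && !d,
             neutral = !d && !a)
    }, logical(1))
    canon[keep]
  }
  lib <- list(donor = classify(cand$donor, "donor"),
              acceptor = classify(cand$acceptor, "acceptor"),
              neutral = classify(cand$neutral, "neutral"))
  # a molecule reachable through two routes keeps its first class
  lib$acceptor <- setdiff(lib$acceptor, lib$donor)
  lib$neutral <- setdiff(lib$neutral, c(lib$donor, lib$acceptor))
  .grammar_env$lib <- lib
  lib
}

#' Generate a synthetic molecule library
#'
#' Draws \code{n_molecules} unique, valid, canonical SMILES from the
#' fragment grammar with the class mix requested by the spec.
#'
#' @param spec A [synthetic_spec()].
#' @return Character vector of canonical SMILES with a \code{class}
#'   attribute (\code{"donor"}, \code{"acceptor"} or \code{"neutral"} per
#'   molecule).
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lib <- .grammar_library()
  n_d <- round(spec$n_molecules * spec$donor_fraction)
  n_a <- round(spec$n_molecules * spec$acceptor_fraction)
  n_n <- spec$n_molecules - n_d - n_a
  avail <- vapply(lib, length, integer(1))
  want <- c(donor = n_d, acceptor = n_a, neutral = n_n)
  if (any(want > avail[names(want)])) {
    bad <- names(want)[want > avail[names(want)]]
    stop_ccg("grammar capacity exceeded for class(es) ",
             paste0(bad, " (max ", avail[bad], ")", collapse = ", "))
  }
  with_seed(derive_seed(spec$seed, 101L), {
    smi <- c(sample(lib$donor, n_d), sample(lib$acceptor, n_a),
             sample(lib$neutral, n_n))
    cls <- rep(c("donor", "acceptor", "neutral"), times = c(n_d, n_a, n_n))
    ord <- sample(length(smi))
    structure(smi[ord], class_label = cls[ord])
  })
}

#' Planted heterosynthon pairing rule
#'
#' Returns 1 exactly when one molecule carries a hydrogen-bond donor motif
#' and the other an acceptor motif (in either order), 0 otherwise. This is
#' the ground-truth labeling function of the synthetic study.
#'
#' @param a,b SMILES strings or \code{mol_graph}s.
#' @return Integer 0 or 1; symmetric in its arguments.
#' @examples
#' planted_label("OC(=O)c1ccccc1", "c1cnccn1")  # benzoic acid + pyrazine -> 1
#' planted_label("CCCCCC", "c1ccccc1")          # hexane + benzene -> 0
#' @export
planted_label <- function(a, b) {
  if (is.character(a)) a <- mol_graph(a)
  if (is.character(b)) b <- mol_graph(b)
  da <- has_donor(a); aa <- has_acceptor(a)
  db <- has_donor(b); ab <- has_acceptor(b)
  as.integer((da && ab) || (db && aa))
}

# sampling weights over library indices (Zipf-like when skew > 0)
.reuse_weights <- function(n, skew) {
  if (skew <= 0) rep(1, n) else seq_len(n)^(-skew)
}

#' Generate a labeled synthetic pair dataset
#'
#' Builds the library, enumerates complementary (donor/acceptor) and
#' non-complementary unordered pairs, samples \code{n_pos} and \code{n_neg}
#' of them (optionally with compound-reuse skew), labels them by the
#' planted rule and finally flips each label independently with probability
#' \code{label_noise}.
#'
#' @param spec A [synthetic_spec()].
#' @return A \code{pair_dataset} with source \code{"synthetic"} and
#'   attributes \code{library} (the molecule library with classes) and
#'   \code{true_label} (pre-noise labels).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lib <- generate_library(spec)
  cls <- attr(lib, "class_label")
  idx <- utils::combn(length(lib), 2L)
  complementary <- (cls[idx[1, ]] == "donor" & cls[idx[2, ]] == "acceptor") |
    (cls[idx[1, ]] == "acceptor" & cls[idx[2, ]] == "donor")
  pos_pool <- which(complementary)
  neg_pool <- which(!complementary)
  if (length(pos_pool) < spec$n_pos || length(neg_pool) < spec$n_neg) {
    stop_ccg("infeasible pair counts: at most ", length(pos_pool),
             " positive and ", length(neg_pool),
             " negative pairs exist for this library")
  }
  w <- .reuse_weights(length(lib), spec$frequency_skew)
  pair_w <- w[idx[1, ]] * w[idx[2, ]]
  with_seed(derive_seed(spec$seed, 202L), {
    pos_sel <- sample(pos_pool, spec$n_pos, prob = pair_w[pos_pool])
    neg_sel <- sample(neg_pool, spec$n_neg, prob = pair_w[neg_pool])
    sel <- c(pos_sel, neg_sel)
    true_lab <- rep(c(1L, 0L), times = c(spec$n_pos, spec$n_neg))
    flip <- stats::rbinom(length(sel), 1L, spec$label_noise) == 1L
    lab <- ifelse(flip, 1L - true_lab, true_lab)
    ord <- sample(length(sel))
    ds <- pair_dataset(lib[idx[1, sel[ord]]], lib[idx[2, sel[ord]]],
                       lab[ord], "synthetic", canonicalize = FALSE)
    attr(ds, "library") <- lib
    attr(ds, "true_label") <- true_lab[ord]
    ds
  })
}
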