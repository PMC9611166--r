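# Molecular graphs from SMILES
#
# Molecules are handled as heavy-atom graphs: hydrogens are implicit and
# enter only through a per-atom hydrogen-count feature. Parsing, canonical
# SMILES and ring/aromaticity perception are delegated to OpenBabel via
# ChemmineR/ChemmineOB.

.mol_cache <- new.env(parent = emptyenv())

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form so that equivalent notations
#' (kekulized vs. aromatic, different atom orderings) map to one string.
#' Canonical SMILES are the identity used throughout the package for
#' deduplication and pair bookkeeping.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, same length as the input.
#'   Idempotent: canonicalizing a canonical string returns it unchanged.
#' @examples
#' canonicalize_smiles(c("OCC", "CCO"))  # identical outputs
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  bad <- !nzchar(trimws(smiles)) | is.na(smiles)
  if (any(bad)) {
    stop_ccg("unparseable SMILES: ", paste(smiles[bad], collapse = ", "))
  }
  out <- vapply(smiles, function(s) {
    res <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", source = s),
      error = function(e) ""
    )
    res <- sub("\t.*$", "", sub("\n.*$", "", res))
    trimws(res)
  }, character(1), USE.NAMES = FALSE)
  failed <- !nzchar(out)
  if (any(failed)) {
    stop_ccg("unparseable SMILES: ", paste(smiles[failed], collapse = ", "))
  }
  out
}

# ---- atom feature configuration -------------------------------------------

.FEAT_ELEMENTS <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "other")
.FEAT_DEGREES  <- 0:5
.FEAT_HCOUNTS  <- 0:4
.FEAT_HYBRID   <- c("sp", "sp2", "sp3", "other")

.DEFAULT_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3,
                      F = 1, Cl = 1, Br = 1, I = 1)

#' Names of the atom feature columns
#'
#' @return Character vector naming the columns of the per-atom feature matrix:
#'   element one-hot, degree one-hot, hydrogen-count one-hot, formal charge,
#'   aromaticity flag, ring-membership flag and hybridization one-hot.
#' @export
atom_feature_names <- function() {
  c(paste0("elem_", .FEAT_ELEMENTS),
    paste0("deg_", .FEAT_DEGREES),
    paste0("numH_", .FEAT_HCOUNTS),
    "formal_charge", "aromatic", "in_ring",
    paste0("hyb_", .FEAT_HYBRID))
}

#' Dimension of the atom feature vector
#' @return Integer, the number of atom feature columns (28 by default).
#' @export
atom_feature_dim <- function() length(atom_feature_names())

# MDL V2000 atom-block charge codes -> formal charges.
.mdl_charge <- function(code) {
  map <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
           `6` = -2, `7` = -3)
  out <- map[as.character(code)]
  out[is.na(out)] <- 0
  unname(out)
}

# Single heavy atoms need special handling: the SDF round trip drops
# zero-bond molecules, so they are parsed straight from the SMILES.
.single_atom_pattern <- "^(\\[([A-Z][a-z]?)H?\\d*([+-]\\d*)?\\]|Br|Cl|[BCNOPSFI])$"

.parse_single_atom <- function(canonical) {
  m <- regmatches(canonical, regexec(.single_atom_pattern, canonical))[[1]]
  elem <- if (nzchar(m[3])) m[3] else m[2]
  charge <- 0L
  if (nzchar(m[4])) {
    sgn <- if (startsWith(m[4], "-")) -1L else 1L
    mag <- sub("^[+-]", "", m[4])
    charge <- sgn * if (nzchar(mag)) as.integer(mag) else 1L
  }
  h <- if (grepl("^\\[", canonical)) {
    hm <- regmatches(canonical, regexec("H(\\d*)", canonical))[[1]]
    if (length(hm) == 0L) 0L
    else if (nzchar(hm[2])) as.integer(hm[2]) else 1L
  } else {
    val <- .DEFAULT_VALENCE[elem]
    if (is.na(val)) 0L else as.integer(val + charge)
  }
  list(elements = elem, bonds = matrix(integer(0), ncol = 2),
       bond_orders = numeric(0), degree = 0L, h_count = max(0L, h),
       formal_charge = charge, aromatic = FALSE, in_ring = FALSE,
       hybridization = if (elem %in% c("C", "N", "O", "S", "P")) "sp3" else "other",
       coords = matrix(0, 1L, 2L))
}

# Parse one SDF component (already canonical-SMILES-derived) into the raw
# graph fields. `sdf` is a ChemmineR::SDF object.
.parse_sdf_component <- function(sdf, canonical) {
  ab <- ChemmineR::atomblock(sdf)
  n <- nrow(ab)
  if (is.null(n) || n == 0L) {
    stop_ccg("molecule has no heavy atoms: ", canonical)
  }
  elements <- sub("_\\d+$", "", rownames(ab))
  charge_code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, n)
  charge <- .mdl_charge(charge_code)

  bb <- ChemmineR::bondblock(sdf)
  if (!is.null(bb) && is.null(dim(bb))) bb <- matrix(bb, nrow = 1L)
  if (is.null(bb) || nrow(bb) == 0L) {
    bonds <- matrix(integer(0), ncol = 2)
    orders <- numeric(0)
  } else {
    bonds <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
    orders <- as.numeric(bb[, 3])
    orders[orders == 4] <- 1.5  # aromatic bond code, if OpenBabel emits it
  }

  degree <- integer(n)
  order_sum <- numeric(n)
  n_double <- integer(n)
  n_triple <- integer(n)
  if (nrow(bonds) > 0L) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]; o <- orders[b]
      degree[i] <- degree[i] + 1L
      degree[j] <- degree[j] + 1L
      order_sum[i] <- order_sum[i] + o
      order_sum[j] <- order_sum[j] + o
      if (o == 2) { n_double[i] <- n_double[i] + 1L; n_double[j] <- n_double[j] + 1L }
      if (o == 3) { n_triple[i] <- n_triple[i] + 1L; n_triple[j] <- n_triple[j] + 1L }
    }
  }

  # Ring perception; aromaticity taken from OpenBabel's ring typing.
  aromatic <- logical(n)
  in_ring <- logical(n)
  if (nrow(bonds) > 0L) {
    rr <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf, type = "all", arom = TRUE)),
      error = function(e) list(RINGS = list(), AROMATIC = logical(0))
    )
    if (length(rr$RINGS) > 0L) {
      for (k in seq_along(rr$RINGS)) {
        idx <- as.integer(sub("^.*_", "", rr$RINGS[[k]]))
        in_ring[idx] <- TRUE
        if (isTRUE(rr$AROMATIC[[k]])) aromatic[idx] <- TRUE
      }
    }
  }

  valence <- .DEFAULT_VALENCE[elements]
  valence[is.na(valence)] <- 0
  h_count <- pmax(0L, as.integer(round(valence + charge - order_sum)))

  hybrid <- ifelse(n_triple > 0L | n_double >= 2L, "sp",
            ifelse(n_double > 0L | aromatic, "sp2",
            ifelse(elements %in% c("C", "N", "O", "S", "P"), "sp3", "other")))

  list(elements = elements, bonds = bonds, bond_orders = orders,
       degree = degree, h_count = h_count, formal_charge = charge,
       aromatic = aromatic, in_ring = in_ring, hybridization = hybrid,
       coords = unname(ab[, 1:2, drop = FALSE]))
}

.one_hot <- function(value, levels) {
  m <- matrix(0, nrow = length(value), ncol = length(levels))
  idx <- match(value, levels)
  idx[is.na(idx)] <- length(levels)  # last level is the catch-all bucket
  m[cbind(seq_along(value), idx)] <- 1
  m
}

.features_from_fields <- function(g) {
  elem <- ifelse(g$elements %in% head(.FEAT_ELEMENTS, -1), g$elements, "other")
  hyb <- ifelse(g$hybridization %in% head(.FEAT_HYBRID, -1), g$hybridization, "other")
  feats <- cbind(
    .one_hot(elem, .FEAT_ELEMENTS),
    .one_hot(pmin(g$degree, max(.FEAT_DEGREES)), .FEAT_DEGREES),
    .one_hot(pmin(g$h_count, max(.FEAT_HCOUNTS)), .FEAT_HCOUNTS),
    g$formal_charge,
    as.numeric(g$aromatic),
    as.numeric(g$in_ring),
    .one_hot(hyb, .FEAT_HYBRID)
  )
  colnames(feats) <- atom_feature_names()
  feats
}

#' Build molecular graphs from SMILES
#'
#' Parses each SMILES into a heavy-atom molecular graph with per-atom
#' features. Results are cached by canonical SMILES, so repeated molecules
#' (the common case when featurizing large pair tables) are parsed once.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A list of \code{mol_graph} objects, one per input.
#' @seealso [mol_graph()] for the single-molecule wrapper,
#'   [pair_graph()] for the paired API/coformer representation.
#' @export
mol_graphs <- function(smiles) {
  canon <- canonicalize_smiles(smiles)
  missing <- unique(canon[!vapply(canon, exists, logical(1), envir = .mol_cache)])
  singles <- grepl(.single_atom_pattern, missing)
  for (s in missing[singles]) {
    fields <- .parse_single_atom(s)
    g <- structure(
      c(list(smiles = s, atom_count = 1L,
             features = .features_from_fields(fields)),
        fields),
      class = "mol_graph")
    assign(s, g, envir = .mol_cache)
  }
  missing <- missing[!singles]
  if (length(missing) > 0L) {
    sdfs <- suppressWarnings(ChemmineR::smiles2sdf(missing))
    for (i in seq_along(missing)) {
      fields <- .parse_sdf_component(sdfs[[i]], missing[i])
      g <- structure(
        c(list(smiles = missing[i],
               atom_count = length(fields$elements),
               features = .features_from_fields(fields)),
          fields),
        class = "mol_graph")
      assign(missing[i], g, envir = .mol_cache)
    }
  }
  lapply(canon, get, envir = .mol_cache)
}

#' Build a molecular graph from one SMILES string
#'
#' @param smiles A single SMILES string.
#' @return A \code{mol_graph}: canonical SMILES, heavy-atom count, element
#'   symbols, bond list (unordered index pairs), and an
#'   \code{atom_count x atom_feature_dim()} feature matrix.
#' @examples
#' g <- mol_graph("c1ccncc1")  # pyridine
#' g$atom_count
#' @export
mol_graph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  mol_graphs(smiles)[[1]]
}

#' Per-atom feature matrix of a molecule
#'
#' One row per heavy atom; columns are named by [atom_feature_names()].
#' One-hot groups (element, degree, hydrogen count, hybridization) each sum
#' to exactly 1 per row; elements outside the supported set fall into the
#' \code{other} bucket.
#'
#' @param mol A \code{mol_graph} or a SMILES string.
#' @return Numeric matrix of shape \code{atom_count x atom_feature_dim()}.
#' @export
featurize_atoms <- function(mol) {
  if (is.character(mol)) mol <- mol_graph(mol)
  stopifnot(inherits(mol, "mol_graph"))
  mol$features
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$smiles, "\n", sep = "")
  cat("  atoms: ", x$atom_count, " (", paste(unique(x$elements), collapse = ","),
      ")  bonds: ", nrow(x$bonds), "\n", sep = "")
  invisible(x)
}

# ---- hydrogen-bond motif detection ----------------------------------------

#' Locate hydrogen-bond donor and acceptor atoms
#'
#' Flags the atoms that carry the package's planted heterosynthon motifs:
#' donors are O or N atoms bearing at least one hydrogen (hydroxyl,
#' carboxylic acid O-H, amide/amine N-H); acceptors are aromatic ring
#' nitrogens without hydrogen (pyridine/pyrazine type) and ester bridging
#' oxygens (O bonded to two carbons, one of which is a carbonyl carbon).
#'
#' @param mol A \code{mol_graph} or SMILES string.
#' @return List with integer vectors \code{donor} and \code{acceptor} of
#'   atom indices (1-based, parser order).
#' @export
motif_atoms <- function(mol) {
  if (is.character(mol)) mol <- mol_graph(mol)
  n <- mol$atom_count
  donor <- which((mol$elements %in% c("O", "N")) & mol$h_count > 0)

  acceptor <- which(mol$elements == "N" & mol$aromatic & mol$h_count == 0)
  # ester bridging oxygen: -C(=O)-O-C
  if (any(mol$elements == "O")) {
    nb <- vector("list", n)
    if (nrow(mol$bonds) > 0L) {
      for (b in seq_len(nrow(mol$bonds))) {
        i <- mol$bonds[b, 1]; j <- mol$bonds[b, 2]
        nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
      }
    }
    carbonyl_c <- logical(n)
    if (nrow(mol$bonds) > 0L) {
      for (b in seq_len(nrow(mol$bonds))) {
        i <- mol$bonds[b, 1]; j <- mol$bonds[b, 2]
        if (mol$bond_orders[b] == 2) {
          if (mol$elements[i] == "C" && mol$elements[j] == "O") carbonyl_c[i] <- TRUE
          if (mol$elements[j] == "C" && mol$elements[i] == "O") carbonyl_c[j] <- TRUE
        }
      }
    }
    ester_o <- which(vapply(seq_len(n), function(i) {
      mol$elements[i] == "O" && mol$h_count[i] == 0 && length(nb[[i]]) == 2 &&
        all(mol$elements[nb[[i]]] == "C") && any(carbonyl_c[nb[[i]]])
    }, logical(1)))
    acceptor <- sort(unique(c(acceptor, ester_o)))
  }
  list(donor = as.integer(donor), acceptor = as.integer(acceptor))
}

has_donor <- function(mol) length(motif_atoms(mol)$donor) > 0
has_acceptor <- function(mol) length(motif_atoms(mol)$acceptor) > 0
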