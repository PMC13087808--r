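## Matched molecular pairs.
##
## Molecules are fragmented at every acyclic single bond into a constant part
## (the larger side, at least `min_constant_frac` of the heavy atoms) and a
## variable part, each carrying one attachment marker. Two molecules sharing
## an identical canonical constant part form a matched pair; the fragment swap
## variable_a -> variable_b is the pair's transformation, which can be applied
## to any molecule exposing the left-hand fragment.

#' Fragment a molecule into (constant, variable) splits
#'
#' Enumerates all single cuts of acyclic single bonds and keeps splits whose
#' constant (larger) side holds at least `min_constant_frac` of the heavy
#' atoms. Molecules with no cuttable bond give an empty result.
#'
#' @param smiles a single SMILES string.
#' @param max_cuts number of simultaneous cuts; only single cuts are
#'   supported (the substituent-level edits the pipeline learns).
#' @param min_constant_frac minimum heavy-atom fraction of the constant part
#'   (default 2/3, a standard matched-pair constraint keeping pairs
#'   congeneric).
#' @return data.frame with columns `constant`, `variable` (canonical
#'   one-marker fragment SMILES), `heavy_constant`, `heavy_variable`,
#'   `n_cuts`.
#' @export
fragmentMolecule <- function(smiles, max_cuts = 1L, min_constant_frac = 2 / 3) {
  if (!identical(as.integer(max_cuts), 1L))
    stop("only single-cut fragmentation is supported (max_cuts = 1)")
  mol <- parse_smiles(smiles)
  cuts <- .enumerate_cuts(mol)
  if (!length(cuts))
    return(data.frame(constant = character(), variable = character(),
                      heavy_constant = integer(), heavy_variable = integer(),
                      n_cuts = integer()))
  total <- heavy_atom_count(mol)
  rows <- lapply(cuts, function(ct) {
    if (ct$heavy_i >= ct$heavy_j) {
      const <- ct$smiles_i; varb <- ct$smiles_j
      hc <- ct$heavy_i; hv <- ct$heavy_j
    } else {
      const <- ct$smiles_j; varb <- ct$smiles_i
      hc <- ct$heavy_j; hv <- ct$heavy_i
    }
    if (hc < min_constant_frac * total) return(NULL)
    data.frame(constant = const, variable = varb,
               heavy_constant = hc, heavy_variable = hv, n_cuts = 1L)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(constant = character(), variable = character(),
                      heavy_constant = integer(), heavy_variable = integer(),
                      n_cuts = integer()))
  unique(out)
}

#' Build matched molecular pairs from a series
#'
#' Fragments every molecule and pairs molecules with an identical canonical
#' constant part. Each unordered pair is reported once per shared constant
#' part; members must differ in their variable fragment. The result is
#' invariant (up to row order) under permutation of the input.
#'
#' @param ms a [MoleculeSet].
#' @param min_constant_frac passed to [fragmentMolecule()].
#' @return a [MatchedPairSet].
#' @export
buildPairs <- function(ms, min_constant_frac = 2 / 3) {
  stopifnot(is(ms, "MoleculeSet"), nMolecules(ms) >= 2L)
  df <- molecules(ms)
  frags <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    fr <- fragmentMolecule(df$smiles[i], min_constant_frac = min_constant_frac)
    if (nrow(fr)) cbind(id = df$id[i], fr) else NULL
  }))
  empty <- data.frame(id_a = character(), id_b = character(),
                      constant = character(), variable_a = character(),
                      variable_b = character())
  if (is.null(frags) || !nrow(frags)) return(new("MatchedPairSet", pairs = empty))
  rows <- list()
  for (const in unique(frags$constant)) {
    grp <- frags[frags$constant == const, , drop = FALSE]
    if (nrow(grp) < 2L) next
    idx <- utils::combn(nrow(grp), 2L)
    for (k in seq_len(ncol(idx))) {
      a <- idx[1, k]; b <- idx[2, k]
      if (grp$id[a] == grp$id[b]) next
      if (grp$variable[a] == grp$variable[b]) next
      ## stable orientation: order by id so input permutation cannot matter
      if (grp$id[a] <= grp$id[b]) {
        rows[[length(rows) + 1L]] <- data.frame(
          id_a = grp$id[a], id_b = grp$id[b], constant = const,
          variable_a = grp$variable[a], variable_b = grp$variable[b])
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          id_a = grp$id[b], id_b = grp$id[a], constant = const,
          variable_a = grp$variable[b], variable_b = grp$variable[a])
      }
    }
  }
  pairs <- if (length(rows)) unique(do.call(rbind, rows)) else empty
  pairs <- pairs[order(pairs$id_a, pairs$id_b, pairs$constant), , drop = FALSE]
  rownames(pairs) <- NULL
  new("MatchedPairSet", pairs = pairs)
}

#' Extract fragment-swap transformations from matched pairs
#'
#' Each matched pair yields one transformation `lhs -> rhs` (the a -> b
#' fragment swap); applying it to molecule a at the shared constant part
#' regenerates molecule b.
#'
#' @param mps a [MatchedPairSet].
#' @param directed when TRUE also return the reverse (b -> a) swaps.
#' @return data.frame with columns `lhs`, `rhs`, `id_a`, `id_b` (provenance).
#' @export
extractTransformations <- function(mps, directed = FALSE) {
  stopifnot(is(mps, "MatchedPairSet"))
  df <- pairs_df(mps)
  out <- data.frame(lhs = df$variable_a, rhs = df$variable_b,
                    id_a = df$id_a, id_b = df$id_b)
  if (directed) {
    out <- rbind(out, data.frame(lhs = df$variable_b, rhs = df$variable_a,
                                 id_a = df$id_b, id_b = df$id_a))
  }
  unique(out)
}

#' Apply a fragment-swap transformation to a molecule
#'
#' Enumerates every single-cut split of the molecule; wherever the variable
#' side equals `lhs` (as a canonical fragment), the constant side is rejoined
#' with `rhs`. Symmetry-equivalent sites are enumerated and the products
#' deduplicated by canonical form. An empty result means `lhs` does not occur.
#'
#' @param lhs,rhs canonical one-marker fragment SMILES.
#' @param smiles the molecule to transform.
#' @return character vector of distinct canonical product SMILES.
#' @export
applyTransformation <- function(lhs, rhs, smiles) {
  mol <- parse_smiles(smiles)
  cuts <- .enumerate_cuts(mol)
  prods <- character(0)
  for (ct in cuts) {
    if (ct$smiles_i == lhs)
      prods <- c(prods, join_fragments(ct$smiles_j, rhs))
    if (ct$smiles_j == lhs)
      prods <- c(prods, join_fragments(ct$smiles_i, rhs))
  }
  unique(prods)
}
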