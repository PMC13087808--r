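## Circular (Morgan/ECFP-style) fingerprints, radius 2 by default, folded to a
## fixed bit length. Used for Tanimoto nearest-neighbour searches in the
## similarity-transfer evaluation and the novelty filter. The hashing scheme
## is deterministic and self-contained; identical molecules always give
## identical fingerprints and the usual ECFP4 radius/size conventions apply.

.atom_init_ids <- function(mol) {
  ringb <- .ring_bonds(mol)
  in_ring <- rep(FALSE, length(mol$elem))
  if (length(ringb)) {
    in_ring[mol$bonds[ringb, "i"]] <- TRUE
    in_ring[mol$bonds[ringb, "j"]] <- TRUE
  }
  deg <- .mol_degree(mol)
  vapply(seq_along(mol$elem), function(a) {
    int_hash32(c(match(mol$elem[a], c(names(.VALENCES))), deg[a],
                 mol$charge[a] + 10L, mol$nH[a], as.integer(mol$arom[a]),
                 as.integer(in_ring[a])))
  }, numeric(1))
}

morgan_fp_mol <- function(mol, radius = 2L, nbits = 2048L) {
  ids <- .atom_init_ids(mol)
  inc <- .mol_incidence(mol)
  bc <- .bond_code(mol)
  all_ids <- ids
  for (r in seq_len(radius)) {
    new_ids <- ids
    for (a in seq_along(ids)) {
      if (!length(inc[[a]])) next
      nb <- vapply(inc[[a]], function(b)
        bc[b] * 4294967296 + ids[.other_end(mol, b, a)], numeric(1))
      new_ids[a] <- int_hash32(c(r, ids[a], sort(nb)))
    }
    ids <- new_ids
    all_ids <- c(all_ids, ids)
  }
  sort(unique(as.integer(all_ids %% nbits)))
}

#' Circular fingerprints
#'
#' Computes folded circular substructure fingerprints (the radius-2 default is
#' the common equivalent of ECFP4). Bits are returned as sorted 0-based
#' positions.
#'
#' @param smiles character vector of SMILES.
#' @param radius neighbourhood radius (default 2).
#' @param nBits folded length (default 2048).
#' @return list of integer vectors (one per molecule).
#' @export
morganFingerprint <- function(smiles, radius = 2L, nBits = 2048L) {
  lapply(smiles, function(s) morgan_fp_mol(parse_smiles(s), radius, nBits))
}

#' Tanimoto similarity between fingerprint sets
#'
#' @param fpsA,fpsB lists of bit-position vectors from [morganFingerprint()].
#' @return numeric matrix `length(fpsA)` x `length(fpsB)` of Tanimoto
#'   coefficients (1 for identical bit sets; 0 when either is empty).
#' @export
tanimotoMatrix <- function(fpsA, fpsB) {
  nbits <- max(c(unlist(fpsA), unlist(fpsB), 0L)) + 1L
  mk <- function(fps) {
    m <- matrix(0, nrow = length(fps), ncol = nbits)
    for (i in seq_along(fps)) m[i, fps[[i]] + 1L] <- 1
    m
  }
  A <- mk(fpsA); B <- mk(fpsB)
  inter <- A %*% t(B)
  na <- rowSums(A); nb <- rowSums(B)
  uni <- outer(na, nb, "+") - inter
  out <- ifelse(uni > 0, inter / uni, 0)
  dimnames(out) <- list(names(fpsA), names(fpsB))
  out
}

#' @rdname tanimotoMatrix
#' @param fpA,fpB single fingerprints (integer bit-position vectors).
#' @export
tanimotoSimilarity <- function(fpA, fpB) {
  inter <- length(intersect(fpA, fpB))
  uni <- length(union(fpA, fpB))
  if (uni == 0L) 0 else inter / uni
}
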