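## Training-set augmentation.
##
## Directed pairs are expanded into (source SELFIES, target SELFIES) training
## examples by drawing randomized SMILES for both molecules. The number of
## augmentations per pair is either uniform or weighted by the pair's score
## difference,
##
##   n_i = floor( (d_i - d_min) / (d_max - d_min) * n ),
##
## so the most-improving pair receives exactly n copies and the least
## improving receives 0 (and is dropped from training). When every score
## difference is equal the formula is undefined and every pair falls back to
## one augmentation.

#' Score-difference-weighted augmentation counts
#'
#' @param score_diffs non-negative score differences, one per directed pair.
#' @param n scale: the maximal-difference pair gets exactly `n` augmentations.
#' @return integer counts, monotone non-decreasing in `score_diffs`,
#'   `0` at the minimum and `n` at the maximum.
#' @export
weightedCounts <- function(score_diffs, n) {
  stopifnot(length(score_diffs) >= 1L, all(is.finite(score_diffs)), n >= 1L)
  dmin <- min(score_diffs); dmax <- max(score_diffs)
  if (dmax == dmin) {
    warning("all score differences equal; falling back to 1 augmentation per pair")
    return(rep(1L, length(score_diffs)))
  }
  as.integer(floor((score_diffs - dmin) / (dmax - dmin) * n))
}

#' Expand directed pairs into SELFIES training examples
#'
#' Pair `i` contributes `counts[i]` examples. Source and target randomized
#' SMILES are drawn independently (distinct encodings per molecule; a
#' molecule admitting fewer distinct encodings than requested contributes its
#' maximum, with a warning). Examples are returned unshuffled; see
#' [shuffleExamples()].
#'
#' @param dps a [DirectedPairSet].
#' @param ms the [MoleculeSet] resolving pair member ids.
#' @param counts integer vector aligned with the directed pairs.
#' @param seed integer seed.
#' @return data.frame with columns `source_selfies`, `target_selfies`,
#'   `source_id`, `target_id`, `pair_index`.
#' @export
augmentPairs <- function(dps, ms, counts, seed = 1L) {
  stopifnot(is(dps, "DirectedPairSet"), is(ms, "MoleculeSet"))
  pr <- directedPairs(dps)
  stopifnot(length(counts) == nrow(pr))
  df <- molecules(ms)
  ## parse each molecule once; variants are emitted straight from the graph
  mol_cache <- new.env(parent = emptyenv())
  mol_of <- function(id) {
    m <- get0(id, envir = mol_cache, inherits = FALSE)
    if (is.null(m)) {
      m <- parse_smiles(df$smiles[match(id, df$id)])
      assign(id, m, envir = mol_cache)
    }
    m
  }
  rows <- vector("list", nrow(pr))
  for (k in seq_len(nrow(pr))) {
    ct <- counts[k]
    if (ct < 1L) next
    src <- .random_selfies_distinct(mol_of(pr$source_id[k]), ct,
                                    derive_seed(seed, paste0("aug-src-", k)))
    tgt <- .random_selfies_distinct(mol_of(pr$target_id[k]), ct,
                                    derive_seed(seed, paste0("aug-tgt-", k)))
    m <- min(length(src), length(tgt))
    if (m < ct)
      warning(sprintf("pair %d (%s -> %s): only %d of %d distinct encodings",
                      k, pr$source_id[k], pr$target_id[k], m, ct))
    rows[[k]] <- data.frame(
      source_selfies = src[seq_len(m)], target_selfies = tgt[seq_len(m)],
      source_id = pr$source_id[k], target_id = pr$target_id[k], pair_index = k)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(source_selfies = character(), target_selfies = character(),
                      source_id = character(), target_id = character(),
                      pair_index = integer())
  rownames(out) <- NULL
  out
}

#' Shuffle training examples
#'
#' Random permutation of the example rows (deterministic per seed) so each
#' training batch mixes transformations from many pairs.
#'
#' @param examples data.frame from [augmentPairs()].
#' @param seed integer seed.
#' @return the permuted data.frame.
#' @export
shuffleExamples <- function(examples, seed = 1L) {
  if (nrow(examples) <= 1L) return(examples)
  rng <- local_rng(derive_seed(seed, "shuffle"))
  out <- examples[rng$sample_int(nrow(examples)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a parallel corpus
#'
#' Writes aligned source/target line files, one example per line (the
#' conventional parallel-corpus layout).
#'
#' @param examples data.frame from [augmentPairs()].
#' @param src_path,tgt_path output files.
#' @export
writeParallelCorpus <- function(examples, src_path, tgt_path) {
  writeLines(examples$source_selfies, src_path)
  writeLines(examples$target_selfies, tgt_path)
  invisible(c(src_path, tgt_path))
}

#' Inference-time input representations
#'
#' Each molecule contributes its canonical SMILES plus `k` randomized
#' variants (k + 1 representations in total), all converted to SELFIES, with
#' no score bias.
#'
#' @param ms a [MoleculeSet].
#' @param k number of randomized variants per molecule (default 5).
#' @param seed integer seed.
#' @return data.frame with columns `id`, `selfies`.
#' @export
inferenceRepresentations <- function(ms, k = 5L, seed = 1L) {
  df <- molecules(ms)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    mol <- parse_smiles(df$smiles[i])
    variants <- c(smilesToSelfies(df$smiles[i]),
                  .random_selfies_distinct(mol, k,
                                           derive_seed(seed, paste0("inf-", df$id[i]))))
    data.frame(id = df$id[i], selfies = variants)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
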