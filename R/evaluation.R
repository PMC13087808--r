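## Evaluation protocols.
##
## Retrospective: hold out the top molecules by potency, fine-tune on the
## remainder, predict from a stratified draw of weak/inactive molecules, then
## count recovered holdout molecules and transfer potencies from
## fingerprint-nearest known compounds. Prospective: deduplicate predictions,
## and pool measured predictions with the training set under the rank-sum
## score.

#' Retrospective train / holdout / inference split
#'
#' The `n_holdout` most potent molecules form the holdout set (their IC50
#' must be strictly better than every other molecule's); `n_inference`
#' molecules - exactly `n_inference_inactive` of them inactive - are drawn
#' uniformly at random (seeded) from the bottom `bottom_frac` of the series
#' by potency; the remainder is the training set.
#'
#' @param ms a [MoleculeSet] with IC50 for every molecule.
#' @param seed integer seed for the stratified draw.
#' @param n_holdout holdout size (default 20).
#' @param n_inference inference-input count (default 30).
#' @param n_inference_inactive inactives among the inference inputs (10).
#' @param bottom_frac potency stratum for the inference draw (default 0.4).
#' @return list of class `"RetroSplit"` with character id vectors `train`,
#'   `holdout`, `inference`.
#' @export
makeRetrospectiveSplit <- function(ms, seed = 1L, n_holdout = 20L,
                                   n_inference = 30L,
                                   n_inference_inactive = 10L,
                                   bottom_frac = 0.4) {
  df <- molecules(ms)
  stopifnot(!anyNA(df$ic50_molar))
  n <- nrow(df)
  if (n < n_holdout + n_inference + 1L)
    stop(sprintf("need more than %d molecules, got %d", n_holdout + n_inference, n))
  ord <- order(df$ic50_molar)                  # best (lowest IC50) first
  holdout <- df$id[ord[seq_len(n_holdout)]]
  cut_val <- df$ic50_molar[ord[n_holdout]]
  if (any(df$ic50_molar[ord[-seq_len(n_holdout)]] <= cut_val))
    stop("holdout potencies are not strictly better than the remainder (ties at the boundary)")

  n_bottom <- floor(bottom_frac * n)
  bottom <- df[ord[seq.int(n - n_bottom + 1L, n)], , drop = FALSE]
  inact <- bottom$id[bottom$is_inactive]
  act <- bottom$id[!bottom$is_inactive]
  if (length(inact) < n_inference_inactive)
    stop(sprintf("only %d inactive molecules in the bottom stratum, %d required",
                 length(inact), n_inference_inactive))
  n_act <- n_inference - n_inference_inactive
  if (length(act) < n_act)
    stop(sprintf("only %d active molecules in the bottom stratum, %d required",
                 length(act), n_act))
  rng <- local_rng(derive_seed(seed, "retro-split"))
  inference <- c(inact[rng$sample_int(length(inact), n_inference_inactive)],
                 act[rng$sample_int(length(act), n_act)])
  train <- setdiff(df$id, c(holdout, inference))
  structure(list(train = train, holdout = holdout, inference = inference),
            class = "RetroSplit")
}

#' @export
print.RetroSplit <- function(x, ...) {
  cat(sprintf("RetroSplit: %d train / %d holdout / %d inference\n",
              length(x$train), length(x$holdout), length(x$inference)))
  invisible(x)
}

#' Deduplicate predictions
#'
#' @param ps a [PredictionSet] (or character vector of canonical SMILES).
#' @return named integer vector: canonical SMILES -> prediction count (empty
#'   generations are counted under the `""` key so that counts conserve the
#'   record total).
#' @export
dedupPredictions <- function(ps) {
  smi <- if (is(ps, "PredictionSet")) predictions(ps)$smiles else ps
  if (!length(smi)) return(integer(0))
  tab <- table(smi)
  out <- as.integer(tab)
  names(out) <- names(tab)
  sort(out, decreasing = TRUE)
}

#' Holdout recovery counts
#'
#' How often each held-out molecule was regenerated by the model.
#'
#' @param counts named counts from [dedupPredictions()].
#' @param holdout a [MoleculeSet] (or character vector of canonical SMILES).
#' @return named integer vector, one count per holdout molecule (0 = never
#'   predicted).
#' @export
holdoutRecovery <- function(counts, holdout) {
  smi <- if (is(holdout, "MoleculeSet")) molecules(holdout)$smiles else holdout
  ids <- if (is(holdout, "MoleculeSet")) molecules(holdout)$id else smi
  out <- counts[smi]
  out[is.na(out)] <- 0L
  names(out) <- ids
  out
}

#' Similarity-based potency transfer
#'
#' Each predicted molecule is assigned the IC50 of its most similar reference
#' molecule (Tanimoto on circular fingerprints, radius `fp_radius`) when that
#' similarity reaches `threshold`; exact matches have similarity 1. Ties for
#' most-similar are broken toward the lowest reference IC50.
#'
#' @param pred_smiles character vector of canonical prediction SMILES.
#' @param reference a [MoleculeSet] with IC50 values.
#' @param threshold minimum similarity for an assignment (default 0.8).
#' @param fp_radius fingerprint radius (default 2).
#' @param nBits fingerprint length (default 2048).
#' @return data.frame with columns `smiles`, `best_ref_id`, `similarity`,
#'   `ic50_assigned` (NA below threshold).
#' @export
similarityTransfer <- function(pred_smiles, reference, threshold = 0.8,
                               fp_radius = 2L, nBits = 2048L) {
  stopifnot(threshold >= 0, threshold <= 1)
  ref <- molecules(reference)
  pred_smiles <- pred_smiles[nzchar(pred_smiles)]
  if (!length(pred_smiles))
    return(data.frame(smiles = character(), best_ref_id = character(),
                      similarity = numeric(), ic50_assigned = numeric()))
  fp_p <- morganFingerprint(pred_smiles, fp_radius, nBits)
  fp_r <- morganFingerprint(ref$smiles, fp_radius, nBits)
  sim <- tanimotoMatrix(fp_p, fp_r)
  best_id <- character(length(pred_smiles))
  best_sim <- numeric(length(pred_smiles))
  for (i in seq_along(pred_smiles)) {
    s <- sim[i, ]
    mx <- max(s)
    tied <- which(s >= mx - 1e-12)
    j <- tied[which.min(ref$ic50_molar[tied])]
    best_id[i] <- ref$id[j]
    best_sim[i] <- mx
  }
  data.frame(smiles = pred_smiles, best_ref_id = best_id,
             similarity = best_sim,
             ic50_assigned = ifelse(best_sim >= threshold,
                                    ref$ic50_molar[match(best_id, ref$id)],
                                    NA_real_))
}

#' Enrichment of transferred potencies over the training distribution
#'
#' Log10-binned histograms (one bin per decade, with the inactive surrogate
#' IC50 pinned in its own terminal bin) plus a shift statistic: the
#' difference in median log10(IC50) between assignments and training values.
#' Negative shift = enrichment toward potency. A rank-based two-sample test
#' p-value (Wilcoxon) is reported alongside.
#'
#' @param assigned numeric assigned IC50 values (molar; NA entries dropped).
#' @param training numeric training IC50 values (molar).
#' @param inactive_ic50 the surrogate inactive IC50 (its own bin).
#' @return list with `hist_assigned`, `hist_training` (data.frames bin /
#'   count), `shift` (median log10 difference), `p_value`, `n_assigned`; or a
#'   list with `message` when nothing was assignable.
#' @export
enrichmentSummary <- function(assigned, training, inactive_ic50 = 1e-3) {
  assigned <- assigned[!is.na(assigned)]
  if (!length(assigned))
    return(list(message = "no assignable predictions", n_assigned = 0L))
  brk <- c(seq(-9.5, -3.5, by = 1), log10(inactive_ic50) + 1e-9)
  binit <- function(x) {
    lx <- pmax(log10(x), -9.5 + 1e-9)
    data.frame(bin = levels(cut(lx, brk)),
               count = as.integer(table(cut(lx, brk))))
  }
  shift <- stats::median(log10(assigned)) - stats::median(log10(training))
  pv <- suppressWarnings(
    stats::wilcox.test(log10(assigned), log10(training),
                       alternative = "less")$p.value)
  list(hist_assigned = binit(assigned), hist_training = binit(training),
       shift = shift, p_value = pv, n_assigned = length(assigned))
}

#' Rank predictions against the training set
#'
#' Pools measured predictions with the training set, recomputes the rank-sum
#' score over the pooled table, and reports each prediction's position (1 =
#' best; ties share their block's position).
#'
#' @param predicted a [MoleculeSet] of predictions with measured IC50 and
#'   half-life.
#' @param training the training [MoleculeSet].
#' @return list with `table` (the pooled [ScoreTable]) and
#'   `prediction_ranks` (data.frame `id`, `position`, `score`).
#' @export
rankPredictions <- function(predicted, training) {
  pd <- molecules(predicted); td <- molecules(training)
  if (anyNA(pd$ic50_molar) || anyNA(pd$t_half_min))
    stop("predictions must carry both measured properties")
  pooled <- MoleculeSet(c(td$id, pd$id), c(td$smiles, pd$smiles),
                        c(td$ic50_molar, pd$ic50_molar),
                        c(td$t_half_min, pd$t_half_min),
                        c(td$is_inactive, pd$is_inactive),
                        inactiveIC50 = training@inactiveIC50,
                        canonicalize = FALSE)
  st <- scoreMolecules(pooled, "multi")
  tab <- scores_df(st)
  pos <- as.integer(rank(-tab$score, ties.method = "min"))
  pr <- data.frame(id = pd$id, position = pos[match(pd$id, tab$id)],
                   score = tab$score[match(pd$id, tab$id)])
  list(table = st, prediction_ranks = pr)
}

#' Ligand efficiency
#'
#' LE = 1.37 x pIC50 / heavy-atom count, in kcal/mol per heavy atom (the
#' 1.37 kcal/mol factor converts one log10 unit of affinity to binding free
#' energy at 298 K).
#'
#' @param ic50_molar IC50 in molar units (> 0).
#' @param heavy_atoms heavy-atom count (>= 1).
#' @return numeric ligand efficiency.
#' @export
ligandEfficiency <- function(ic50_molar, heavy_atoms) {
  stopifnot(all(ic50_molar > 0), all(heavy_atoms >= 1))
  1.37 * (-log10(ic50_molar)) / heavy_atoms
}

#' Heavy-atom count of a molecule
#'
#' @param smiles character vector of SMILES.
#' @return integer heavy-atom counts.
#' @export
countHeavyAtoms <- function(smiles) {
  vapply(smiles, function(s) heavy_atom_count(parse_smiles(s)), integer(1),
         USE.NAMES = FALSE)
}
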