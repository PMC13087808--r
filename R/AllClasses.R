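## Central S4 containers. All are thin, validity-checked wrappers around data
## frames so that every pipeline stage has a typed input/output surface and
## serializes naturally to the plain-text formats written by the pipeline.

#' @import methods
NULL

#' MoleculeSet: a congeneric series with measured properties
#'
#' Holds one compound per row: identifier, canonical stereochemistry-free
#' SMILES, IC50 (molar), microsomal half-life (minutes) and an inactive flag.
#' Inactive compounds carry the fixed surrogate IC50 (`inactiveIC50`, default
#' 1e-3 M, i.e. 1 mM).
#'
#' @slot records data.frame with columns `id`, `smiles`, `ic50_molar`,
#'   `t_half_min`, `is_inactive`.
#' @slot inactiveIC50 the surrogate IC50 assigned to inactives (molar).
#' @export
setClass("MoleculeSet",
  representation(records = "data.frame", inactiveIC50 = "numeric"),
  prototype(records = data.frame(id = character(), smiles = character(),
                                 ic50_molar = numeric(), t_half_min = numeric(),
                                 is_inactive = logical()),
            inactiveIC50 = 1e-3))

setValidity("MoleculeSet", function(object) {
  df <- object@records
  need <- c("id", "smiles", "ic50_molar", "t_half_min", "is_inactive")
  if (!all(need %in% names(df)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(df$id)) return("molecule ids must be unique")
  if (anyDuplicated(df$smiles)) return("canonical SMILES must be distinct")
  if (length(object@inactiveIC50) != 1L || object@inactiveIC50 <= 0)
    return("inactiveIC50 must be a single positive number")
  bad <- df$is_inactive & (is.na(df$ic50_molar) |
                           df$ic50_molar != object@inactiveIC50)
  if (any(bad))
    return(sprintf("inactive molecules must carry IC50 == %g M: %s",
                   object@inactiveIC50, paste(df$id[bad], collapse = ", ")))
  ok <- !is.na(df$ic50_molar) & df$ic50_molar <= 0
  if (any(ok)) return("ic50_molar must be positive where present")
  ok <- !is.na(df$t_half_min) & df$t_half_min <= 0
  if (any(ok)) return("t_half_min must be positive where present")
  TRUE
})

#' Construct a MoleculeSet
#'
#' SMILES are canonicalized (stereochemistry removed, largest fragment kept)
#' on construction.
#'
#' @param id character identifiers (unique).
#' @param smiles SMILES strings.
#' @param ic50_molar numeric IC50 values in molar units (NA allowed).
#' @param t_half_min numeric microsomal half-lives in minutes (NA allowed).
#' @param is_inactive logical inactive flags.
#' @param inactiveIC50 surrogate IC50 for inactives (default 1 mM).
#' @param canonicalize set FALSE when `smiles` are already canonical.
#' @return a `MoleculeSet`.
#' @export
MoleculeSet <- function(id, smiles, ic50_molar = NA_real_, t_half_min = NA_real_,
                        is_inactive = FALSE, inactiveIC50 = 1e-3,
                        canonicalize = TRUE) {
  n <- length(smiles)
  df <- data.frame(
    id = as.character(id),
    smiles = if (canonicalize) canonicalizeSmiles(smiles) else as.character(smiles),
    ic50_molar = rep_len(as.numeric(ic50_molar), n),
    t_half_min = rep_len(as.numeric(t_half_min), n),
    is_inactive = rep_len(as.logical(is_inactive), n),
    stringsAsFactors = FALSE
  )
  new("MoleculeSet", records = df, inactiveIC50 = inactiveIC50)
}

#' @describeIn MoleculeSet records as a data.frame
#' @param x a MoleculeSet.
#' @export
molecules <- function(x) x@records

#' @describeIn MoleculeSet number of molecules
#' @export
nMolecules <- function(x) nrow(x@records)

#' @describeIn MoleculeSet surrogate IC50 assigned to inactives (molar)
#' @export
inactiveIC50 <- function(x) x@inactiveIC50

setMethod("show", "MoleculeSet", function(object) {
  df <- object@records
  cat(sprintf("MoleculeSet with %d molecules (%d inactive at %g M)\n",
              nrow(df), sum(df$is_inactive), object@inactiveIC50))
  if (nrow(df)) {
    cat(sprintf("  IC50 range: %.3g - %.3g M; t1/2 range: %.3g - %.3g min\n",
                suppressWarnings(min(df$ic50_molar, na.rm = TRUE)),
                suppressWarnings(max(df$ic50_molar, na.rm = TRUE)),
                suppressWarnings(min(df$t_half_min, na.rm = TRUE)),
                suppressWarnings(max(df$t_half_min, na.rm = TRUE))))
  }
})

setMethod("[", "MoleculeSet", function(x, i, j, ..., drop = FALSE) {
  new("MoleculeSet", records = x@records[i, , drop = FALSE],
      inactiveIC50 = x@inactiveIC50)
})

#' MatchedPairSet: matched molecular pairs on a shared constant part
#'
#' One row per unordered pair of molecules that share an identical constant
#' fragment and differ in their variable fragments.
#'
#' @slot pairs data.frame with columns `id_a`, `id_b`, `constant`,
#'   `variable_a`, `variable_b`.
#' @export
setClass("MatchedPairSet", representation(pairs = "data.frame"))

setValidity("MatchedPairSet", function(object) {
  df <- object@pairs
  need <- c("id_a", "id_b", "constant", "variable_a", "variable_b")
  if (!all(need %in% names(df)))
    return(paste("pairs must have columns:", paste(need, collapse = ", ")))
  if (any(df$id_a == df$id_b)) return("self-pairs are not allowed")
  if (any(df$variable_a == df$variable_b))
    return("pair members must differ in their variable fragment")
  TRUE
})

#' @describeIn MatchedPairSet pairs as a data.frame
#' @param x a MatchedPairSet.
#' @export
pairs_df <- function(x) x@pairs

setMethod("show", "MatchedPairSet", function(object) {
  cat(sprintf("MatchedPairSet with %d pairs over %d constant parts\n",
              nrow(object@pairs), length(unique(object@pairs$constant))))
})

#' DirectedPairSet: property-ordered (worse -> better) pairs
#'
#' @slot pairs data.frame with columns `source_id`, `target_id`, `score_diff`,
#'   `constant`, `variable_source`, `variable_target`; `score_diff` is always
#'   non-negative (score(target) - score(source)).
#' @export
setClass("DirectedPairSet", representation(pairs = "data.frame"))

setValidity("DirectedPairSet", function(object) {
  df <- object@pairs
  need <- c("source_id", "target_id", "score_diff")
  if (!all(need %in% names(df)))
    return(paste("pairs must have columns:", paste(need, collapse = ", ")))
  if (any(df$score_diff < 0)) return("score_diff must be non-negative")
  TRUE
})

#' @describeIn DirectedPairSet directed pairs as a data.frame
#' @param x a DirectedPairSet.
#' @export
directedPairs <- function(x) x@pairs

setMethod("show", "DirectedPairSet", function(object) {
  cat(sprintf("DirectedPairSet with %d directed pairs (%d ties kept in both orders)\n",
              nrow(object@pairs), sum(object@pairs$score_diff == 0) %/% 2L))
})

#' ScoreTable: per-molecule ranks and final score
#'
#' Ranks run from 1 (worst) to N (best); tied values share the minimum rank of
#' their block. The multiobjective score is the unweighted sum of the potency
#' and stability ranks; single-objective scoring uses the potency rank alone.
#'
#' @slot table data.frame with columns `id`, `potency_rank`, `stability_rank`
#'   (NA in single-objective mode) and `score`.
#' @export
setClass("ScoreTable", representation(table = "data.frame"))

setValidity("ScoreTable", function(object) {
  df <- object@table
  need <- c("id", "potency_rank", "stability_rank", "score")
  if (!all(need %in% names(df)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(df$id)) return("ids must be unique")
  TRUE
})

#' @describeIn ScoreTable scores as a data.frame
#' @param x a ScoreTable.
#' @export
scores_df <- function(x) x@table

setMethod("show", "ScoreTable", function(object) {
  df <- object@table
  mode <- if (all(is.na(df$stability_rank))) "single-objective (potency)"
          else "multiobjective (potency + stability rank sum)"
  cat(sprintf("ScoreTable for %d molecules, %s; score range [%g, %g]\n",
              nrow(df), mode, min(df$score), max(df$score)))
})

#' PredictionSet: sampled model outputs
#'
#' @slot records data.frame with columns `input_id`, `epoch`, `smiles`
#'   (canonical form, `""` for empty generations) and `selfies` (raw sampled
#'   token string).
#' @export
setClass("PredictionSet", representation(records = "data.frame"))

setValidity("PredictionSet", function(object) {
  need <- c("input_id", "epoch", "smiles", "selfies")
  if (!all(need %in% names(object@records)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  TRUE
})

#' @describeIn PredictionSet prediction records as a data.frame
#' @param x a PredictionSet.
#' @export
predictions <- function(x) x@records

setMethod("show", "PredictionSet", function(object) {
  df <- object@records
  cat(sprintf("PredictionSet: %d records, %d unique molecules, %d empty generations\n",
              nrow(df), length(unique(df$smiles[nzchar(df$smiles)])),
              sum(!nzchar(df$smiles))))
})
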