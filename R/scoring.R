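## Scoring and pair orientation.
##
## Molecules are ranked per property (1 = worst, N = best, ties share the
## minimum rank of their block); the multiobjective score is the unweighted
## rank sum over potency and metabolic stability, and matched pairs are
## oriented worse -> better so the model only sees property-improving
## transformations. Tied pairs are kept in both orders.

#' Rank a property
#'
#' Best value receives rank N, worst rank 1; tied values share the minimum
#' rank of the tied block (competition ranking), which keeps rank-sum score
#' differences integral.
#'
#' @param values numeric vector (all finite).
#' @param direction `"higher_is_better"` (e.g. half-life) or
#'   `"lower_is_better"` (e.g. IC50).
#' @param ids optional identifiers used in error messages.
#' @return integer ranks.
#' @export
rankProperty <- function(values, direction = c("higher_is_better", "lower_is_better"),
                         ids = NULL) {
  direction <- match.arg(direction)
  bad <- !is.finite(values)
  if (any(bad)) {
    who <- if (!is.null(ids)) paste(ids[bad], collapse = ", ")
           else paste(which(bad), collapse = ", ")
    stop(sprintf("non-finite property value for: %s", who))
  }
  x <- if (direction == "higher_is_better") values else -values
  as.integer(rank(x, ties.method = "min"))
}

#' Score a molecule series
#'
#' `objective = "multi"` requires both IC50 and half-life and scores by the
#' unweighted sum of the two ranks (range 2..2N); `objective = "potency"`
#' scores by the potency rank alone (the single-objective retrospective
#' protocol).
#'
#' @param ms a [MoleculeSet].
#' @param objective `"multi"` or `"potency"`.
#' @return a [ScoreTable].
#' @export
scoreMolecules <- function(ms, objective = c("multi", "potency")) {
  objective <- match.arg(objective)
  df <- molecules(ms)
  miss <- is.na(df$ic50_molar)
  if (any(miss))
    stop(sprintf("molecules lacking IC50: %s", paste(df$id[miss], collapse = ", ")))
  pot <- rankProperty(df$ic50_molar, "lower_is_better", df$id)
  if (objective == "multi") {
    miss <- is.na(df$t_half_min)
    if (any(miss))
      stop(sprintf("molecules lacking half-life: %s", paste(df$id[miss], collapse = ", ")))
    sta <- rankProperty(df$t_half_min, "higher_is_better", df$id)
    tab <- data.frame(id = df$id, potency_rank = pot, stability_rank = sta,
                      score = pot + sta)
  } else {
    tab <- data.frame(id = df$id, potency_rank = pot,
                      stability_rank = NA_integer_, score = as.numeric(pot))
  }
  new("ScoreTable", table = tab)
}

#' Orient matched pairs worse -> better
#'
#' Pairs with unequal scores yield one directed pair from the worse to the
#' better molecule; tied pairs are emitted in both orders (score_diff 0), as
#' in undirected base-model training.
#'
#' @param mps a [MatchedPairSet].
#' @param st a [ScoreTable] covering every pair member.
#' @return a [DirectedPairSet].
#' @export
orientPairs <- function(mps, st) {
  stopifnot(is(mps, "MatchedPairSet"), is(st, "ScoreTable"))
  pr <- pairs_df(mps)
  sc <- scores_df(st)
  score <- stats::setNames(sc$score, sc$id)
  missing_ids <- setdiff(unique(c(pr$id_a, pr$id_b)), sc$id)
  if (length(missing_ids))
    stop(sprintf("no score for pair member(s): %s", paste(missing_ids, collapse = ", ")))
  empty <- data.frame(source_id = character(), target_id = character(),
                      score_diff = numeric(), constant = character(),
                      variable_source = character(), variable_target = character())
  if (!nrow(pr)) return(new("DirectedPairSet", pairs = empty))
  rows <- vector("list", nrow(pr))
  for (k in seq_len(nrow(pr))) {
    sa <- score[[pr$id_a[k]]]; sb <- score[[pr$id_b[k]]]
    fwd <- data.frame(source_id = pr$id_a[k], target_id = pr$id_b[k],
                      score_diff = sb - sa, constant = pr$constant[k],
                      variable_source = pr$variable_a[k],
                      variable_target = pr$variable_b[k])
    rev <- data.frame(source_id = pr$id_b[k], target_id = pr$id_a[k],
                      score_diff = sa - sb, constant = pr$constant[k],
                      variable_source = pr$variable_b[k],
                      variable_target = pr$variable_a[k])
    rows[[k]] <- if (sa < sb) fwd else if (sa > sb) rev else rbind(fwd, rev)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  new("DirectedPairSet", pairs = out)
}

#' @describeIn scoreMolecules write a ScoreTable as CSV
#' @param x a ScoreTable.
#' @param path output file.
#' @export
writeScoreTable <- function(x, path) {
  stopifnot(is(x, "ScoreTable"))
  utils::write.csv(scores_df(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
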