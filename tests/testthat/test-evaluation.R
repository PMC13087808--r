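# Retrospective split, deduplication, similarity transfer, enrichment,
# prediction ranking and ligand efficiency.

test_that("retrospective split partitions with the stated counts", {
  ms <- generateSeries(seriesSpec(n_molecules = 120L, n_inactive = 20L, seed = 41L))
  sp <- makeRetrospectiveSplit(ms, seed = 5, n_holdout = 20L, n_inference = 30L,
                               n_inference_inactive = 10L)
  df <- molecules(ms)
  ## partition law
  expect_setequal(c(sp$train, sp$holdout, sp$inference), df$id)
  expect_equal(length(sp$train) + length(sp$holdout) + length(sp$inference), 120L)
  expect_length(sp$holdout, 20L)
  expect_length(sp$inference, 30L)
  expect_equal(sum(df$is_inactive[match(sp$inference, df$id)]), 10L)
  ## holdout strictly more potent than everything else
  expect_lt(max(df$ic50_molar[match(sp$holdout, df$id)]),
            min(df$ic50_molar[match(c(sp$train, sp$inference), df$id)]))
  ## inference molecules come from the bottom 40% stratum
  bottom_ids <- df$id[order(df$ic50_molar, decreasing = TRUE)[seq_len(floor(0.4 * 120))]]
  expect_true(all(sp$inference %in% bottom_ids))
  ## determinism
  expect_identical(sp, makeRetrospectiveSplit(ms, seed = 5, n_holdout = 20L,
                                              n_inference = 30L,
                                              n_inference_inactive = 10L))
  ## insufficient inactives is an explicit error
  expect_error(makeRetrospectiveSplit(ms, seed = 5, n_inference_inactive = 50L),
               "inactive")
})

test_that("prediction deduplication conserves totals", {
  rec <- data.frame(input_id = "x", epoch = 1L,
                    smiles = c("CCO", "CCO", "CCC", "", "CCO"),
                    selfies = "")
  ps <- new("PredictionSet", records = rec)
  cnt <- dedupPredictions(ps)
  expect_equal(sum(cnt), 5L)
  expect_equal(unname(cnt[["CCO"]]), 3L)
  expect_equal(length(dedupPredictions(character(0))), 0L)
})

test_that("holdout recovery counts known molecules and zeros the rest", {
  cnt <- c(CCO = 6L, CCC = 2L)
  hold <- MoleculeSet(c("h1", "h2"), c("CCO", "CCCCO"))
  rec <- holdoutRecovery(cnt, hold)
  expect_equal(unname(rec["h1"]), 6L)
  expect_equal(unname(rec["h2"]), 0L)
  ## order invariance
  rec2 <- holdoutRecovery(cnt, hold[2:1])
  expect_equal(sort(rec), sort(rec2))
})

test_that("similarity transfer assigns by nearest reference above threshold", {
  ms <- small_series()
  df <- molecules(ms)
  ## a prediction identical to a reference: similarity 1, that IC50 assigned
  tr <- similarityTransfer(df$smiles[3], ms, threshold = 0.8)
  expect_equal(tr$similarity, 1)
  expect_equal(tr$ic50_assigned, df$ic50_molar[3])
  ## structurally unrelated molecule: low similarity, unassigned at 0.8
  tr2 <- similarityTransfer("C", ms, threshold = 0.8)
  expect_true(is.na(tr2$ic50_assigned))
  expect_lt(tr2$similarity, 0.8)
})

test_that("raising the threshold never gains assignments; 0 and 1 are extreme", {
  ms <- small_series()
  preds <- unique(unlist(lapply(molecules(ms)$smiles[1:6], function(s) {
    tr <- extractTransformations(buildPairs(ms))
    applyTransformation(tr$lhs[1], tr$rhs[1], s)
  })))
  preds <- c(preds, molecules(ms)$smiles[1], "C")
  n_assigned <- vapply(c(0, 0.75, 0.8, 0.85, 0.9, 1), function(th)
    sum(!is.na(similarityTransfer(preds, ms, threshold = th)$ic50_assigned)),
    numeric(1))
  expect_true(all(diff(n_assigned) <= 0))
  expect_equal(n_assigned[1], length(preds))          # threshold 0: all assigned
  ## threshold 1: only exact matches
  expect_equal(n_assigned[6], sum(preds %in% molecules(ms)$smiles))
})

test_that("enrichment shift is zero for identical and negative for potent sets", {
  train <- c(1e-8, 1e-7, 1e-6, 1e-5, 1e-3)
  same <- enrichmentSummary(train, train)
  expect_equal(same$shift, 0)
  best <- enrichmentSummary(rep(min(train), 5), train)
  expect_lt(best$shift, 0)
  expect_equal(best$shift, log10(min(train)) - stats::median(log10(train)))
  none <- enrichmentSummary(rep(NA_real_, 3), train)
  expect_match(none$message, "no assignable")
  ## histograms cover the inactive bin
  expect_equal(sum(same$hist_assigned$count), length(train))
})

test_that("prediction ranking pools and positions correctly", {
  ms <- small_series()
  df <- molecules(ms)
  ## a prediction dominating every training molecule ranks first
  best <- MoleculeSet("pred1", "CCCCCCCCCO",
                      ic50_molar = min(df$ic50_molar) / 10,
                      t_half_min = max(df$t_half_min) * 2)
  rk <- rankPredictions(best, ms)
  expect_equal(rk$prediction_ranks$position, 1L)
  expect_equal(nrow(scores_df(rk$table)), nMolecules(ms) + 1L)
  ## a prediction tied with a training molecule shares its rank block
  tied <- MoleculeSet("pred2", "CCCCCCCCCCO",
                      ic50_molar = df$ic50_molar[5], t_half_min = df$t_half_min[5])
  rk2 <- rankPredictions(tied, ms)
  tab <- scores_df(rk2$table)
  pos_all <- rank(-tab$score, ties.method = "min")
  expect_equal(rk2$prediction_ranks$position,
               pos_all[match(tab$id[match("pred2", tab$id)], tab$id)])
  expect_error(rankPredictions(MoleculeSet("p", "CCO", ic50_molar = 1e-6), ms),
               "both measured")
})

test_that("ligand efficiency follows the closed form", {
  expect_equal(ligandEfficiency(1e-9, 30), 1.37 * 9 / 30, tolerance = 1e-12)
  expect_equal(ligandEfficiency(1e-9, 30), 0.411, tolerance = 1e-3)
  ## doubling size halves LE; monotone decay toward zero
  expect_equal(ligandEfficiency(1e-8, 60), ligandEfficiency(1e-8, 30) / 2)
  le <- ligandEfficiency(1e-8, c(10, 100, 1000, 10000))
  expect_true(all(diff(le) < 0) && all(le > 0))
  expect_equal(countHeavyAtoms(c("CCO", "c1ccccc1")), c(3L, 6L))
})
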