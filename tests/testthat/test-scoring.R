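# Ranking, rank-sum scoring and pair orientation.

test_that("ranks run worst=1 to best=N with competition ties", {
  expect_equal(rankProperty(c(1e-9, 1e-8, 1e-7), "lower_is_better"), c(3L, 2L, 1L))
  expect_equal(rankProperty(c(10, 10, 5), "higher_is_better"), c(2L, 2L, 1L))
  expect_equal(rankProperty(3.14, "higher_is_better"), 1L)
  expect_error(rankProperty(c(1, NA), "higher_is_better", ids = c("a", "b")), "b")
})

test_that("the multiobjective score is the unweighted rank sum", {
  ms <- small_series()
  tab <- scores_df(scoreMolecules(ms, "multi"))
  n <- nrow(tab)
  expect_true(all(tab$score >= 2 & tab$score <= 2 * n))
  expect_equal(tab$score, tab$potency_rank + tab$stability_rank)
  ## molecule best in both gets 2N, worst in both gets 2
  ms2 <- MoleculeSet(letters[1:3], c("CCO", "CCCO", "CCCCO"),
                     ic50_molar = c(1e-9, 1e-6, 1e-3), t_half_min = c(300, 30, 3),
                     is_inactive = c(FALSE, FALSE, TRUE))
  tab2 <- scores_df(scoreMolecules(ms2, "multi"))
  expect_equal(tab2$score[1], 6)
  expect_equal(tab2$score[3], 2)
  ## perfectly rank-correlated properties: score = 2 x potency rank
  ## (brute-force check over a 10-molecule table)
  ic <- 10^-(1:10)
  th <- 1:10 * 10
  ms3 <- MoleculeSet(sprintf("m%02d", 1:10),
                     paste0("C", strrep("C", 1:10), "O"),
                     ic50_molar = ic, t_half_min = th)
  tab3 <- scores_df(scoreMolecules(ms3, "multi"))
  expect_equal(tab3$score, 2 * tab3$potency_rank)
  ## missing property is an error listing the ids
  ms4 <- MoleculeSet(c("x", "y"), c("CCO", "CCC"), ic50_molar = c(1e-6, 1e-7))
  expect_error(scoreMolecules(ms4, "multi"), "half-life")
  expect_error(scoreMolecules(ms4, "multi"), "x")
})

test_that("single-objective mode scores by potency rank alone", {
  ms <- small_series()
  tab <- scores_df(scoreMolecules(ms, "potency"))
  expect_true(all(is.na(tab$stability_rank)))
  expect_equal(tab$score, as.numeric(tab$potency_rank))
})

test_that("orientation emits worse->better, ties in both orders", {
  ms <- MoleculeSet(c("A", "B"), c("Cc1ccccc1", "CCc1ccccc1"),
                    ic50_molar = c(1e-8, 1e-6))
  mps <- buildPairs(ms, min_constant_frac = 0)
  st <- scoreMolecules(ms, "potency")
  dp <- directedPairs(orientPairs(mps, st))
  expect_equal(nrow(dp), 1L)
  expect_equal(dp$source_id, "B")   # worse potency
  expect_equal(dp$target_id, "A")
  expect_equal(dp$score_diff, 1)
  ## tie: both orders, diff 0
  ms2 <- MoleculeSet(c("A", "B"), c("Cc1ccccc1", "CCc1ccccc1"),
                     ic50_molar = c(1e-6, 1e-6))
  dp2 <- directedPairs(orientPairs(buildPairs(ms2, min_constant_frac = 0),
                                   scoreMolecules(ms2, "potency")))
  expect_equal(nrow(dp2), 2L)
  expect_true(all(dp2$score_diff == 0))
  expect_setequal(paste(dp2$source_id, dp2$target_id), c("A B", "B A"))
  ## empty pair list
  e <- orientPairs(new("MatchedPairSet",
                       pairs = data.frame(id_a = character(), id_b = character(),
                                          constant = character(),
                                          variable_a = character(),
                                          variable_b = character())), st)
  expect_equal(nrow(directedPairs(e)), 0L)
})

test_that("directed-pair count law and relabeling invariance hold", {
  ms <- small_series()
  mps <- buildPairs(ms)
  st <- scoreMolecules(ms, "multi")
  dp <- directedPairs(orientPairs(mps, st))
  sc <- stats::setNames(scores_df(st)$score, scores_df(st)$id)
  pr <- pairs_df(mps)
  ties <- sum(sc[pr$id_a] == sc[pr$id_b])
  expect_equal(nrow(dp), (nrow(pr) - ties) + 2L * ties)
  ## relabeling ids leaves score_diffs unchanged (as a multiset)
  df <- molecules(ms)
  relab <- MoleculeSet(paste0("X", df$id), df$smiles, df$ic50_molar,
                       df$t_half_min, df$is_inactive, canonicalize = FALSE)
  dp2 <- directedPairs(orientPairs(buildPairs(relab), scoreMolecules(relab, "multi")))
  expect_equal(sort(dp$score_diff), sort(dp2$score_diff))
})
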