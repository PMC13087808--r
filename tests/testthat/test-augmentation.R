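# Score-difference-weighted augmentation and example generation.

test_that("weighted counts hit the endpoints exactly and floor correctly", {
  expect_equal(weightedCounts(c(0, 5, 10), 200), c(0L, 100L, 200L))
  ## (d - dmin)/(dmax - dmin) = 0.499 -> floor(99.8) = 99
  expect_equal(weightedCounts(c(0, 0.499, 1), 200)[2], 99L)
  expect_warning(ct <- weightedCounts(c(3, 3, 3), 200), "equal")
  expect_equal(ct, c(1L, 1L, 1L))
})

test_that("weighted counts agree with an independent evaluation of the formula", {
  set.seed(99)
  for (rep in 1:20) {
    d <- round(stats::runif(sample(2:40, 1), 0, 50), 3)
    if (max(d) == min(d)) next
    n <- sample(1:300, 1)
    oracle <- as.integer(floor((d - min(d)) / (max(d) - min(d)) * n))
    got <- weightedCounts(d, n)
    expect_identical(got, oracle)
    expect_true(all(diff(got[order(d)]) >= 0L))   # monotone in d
  }
})

test_that("augmentation conserves counts and decodes to the right molecules", {
  ms <- small_series()
  mps <- buildPairs(ms)
  dp <- orientPairs(mps, scoreMolecules(ms, "multi"))
  npairs <- nrow(directedPairs(dp))
  counts <- rep(0L, npairs)
  counts[1:4] <- c(3L, 0L, 5L, 2L)
  ex <- augmentPairs(dp, ms, counts, seed = 13)
  expect_equal(nrow(ex), sum(counts))
  expect_false(2L %in% ex$pair_index)     # count 0 contributes nothing
  ## every example decodes to its pair's canonical molecules
  df <- molecules(ms)
  for (k in seq_len(nrow(ex))) {
    expect_identical(canonicalizeSmiles(selfiesToSmiles(ex$source_selfies[k])),
                     df$smiles[match(ex$source_id[k], df$id)])
    expect_identical(canonicalizeSmiles(selfiesToSmiles(ex$target_selfies[k])),
                     df$smiles[match(ex$target_id[k], df$id)])
    ## source and target are distinct molecules (pair invariant)
    expect_false(identical(ex$source_id[k], ex$target_id[k]))
  }
  ## deterministic per seed
  expect_identical(ex, augmentPairs(dp, ms, counts, seed = 13))
})

test_that("shuffling permutes examples deterministically", {
  ms <- small_series()
  dp <- orientPairs(buildPairs(ms), scoreMolecules(ms, "multi"))
  ex <- augmentPairs(dp, ms, rep(1L, nrow(directedPairs(dp))), seed = 1)
  sh <- shuffleExamples(ex, seed = 8)
  expect_identical(sh, shuffleExamples(ex, seed = 8))
  expect_false(identical(sh, ex))
  expect_identical(sort(paste(sh$source_selfies, sh$target_selfies)),
                   sort(paste(ex$source_selfies, ex$target_selfies)))
  one <- ex[1, , drop = FALSE]
  expect_identical(shuffleExamples(one, seed = 3), one)
})

test_that("inference representations are canonical-plus-k randomized variants", {
  ms <- small_series()[1:4]
  reps <- inferenceRepresentations(ms, k = 5L, seed = 4)
  expect_equal(nrow(reps), 4L * 6L)
  df <- molecules(ms)
  for (id in df$id) {
    mine <- reps$selfies[reps$id == id]
    expect_length(mine, 6L)
    cs <- df$smiles[match(id, df$id)]
    expect_identical(mine[1], smilesToSelfies(cs))   # canonical first
    for (v in mine)
      expect_identical(canonicalizeSmiles(selfiesToSmiles(v)), cs)
  }
})

test_that("parallel corpus files align line by line", {
  ms <- small_series()
  dp <- orientPairs(buildPairs(ms), scoreMolecules(ms, "multi"))
  ex <- augmentPairs(dp, ms, rep(1L, nrow(directedPairs(dp))), seed = 2)
  fs <- tempfile(); ft <- tempfile()
  writeParallelCorpus(ex, fs, ft)
  expect_identical(readLines(fs), ex$source_selfies)
  expect_identical(readLines(ft), ex$target_selfies)
})
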