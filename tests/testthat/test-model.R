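# Vocabulary, transformer training, checkpoints and nucleus sampling.

test_that("vocabulary holds specials first, orders by frequency, maps unknowns", {
  v <- buildVocabulary(c("[C][C]", "[C][O]"))
  expect_identical(vocabTokens(v)[1:4], c("<pad>", "<unk>", "<s>", "</s>"))
  expect_identical(vocabTokens(v)[5:6], c("[C]", "[O]"))  # frequency then lexicographic
  expect_identical(vocabTokens(buildVocabulary(c("[C][C]", "[C][O]"))), vocabTokens(v))
  ids <- PairTune:::.encode_tokens(v, "[C][N][O]")
  expect_equal(ids[2], PairTune:::.UNK_ID)   # [N] unseen -> <unk>
})

test_that("training gradients match finite differences", {
  ex <- data.frame(source_selfies = c("[C][C][O]", "[C][N]", "[O][C]"),
                   target_selfies = c("[C][O]", "[C][C][N]", "[O][C][C]"))
  vocab <- buildVocabulary(ex$source_selfies, ex$target_selfies)
  cfg <- modelConfig(n_layers = 1, d_model = 8, n_heads = 2, d_ff = 16,
                     dropout = 0, batch_size = 4, epochs = 1, seed = 3)
  params <- PairTune:::.init_params(cfg, vocabSize(vocab), 3)
  enc <- PairTune:::.encode_examples(vocab, ex)
  r <- PairTune:::.batch_nll(params, cfg, enc, 1:3)
  g <- PairTune:::.model_bwd(params, cfg, r$ec, r$dc, r$ce$dlogits, r$src, r$tin)
  eps <- 1e-5
  probe <- function(set, get_grad) {
    p2 <- set(params, eps); p3 <- set(params, -eps)
    num <- (PairTune:::.batch_nll(p2, cfg, enc, 1:3)$ce$loss -
            PairTune:::.batch_nll(p3, cfg, enc, 1:3)$ce$loss) / (2 * eps)
    expect_lt(abs(get_grad(g) - num), 1e-6 * max(abs(num), 1))
  }
  probe(function(p, e) { p$embed[5, 2] <- p$embed[5, 2] + e; p },
        function(g) g$embed[5, 2])
  probe(function(p, e) { p$dec[[1]]$cross$Wk[2, 2] <- p$dec[[1]]$cross$Wk[2, 2] + e; p },
        function(g) g$dec[[1]]$cross$Wk[2, 2])
  probe(function(p, e) { p$enc[[1]]$ff$W1[1, 3] <- p$enc[[1]]$ff$W1[1, 3] + e; p },
        function(g) g$enc[[1]]$ff$W1[1, 3])
})

test_that("a zeroed output head is the uniform predictor with perplexity V", {
  ex <- data.frame(source_selfies = "[C][C][O]", target_selfies = "[C][O]")
  vocab <- buildVocabulary(ex$source_selfies, ex$target_selfies)
  cfg <- tiny_config()
  params <- PairTune:::.init_params(cfg, vocabSize(vocab), 1)
  params$Wout[] <- 0; params$bout[] <- 0
  enc <- PairTune:::.encode_examples(vocab, ex)
  r <- PairTune:::.batch_nll(params, cfg, enc, 1L)
  expect_equal(exp(r$ce$loss), vocabSize(vocab), tolerance = 1e-8)
})

test_that("training produces one checkpoint per epoch and decreasing loss", {
  ms <- small_series()
  dp <- orientPairs(buildPairs(ms), scoreMolecules(ms, "multi"))
  ex <- augmentPairs(dp, ms, rep(2L, nrow(directedPairs(dp))), seed = 6)
  cfg <- tiny_config(epochs = 3L)
  fit <- trainModel(ex, cfg, quiet = TRUE)
  expect_length(fit$checkpoints, 3L)
  expect_equal(vapply(fit$checkpoints, function(m) m@epoch, integer(1)), 1:3)
  expect_lt(fit$history$train_ppl[3], fit$history$train_ppl[1])
  expect_error(trainModel(ex[0, ], cfg), "nrow")
})

test_that("pretraining stops early when perplexity stalls", {
  ## constant example set with high capacity: perplexity flatlines quickly
  ex <- data.frame(source_selfies = rep("[C][C][O]", 40),
                   target_selfies = rep("[C][O]", 40))
  cfg <- tiny_config(d_model = 32L, n_heads = 4L, d_ff = 64L, batch_size = 40L,
                     epochs = 25L, warmup = 30L, val_frac = 0.2)
  fit <- trainModel(ex, cfg, patience = 1L, quiet = TRUE)
  expect_lt(nrow(fit$history), 25L)
  best <- bestCheckpoint(fit)
  expect_s4_class(best, "TransformerModel")
  expect_equal(best@epoch, which.min(fit$history$val_ppl))
})

test_that("checkpoints reload to identical behaviour", {
  ms <- small_series()
  dp <- orientPairs(buildPairs(ms), scoreMolecules(ms, "multi"))
  ex <- augmentPairs(dp, ms, rep(1L, nrow(directedPairs(dp))), seed = 9)
  fit <- trainModel(ex, tiny_config(), quiet = TRUE)
  m <- fit$checkpoints[[2]]
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(m, f)
  m2 <- loadCheckpoint(f)
  expect_identical(logLikelihood(m, ex[1:5, ]), logLikelihood(m2, ex[1:5, ]))
  s1 <- nucleusSample(m, ex$source_selfies[1], seed = 4)
  s2 <- nucleusSample(m2, ex$source_selfies[1], seed = 4)
  expect_identical(s1, s2)
})

test_that("nucleus candidate sets follow the smallest-prefix rule", {
  ## worked example: (0.5, 0.3, 0.15, 0.05) at p = 0.9 -> top 3
  expect_identical(nucleusCandidates(c(0.5, 0.3, 0.15, 0.05), 0.9), 1:3)
  ## p -> 0: greedy (argmax only)
  expect_identical(nucleusCandidates(c(0.2, 0.5, 0.3), 1e-12), 2L)
  ## p = 1: whole vocabulary
  expect_length(nucleusCandidates(c(0.25, 0.25, 0.25, 0.25), 1), 4L)
})

test_that("sampled tokens always lie inside the candidate set", {
  set.seed(42)
  for (rep in 1:50) {
    v <- sample(3:30, 1)
    pr <- stats::runif(v); pr <- pr / sum(pr)
    p <- stats::runif(1, 0.1, 1)
    cand <- nucleusCandidates(pr, p)
    tok <- PairTune:::.nucleus_step(matrix(pr, 1), p, stats::runif(1))
    expect_true(tok %in% cand)
  }
})

test_that("batched prediction yields one record per (checkpoint, input)", {
  ms <- small_series()[1:4]
  dp <- orientPairs(buildPairs(small_series()), scoreMolecules(small_series(), "multi"))
  ex <- augmentPairs(dp, small_series(), rep(1L, nrow(directedPairs(dp))), seed = 2)
  fit <- trainModel(ex, tiny_config(), quiet = TRUE)
  reps <- inferenceRepresentations(ms, k = 1L, seed = 3)   # 4 x 2 representations
  ps <- predictBatch(fit$checkpoints, reps, seed = 5)
  rec <- predictions(ps)
  expect_equal(nrow(rec), nrow(reps) * length(fit$checkpoints))
  expect_setequal(unique(rec$epoch), 1:2)
  ## non-empty outputs are canonical fixed points
  for (s in unique(rec$smiles[nzchar(rec$smiles)]))
    expect_identical(canonicalizeSmiles(s), s)
  ## determinism
  ps2 <- predictBatch(fit$checkpoints, reps, seed = 5)
  expect_identical(predictions(ps), predictions(ps2))
})
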