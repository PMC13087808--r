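# Synthetic congeneric series and pretraining corpus.

test_that("generated series honours counts, inactive block and determinism", {
  ms <- small_series()
  df <- molecules(ms)
  expect_equal(nrow(df), 40L)
  expect_equal(sum(df$is_inactive), 4L)
  expect_true(all(df$ic50_molar[df$is_inactive] == inactiveIC50(ms)))
  expect_true(all(df$ic50_molar[!df$is_inactive] < inactiveIC50(ms)))
  expect_true(all(df$t_half_min > 0))
  expect_false(anyDuplicated(df$smiles) > 0)
  ms2 <- generateSeries(seriesSpec(n_molecules = 40L, n_inactive = 4L, seed = 11L))
  expect_identical(df, molecules(ms2))
  ## inactives are the worst by the noise-free model
  mu <- attr(ms, "mu_potency")
  expect_true(min(mu[df$is_inactive]) >= max(mu[!df$is_inactive]) - 1e-12 ||
              all(rank(-mu)[df$is_inactive] <= 4L))
})

test_that("every molecule is the scaffold plus its recorded substituents", {
  ms <- small_series()
  sp <- seriesSpec(n_molecules = 40L, n_inactive = 4L, seed = 11L)
  sub <- attr(ms, "substituents")
  df <- molecules(ms)
  for (i in c(1L, 7L, 23L, 40L)) {
    rebuilt <- PairTune:::assemble_scaffold(
      sp$scaffold, list(sp$substituent_pool[[1]][sub[i, 1]],
                        sp$substituent_pool[[2]][sub[i, 2]]))
    expect_identical(rebuilt, df$smiles[i])
  }
})

test_that("a single-molecule spec and an exhausted pool behave as specified", {
  one <- generateSeries(seriesSpec(n_molecules = 1L, n_inactive = 0L, seed = 2L))
  expect_equal(nMolecules(one), 1L)
  tiny_pool <- list(c("[*:1]C", "[*:1]CC"), c("[*:1]F"))
  expect_error(
    generateSeries(seriesSpec(substituent_pool = tiny_pool, n_molecules = 5L,
                              n_inactive = 0L, seed = 1L,
                              potency_contrib = list(c(0, 0), 0),
                              stability_contrib = list(c(0, 0), 0))),
    "exhausted")
})

test_that("regression on substituent indicators recovers the potency model", {
  sp <- seriesSpec(n_molecules = 220L, n_inactive = 0L, seed = 31L)
  ms <- generateSeries(sp)
  df <- molecules(ms)
  sub <- attr(ms, "substituents")
  d <- data.frame(y = log10(df$ic50_molar),
                  s1 = factor(sub[, 1]), s2 = factor(sub[, 2]))
  fit <- stats::lm(y ~ s1 + s2, data = d)
  co <- stats::coef(fit)
  ## estimated level contrasts must match the true contribution differences
  ## within 3 s.d. of the assay noise
  tol <- 3 * sp$potency_sd
  for (lv in levels(d$s1)[-1]) {
    est <- co[[paste0("s1", lv)]]
    truth <- sp$potency_contrib[[1]][as.integer(lv)] -
             sp$potency_contrib[[1]][as.integer(levels(d$s1)[1])]
    expect_lt(abs(est - truth), tol)
  }
})

test_that("pretraining corpus is valid, distinct, diverse and deterministic", {
  corp <- generatePretrainCorpus(60, seed = 3L)
  expect_length(corp, 60L)
  expect_false(anyDuplicated(corp) > 0)
  expect_identical(canonicalizeSmiles(corp), corp)
  expect_identical(corp, generatePretrainCorpus(60, seed = 3L))
  expect_length(generatePretrainCorpus(1, seed = 5L), 1L)
  theirs <- rdkit_canonical(corp)
  if (!is.null(theirs)) expect_false(any(theirs == "PARSE_FAIL"))
})

test_that("molecule tables round-trip through CSV and SMI", {
  ms <- small_series()
  csv <- tempfile(fileext = ".csv"); smi <- tempfile(fileext = ".smi")
  writeMoleculeCsv(ms, csv)
  writeSmi(ms, smi)
  back <- readMoleculeCsv(csv, canonicalize = FALSE)
  expect_identical(molecules(back)$id, molecules(ms)$id)
  expect_identical(molecules(back)$smiles, molecules(ms)$smiles)
  expect_identical(molecules(back)$is_inactive, molecules(ms)$is_inactive)
  ## numeric columns round-trip to printed precision
  expect_equal(molecules(back)$ic50_molar, molecules(ms)$ic50_molar,
               tolerance = 1e-6)
  expect_equal(molecules(back)$t_half_min, molecules(ms)$t_half_min,
               tolerance = 1e-6)
  lines <- readLines(smi)
  expect_length(lines, nMolecules(ms))
  expect_true(all(grepl("\t", lines, fixed = TRUE)))
})
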