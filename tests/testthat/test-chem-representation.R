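# The string layer: canonicalization, randomized SMILES, SELFIES codec.

test_that("canonicalization removes stereochemistry and is a fixed point", {
  expect_identical(canonicalizeSmiles("C[C@H](N)O"),
                   canonicalizeSmiles("C[C@@H](N)O"))
  expect_identical(canonicalizeSmiles("OCC"), canonicalizeSmiles("CCO"))
  for (s in chem_fixture_smiles()) {
    cs <- canonicalizeSmiles(s)
    expect_identical(canonicalizeSmiles(cs), cs)
    expect_false(grepl("[@/\\\\]", cs))
  }
  ## kekulized and aromatic input converge
  expect_identical(canonicalizeSmiles("C1=CC=CC=C1"), canonicalizeSmiles("c1ccccc1"))
})

test_that("equivalent encodings collapse and distinct molecules stay distinct", {
  for (s in chem_fixture_smiles()) {
    cs <- canonicalizeSmiles(s)
    vars <- suppressWarnings(randomSmiles(s, 6, seed = 5))
    expect_true(all(canonicalizeSmiles(vars) == cs), info = s)
  }
  all_canon <- canonicalizeSmiles(chem_fixture_smiles())
  expect_false(anyDuplicated(all_canon) > 0)
})

test_that("canonical equivalence classes agree with an independent toolkit", {
  smiles <- chem_fixture_smiles()
  variants <- unlist(lapply(smiles, function(s)
    c(s, suppressWarnings(randomSmiles(s, 4, seed = 17)))))
  parent <- rep(smiles, times = vapply(smiles, function(s)
    1L + length(suppressWarnings(randomSmiles(s, 4, seed = 17))), integer(1)))
  theirs <- rdkit_canonical(variants)
  expect_false(is.null(theirs))          # oracle must be available
  expect_false(any(theirs == "PARSE_FAIL"))
  mine <- canonicalizeSmiles(variants)
  for (p in unique(parent)) {
    ix <- parent == p
    expect_length(unique(mine[ix]), 1L)
    expect_length(unique(theirs[ix]), 1L)
  }
})

test_that("unparseable SMILES raise a parse error carrying the input", {
  err <- tryCatch(canonicalizeSmiles("C1CC"), error = identity)
  expect_s3_class(err, "pairtune_parse_error")
  expect_match(conditionMessage(err), "C1CC", fixed = TRUE)
  expect_error(canonicalizeSmiles("C(C"), class = "pairtune_parse_error")
  expect_error(canonicalizeSmiles("Cq"), class = "pairtune_parse_error")
})

test_that("multi-fragment SMILES keep the largest fragment", {
  expect_message(out <- canonicalizeSmiles("CCO.[Na]"), "largest fragment")
  expect_identical(out, canonicalizeSmiles("CCO"))
})

test_that("randomized SMILES are deterministic, distinct and formula-preserving", {
  s <- "CC(C)Cc1ccc(cc1)C(C)C(=O)O"
  a <- randomSmiles(s, 8, seed = 42)
  b <- randomSmiles(s, 8, seed = 42)
  expect_identical(a, b)
  expect_length(unique(a), 8L)
  f0 <- PairTune:::mol_formula(PairTune:::parse_smiles(s))
  for (v in a)
    expect_identical(PairTune:::mol_formula(PairTune:::parse_smiles(v)), f0)
  ## methane admits very few encodings: shortfall reported, no failure
  expect_warning(m <- randomSmiles("C", 3, seed = 1), "only")
  expect_lt(length(m), 3L)
  expect_gt(attr(m, "shortfall"), 0L)
})

test_that("SELFIES round-trip preserves the canonical form", {
  for (s in chem_fixture_smiles()) {
    sf <- smilesToSelfies(s)
    back <- selfiesToSmiles(sf)
    expect_identical(canonicalizeSmiles(back), canonicalizeSmiles(s), info = s)
  }
  ## and on randomized encodings of series molecules
  df <- molecules(small_series())
  for (s in df$smiles[1:10]) {
    for (v in suppressWarnings(randomSmiles(s, 3, seed = 3))) {
      expect_identical(canonicalizeSmiles(selfiesToSmiles(smilesToSelfies(v))),
                       s)
    }
  }
})

test_that("simple SELFIES decode to the expected molecules", {
  expect_identical(canonicalizeSmiles(selfiesToSmiles("[C][C][O]")),
                   canonicalizeSmiles("CCO"))
})

test_that("tokenization is invertible and malformed strings are rejected", {
  s <- smilesToSelfies("CC(=O)Nc1ccc(O)cc1")
  toks <- tokenizeSelfies(s)
  expect_identical(pasteSelfies(toks), s)
  expect_true(all(grepl("^\\[.*\\]$", toks)))
  expect_error(tokenizeSelfies("[C]x[O]"), "malformed")
})

test_that("every token sequence from the vocabulary decodes to a valid molecule", {
  alphabet <- unique(unlist(lapply(molecules(small_series())$smiles[1:15],
                                   function(s) tokenizeSelfies(smilesToSelfies(s)))))
  rng_seeds <- 1:200
  smis <- character(0)
  for (sd in rng_seeds) {
    set.seed(sd)
    soup <- pasteSelfies(sample(alphabet, sample(1:25, 1), replace = TRUE))
    smi <- selfiesToSmiles(soup)
    if (nzchar(smi)) smis <- c(smis, smi)
    expect_no_error(if (nzchar(smi)) PairTune:::parse_smiles(smi))
  }
  expect_gt(length(smis), 100)
  ## independent validity check of the decoded structures
  theirs <- rdkit_canonical(smis)
  if (!is.null(theirs)) expect_false(any(theirs == "PARSE_FAIL"))
})
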