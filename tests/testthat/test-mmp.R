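# Matched-pair fragmentation, pairing and transformations.

test_that("single-cut fragmentation enumerates the expected splits", {
  ## ethanol: cuts at C-C and C-O, larger side constant
  fr <- fragmentMolecule("CCO", min_constant_frac = 0)
  expect_equal(nrow(fr), 2L)
  expect_setequal(paste(fr$constant, fr$variable),
                  c("[*:1]CO [*:1]C", "[*:1]CC [*:1]O"))
  expect_true(all(fr$heavy_constant >= fr$heavy_variable))
  ## methane: nothing to cut
  expect_equal(nrow(fragmentMolecule("C")), 0L)
  ## toluene: ring bonds are not cut; only the methyl split remains
  fr <- fragmentMolecule("Cc1ccccc1", min_constant_frac = 0)
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$variable, "[*:1]C")
  expect_equal(fr$constant, canonicalizeSmiles("[*:1]c1ccccc1"))
  expect_error(fragmentMolecule("CCO", max_cuts = 2L), "single-cut")
})

test_that("fragmentation agrees with a hand-enumerated bond-cut oracle", {
  ## distinct splits per molecule, enumerated by hand over the acyclic single
  ## bonds (symmetry-equivalent cuts collapse to one split); each split must
  ## rejoin to the parent
  expected <- c("CCO" = 2L,        # C-C and C-O
                "CCCC" = 2L,       # terminal cut and the (symmetric) centre
                "CC(C)O" = 2L,     # methyl cut (x2 equivalent) and C-O
                "Cc1ccccc1" = 1L,  # only the methyl-ring bond is acyclic
                "CC(=O)OC" = 3L,   # C-C(=O), C(=O)-O, O-C
                "C#CCN" = 2L)      # triple bond not cuttable
  for (s in names(expected)) {
    fr <- fragmentMolecule(s, min_constant_frac = 0)
    expect_equal(nrow(fr), unname(expected[s]), info = s)
    cs <- canonicalizeSmiles(s)
    for (k in seq_len(nrow(fr)))
      expect_identical(PairTune:::join_fragments(fr$constant[k], fr$variable[k]),
                       cs)
  }
})

test_that("matched pairs form on shared constant parts only", {
  ms <- MoleculeSet(c("tol", "etb"), c("Cc1ccccc1", "CCc1ccccc1"))
  pr <- pairs_df(buildPairs(ms, min_constant_frac = 0))
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$constant, canonicalizeSmiles("[*:1]c1ccccc1"))
  expect_setequal(c(pr$variable_a, pr$variable_b), c("[*:1]C", "[*:1]CC"))
  ## no shared constant part -> no pairs
  ms2 <- MoleculeSet(c("a", "b"), c("CCCCO", "c1ccc2ccccc2c1"))
  expect_equal(nrow(pairs_df(buildPairs(ms2, min_constant_frac = 0))), 0L)
})

test_that("pairing is invariant under permutation of the input records", {
  ms <- small_series()
  p1 <- pairs_df(buildPairs(ms))
  perm <- rev(seq_len(nMolecules(ms)))
  p2 <- pairs_df(buildPairs(ms[perm]))
  key <- function(p) sort(paste(p$id_a, p$id_b, p$constant, p$variable_a, p$variable_b))
  expect_identical(key(p1), key(p2))
  expect_gt(nrow(p1), 0L)
  ## every pair's molecules share the constant part by construction: rejoin
  for (k in sample(nrow(p1), min(10L, nrow(p1)))) {
    df <- molecules(ms)
    a <- df$smiles[match(p1$id_a[k], df$id)]
    expect_identical(PairTune:::join_fragments(p1$constant[k], p1$variable_a[k]), a)
  }
})

test_that("extracted transformations regenerate the partner molecule", {
  ms <- MoleculeSet(c("tol", "etb"), c("Cc1ccccc1", "CCc1ccccc1"))
  mps <- buildPairs(ms, min_constant_frac = 0)
  tr <- extractTransformations(mps)
  expect_equal(nrow(tr), 1L)
  src <- molecules(ms)$smiles[match(tr$id_a, molecules(ms)$id)]
  tgt <- molecules(ms)$smiles[match(tr$id_b, molecules(ms)$id)]
  expect_true(tgt %in% applyTransformation(tr$lhs, tr$rhs, src))
  ## re-extraction is stable
  expect_identical(tr, extractTransformations(buildPairs(ms, min_constant_frac = 0)))
  ## directed = TRUE adds the reverse swap
  expect_equal(nrow(extractTransformations(mps, directed = TRUE)), 2L)
})

test_that("transformation application enumerates symmetric sites and deduplicates", {
  ## ortho-xylene: two equivalent methyls collapse to one canonical product
  prods <- applyTransformation("[*:1]C", "[*:1]CC", "Cc1ccccc1C")
  expect_identical(prods, canonicalizeSmiles("CCc1ccccc1C"))
  ## no match -> empty
  expect_length(applyTransformation("[*:1]C", "[*:1]CC", "c1ccccc1"), 0L)
  ## para-disubstituted with distinct groups: methyl swap gives one product
  prods2 <- applyTransformation("[*:1]C", "[*:1]O", "Cc1ccc(F)cc1")
  expect_identical(prods2, canonicalizeSmiles("Oc1ccc(F)cc1"))
})

test_that("extract-then-apply round-trips on series pairs", {
  ms <- small_series()
  pr <- pairs_df(buildPairs(ms))
  df <- molecules(ms)
  take <- seq_len(min(25L, nrow(pr)))
  for (k in take) {
    src <- df$smiles[match(pr$id_a[k], df$id)]
    tgt <- df$smiles[match(pr$id_b[k], df$id)]
    expect_true(tgt %in% applyTransformation(pr$variable_a[k], pr$variable_b[k], src))
  }
})
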