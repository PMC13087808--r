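# PAINS screening, novelty window, one-step reachability.

test_that("PAINS screen flags known interference motifs and passes clean ones", {
  pat <- painsPatterns()
  expect_gt(nrow(pat), 5L)
  res <- painsFilter(c("Oc1ccccc1O", "C", "CC(=O)Nc1ccc(O)cc1"), pat)
  expect_false(res$passed[1])
  expect_match(res$pains_flags[1], "catechol")
  expect_true(res$passed[2])     # methane
  expect_true(res$passed[3])     # single phenol is not a catechol
  expect_equal(nrow(painsFilter(character(0), pat)), 0L)
})

test_that("adding patterns never un-flags a molecule (monotonicity)", {
  pat <- painsPatterns()
  mols <- c("Oc1ccccc1O", "CCO", "O=C1C=CC(=O)C=C1", "NC(=S)Nc1ccccc1")
  few <- painsFilter(mols, pat[1:3, ])
  all_ <- painsFilter(mols, pat)
  expect_true(all((!few$passed) <= (!all_$passed)))
  flagged_few <- strsplit(few$pains_flags, ",")
  flagged_all <- strsplit(all_$pains_flags, ",")
  for (i in seq_along(mols))
    expect_true(all(flagged_few[[i]] %in% c("", flagged_all[[i]])))
})

test_that("malformed user patterns are rejected by name", {
  bad <- data.frame(name = "broken_pattern", smarts = "c1ccc")  # unclosed ring
  expect_error(painsFilter("CCO", bad), "broken_pattern")
})

test_that("the novelty window keeps near-but-not-identical analogues", {
  ms <- small_series()
  lead <- molecules(ms)$smiles[1]
  preds <- c(lead,                       # identical to lead -> similarity 1
             molecules(ms)$smiles[2],    # training member -> discarded
             "C")                        # unrelated -> below window
  nv <- noveltyFilter(preds, ms, lead, sim_window = c(0.5, 0.95))
  expect_false(nv$passed[1])
  expect_equal(nv$similarity_to_lead[1], 1)
  expect_false(nv$passed[2])
  expect_true(nv$in_training_set[2])
  expect_false(nv$passed[3])
  ## an in-window analogue passes: swap a fragment of the lead
  tr <- extractTransformations(buildPairs(ms))
  prods <- applyTransformation(tr$lhs[1], tr$rhs[1], lead)
  prods <- setdiff(prods, molecules(ms)$smiles)
  if (length(prods)) {
    nv2 <- noveltyFilter(prods[1], ms, lead)
    expect_true(nv2$passed == (nv2$similarity_to_lead >= 0.5 &&
                               nv2$similarity_to_lead <= 0.95))
  }
})

test_that("one-step reachability matches constructive application", {
  ms <- MoleculeSet(c("tol", "anis"), c("Cc1ccccc1", "COc1ccccc1"))
  tr <- data.frame(lhs = "[*:1]C", rhs = "[*:1]CC")
  r <- oneStepReachable("CCc1ccccc1", ms, tr)
  expect_true(r$reachable)
  expect_true("tol" %in% r$witnesses$id)
  ## a product no catalogue rhs can build
  r2 <- oneStepReachable("CCCCCc1ccccc1", ms, tr)
  expect_false(r2$reachable)
  expect_equal(nrow(r2$witnesses), 0L)
})

test_that("reachability agrees with exhaustive product enumeration", {
  ms <- small_series()[1:10]
  mps <- buildPairs(ms)
  tr <- utils::head(extractTransformations(mps, directed = TRUE), 12L)
  prods <- enumerateProducts(ms, tr, cap = 500L)
  expect_gt(length(prods), 0L)
  expect_identical(canonicalizeSmiles(prods), prods)   # validity contract
  ## every enumerated product is one-step reachable; a foreign molecule is not
  for (p in utils::head(prods, 8L))
    expect_true(oneStepReachable(p, ms, tr)$reachable, info = p)
  expect_false(oneStepReachable("C1CCNCC1", ms, tr)$reachable)
  ## empty transformation set -> empty products
  expect_length(enumerateProducts(ms, tr[0, ]), 0L)
  ## cap stops enumeration with a warning
  expect_warning(short <- enumerateProducts(ms, tr, cap = 3L), "cap")
  expect_length(short, 3L)
})
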