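## Synthetic congeneric inhibitor series.
##
## Emulates the statistical structure the pipeline assumes: a single
## spiro-bicyclic scaffold decorated at two attachment points with enumerated
## substituents, log-additive substituent contributions to potency (IC50) and
## microsomal half-life plus Gaussian noise, and a block of inactives pinned
## at a surrogate IC50 of 1 mM. Also provides a scaffold-diverse corpus that
## stands in for a large public pretraining library.

.DEFAULT_SCAFFOLD <- "[*:1]N1CCC2(C1)CCN([*:2])CC2"

.DEFAULT_POOL_R1 <- c(
  "[*:1]C(=O)c1ccccc1",         "[*:1]C(=O)c1ccc(F)cc1",
  "[*:1]C(=O)c1ccc(Cl)cc1",     "[*:1]C(=O)c1ccc(C)cc1",
  "[*:1]C(=O)c1ccc(OC)cc1",     "[*:1]C(=O)c1ccncc1",
  "[*:1]C(=O)c1cccnc1",         "[*:1]C(=O)c1cc(F)ccc1F",
  "[*:1]C(=O)c1ccco1",          "[*:1]C(=O)c1cccs1",
  "[*:1]C(=O)C1CC1",            "[*:1]C(=O)C1CCC1",
  "[*:1]C(=O)CC1CC1",           "[*:1]C(=O)C(C)C",
  "[*:1]C(=O)CC",               "[*:1]C(=O)C",
  "[*:1]C(=O)c1ccc(cc1)C#N",    "[*:1]C(=O)c1ccc(Br)cc1",
  "[*:1]C(=O)c1ccc(cc1)C(F)(F)F", "[*:1]C(=O)c1cnccn1",
  "[*:1]S(=O)(=O)C",            "[*:1]S(=O)(=O)c1ccccc1",
  "[*:1]S(=O)(=O)CC",           "[*:1]S(=O)(=O)c1ccc(C)cc1",
  "[*:1]Cc1ccccc1",             "[*:1]Cc1ccc(F)cc1",
  "[*:1]Cc1ccncc1",             "[*:1]CC(C)C",
  "[*:1]C(=O)OC(C)(C)C",        "[*:1]C(=O)N(C)C"
)

.DEFAULT_POOL_R2 <- c(
  "[*:1]c1ccccc1",              "[*:1]c1ccc(F)cc1",
  "[*:1]c1ccc(Cl)cc1",          "[*:1]c1ccc(C)cc1",
  "[*:1]c1ccc(OC)cc1",          "[*:1]c1ccncc1",
  "[*:1]c1cccnc1",              "[*:1]c1ncccn1",
  "[*:1]c1ccc(cc1)C(F)(F)F",    "[*:1]c1ccc(cc1)C#N",
  "[*:1]c1cc(F)ccc1F",          "[*:1]c1ccc(Br)cc1",
  "[*:1]C1CC1",                 "[*:1]C1CCC1",
  "[*:1]C1CCCC1",               "[*:1]C1CCOCC1",
  "[*:1]CC1CC1",                "[*:1]C(C)C",
  "[*:1]CC(C)C",                "[*:1]CCc1ccccc1",
  "[*:1]Cc1ccc(Cl)cc1",         "[*:1]Cc1ccco1",
  "[*:1]CCOC",                  "[*:1]CC#N"
)

#' Specification of a synthetic congeneric series
#'
#' Defines the scaffold, the substituent pools, the additive log10 property
#' models and the inactive block. Substituent contributions default to draws
#' from centred normals (one value per pool member, fixed by `seed`), giving
#' IC50 spanning roughly 1 nM - 1 mM and half-lives spanning roughly 5 - 400
#' minutes under the default bases.
#'
#' @param scaffold SMILES with numbered attachment points `[*:1]`, `[*:2]`.
#' @param substituent_pool list of character vectors, one pool per attachment
#'   point, each fragment carrying one `[*:1]` marker.
#' @param n_molecules number of molecules to generate.
#' @param n_inactive number of molecules flagged inactive (the worst by the
#'   noise-free potency model), pinned at `inactive_ic50_molar`.
#' @param potency_base,potency_sd base log10(IC50 / M) and the per-molecule
#'   noise s.d. in log10 units (default -6.5 and 0.3).
#' @param potency_contrib optional list of per-pool numeric contribution
#'   vectors; drawn from Normal(0, 0.8) when NULL.
#' @param stability_base,stability_sd base log10(t1/2 / min) and noise s.d.
#' @param stability_contrib as `potency_contrib`, drawn from Normal(0, 0.35).
#' @param inactive_ic50_molar surrogate IC50 for inactives (default 1e-3 M).
#' @param seed integer seed fixing contributions and noise.
#' @return an object of class `"SeriesSpec"` (a validated list).
#' @export
seriesSpec <- function(scaffold = .DEFAULT_SCAFFOLD,
                       substituent_pool = list(.DEFAULT_POOL_R1, .DEFAULT_POOL_R2),
                       n_molecules = 160L, n_inactive = 16L,
                       potency_base = -6.5, potency_sd = 0.3,
                       potency_contrib = NULL,
                       stability_base = log10(60), stability_sd = 0.15,
                       stability_contrib = NULL,
                       inactive_ic50_molar = 1e-3, seed = 1L) {
  stopifnot(n_molecules >= 1L, n_inactive >= 0L, n_inactive <= n_molecules,
            length(substituent_pool) >= 1L, inactive_ic50_molar > 0)
  rng <- local_rng(derive_seed(seed, "series-contrib"))
  if (is.null(potency_contrib))
    potency_contrib <- lapply(substituent_pool, function(p) rng$rnorm(length(p), 0, 0.8))
  if (is.null(stability_contrib))
    stability_contrib <- lapply(substituent_pool, function(p) rng$rnorm(length(p), 0, 0.35))
  stopifnot(lengths(potency_contrib) == lengths(substituent_pool),
            lengths(stability_contrib) == lengths(substituent_pool))
  structure(list(
    scaffold = scaffold, substituent_pool = substituent_pool,
    n_molecules = as.integer(n_molecules), n_inactive = as.integer(n_inactive),
    potency_base = potency_base, potency_sd = potency_sd,
    potency_contrib = potency_contrib,
    stability_base = stability_base, stability_sd = stability_sd,
    stability_contrib = stability_contrib,
    inactive_ic50_molar = inactive_ic50_molar, seed = as.integer(seed)
  ), class = "SeriesSpec")
}

#' Generate a synthetic congeneric series
#'
#' Draws `n_molecules` distinct substituent combinations, assembles them on
#' the scaffold, and assigns IC50 and half-life from the additive log-scale
#' models. The `n_inactive` molecules with the worst noise-free model potency
#' are flagged inactive and pinned at the surrogate IC50, mirroring an
#' activity cliff at the bottom of a real series. Deterministic per spec seed.
#'
#' @param spec a [seriesSpec()].
#' @return a [MoleculeSet] with substituent indices in
#'   `attr(, "substituents")` (used by parameter-recovery checks).
#' @export
generateSeries <- function(spec) {
  stopifnot(inherits(spec, "SeriesSpec"))
  pools <- spec$substituent_pool
  sizes <- lengths(pools)
  total <- prod(sizes)
  if (total < spec$n_molecules)
    stop(sprintf("substituent pool exhausted: %d combinations available, %d requested (shortfall %d)",
                 total, spec$n_molecules, spec$n_molecules - total))
  rng <- local_rng(derive_seed(spec$seed, "series-draw"))
  combo_order <- rng$sample_int(total)

  idx_of <- function(k) {
    k <- k - 1L
    out <- integer(length(sizes))
    for (d in seq_along(sizes)) { out[d] <- k %% sizes[d] + 1L; k <- k %/% sizes[d] }
    out
  }

  ids <- character(0); smi <- character(0)
  sub_idx <- matrix(0L, nrow = 0, ncol = length(sizes))
  seen <- character(0)
  ptr <- 0L
  while (length(smi) < spec$n_molecules && ptr < total) {
    ptr <- ptr + 1L
    ix <- idx_of(combo_order[ptr])
    s <- assemble_scaffold(spec$scaffold,
                           lapply(seq_along(ix), function(d) pools[[d]][ix[d]]))
    if (s %in% seen) next
    seen <- c(seen, s)
    smi <- c(smi, s)
    sub_idx <- rbind(sub_idx, ix)
  }
  if (length(smi) < spec$n_molecules)
    stop(sprintf("substituent pool exhausted: only %d distinct molecules found, %d requested (shortfall %d)",
                 length(smi), spec$n_molecules, spec$n_molecules - length(smi)))
  n <- spec$n_molecules
  ids <- sprintf("M%04d", seq_len(n))

  contrib_sum <- function(contrib) {
    rowSums(matrix(vapply(seq_along(contrib),
                          function(d) contrib[[d]][sub_idx[, d]], numeric(n)),
                   nrow = n))
  }
  mu_pot <- spec$potency_base + contrib_sum(spec$potency_contrib)
  mu_sta <- spec$stability_base + contrib_sum(spec$stability_contrib)
  log_ic50 <- mu_pot + rng$rnorm(n, 0, spec$potency_sd)
  log_thalf <- mu_sta + rng$rnorm(n, 0, spec$stability_sd)

  ic50 <- pmin(pmax(10^log_ic50, 1e-10), spec$inactive_ic50_molar / 1.001)
  thalf <- pmin(pmax(10^log_thalf, 1), 1000)

  is_inactive <- rep(FALSE, n)
  if (spec$n_inactive > 0L) {
    worst <- order(mu_pot, decreasing = TRUE)[seq_len(spec$n_inactive)]
    is_inactive[worst] <- TRUE
    ic50[worst] <- spec$inactive_ic50_molar
  }

  ms <- MoleculeSet(ids, smi, ic50, thalf, is_inactive,
                    inactiveIC50 = spec$inactive_ic50_molar, canonicalize = FALSE)
  attr(ms, "substituents") <- sub_idx
  attr(ms, "mu_potency") <- mu_pot
  ms
}

.PRETRAIN_SCAFFOLDS <- c(
  "[*:1]c1ccccc1", "[*:1]c1ccncc1", "[*:1]c1ccc2ccccc2c1",
  "[*:1]C1CCNCC1", "[*:1]N1CCOCC1", "[*:1]c1cccs1", "[*:1]c1ccco1",
  "[*:1]C1CCCCC1", "[*:1]N1CCNCC1", "[*:1]c1cc(F)ccc1",
  "[*:1]C1CCC(CC1)O", "[*:1]c1ncccn1"
)

#' Generate a scaffold-diverse pretraining corpus
#'
#' Assembles valid, canonical, stereochemistry-free SMILES from a dozen common
#' ring systems decorated with random substituents, as a desk-scale stand-in
#' for a large public compound library. Distinctness is guaranteed; scaffolds
#' deliberately extend beyond the congeneric-series core.
#'
#' @param n number of molecules (>= 1).
#' @param seed integer seed.
#' @return character vector of `n` distinct canonical SMILES.
#' @export
generatePretrainCorpus <- function(n, seed = 1L) {
  stopifnot(is.numeric(n), n >= 1)
  n <- as.integer(n)
  rng <- local_rng(derive_seed(seed, "pretrain-corpus"))
  frag_pool <- unique(c(.DEFAULT_POOL_R1, .DEFAULT_POOL_R2))
  out <- character(0)
  tries <- 0L
  max_tries <- 60L * n + 1000L
  while (length(out) < n && tries < max_tries) {
    tries <- tries + 1L
    scaf <- .PRETRAIN_SCAFFOLDS[rng$sample_int(length(.PRETRAIN_SCAFFOLDS), 1L)]
    frag <- frag_pool[rng$sample_int(length(frag_pool), 1L)]
    s <- tryCatch(join_fragments(scaf, frag, map = 1L), error = function(e) NULL)
    if (is.null(s)) next
    ## occasionally decorate once more for size diversity
    if (rng$runif(1) < 0.35) {
      frag2 <- frag_pool[rng$sample_int(length(frag_pool), 1L)]
      cuts <- .enumerate_cuts(parse_smiles(s))
      if (length(cuts)) {
        ct <- cuts[[rng$sample_int(length(cuts), 1L)]]
        s2 <- tryCatch(join_fragments(ct$smiles_i, frag2), error = function(e) NULL)
        if (!is.null(s2)) s <- s2
      }
    }
    s <- canonicalizeSmiles(s)
    if (!(s %in% out)) out <- c(out, s)
  }
  if (length(out) < n)
    stop(sprintf("could not assemble %d distinct corpus molecules (got %d)", n, length(out)))
  out
}

#' Write a molecule table
#'
#' `writeMoleculeCsv()` writes the standard CSV schema
#' (`id,smiles,ic50_molar,t_half_min,is_inactive`); `writeSmi()` writes the
#' two-column SMILES format (`SMILES<tab>id`). `readMoleculeCsv()` reads the
#' CSV schema back into a [MoleculeSet].
#'
#' @param x a [MoleculeSet].
#' @param path output file.
#' @export
writeMoleculeCsv <- function(x, path) {
  stopifnot(is(x, "MoleculeSet"))
  utils::write.csv(x@records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeMoleculeCsv
#' @export
writeSmi <- function(x, path) {
  stopifnot(is(x, "MoleculeSet"))
  writeLines(paste(x@records$smiles, x@records$id, sep = "\t"), path)
  invisible(path)
}

#' @rdname writeMoleculeCsv
#' @param inactiveIC50 surrogate IC50 used to validate the inactive flag.
#' @param canonicalize re-canonicalize SMILES on read.
#' @export
readMoleculeCsv <- function(path, inactiveIC50 = 1e-3, canonicalize = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  MoleculeSet(df$id, df$smiles, df$ic50_molar, df$t_half_min,
              as.logical(df$is_inactive), inactiveIC50 = inactiveIC50,
              canonicalize = canonicalize)
}
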