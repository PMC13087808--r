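---
title: "Directed matched-pair fine-tuning: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed matched-pair fine-tuning: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(PairTune)
```

## The method

PairTune treats lead optimization as a translation problem: given a molecule
of a congeneric series, translate it into a *better* member of the same
chemical neighbourhood. The training signal is built from matched molecular
pairs (MMPs) — two molecules that differ by a single substituent swap on a
shared constant part — ordered by a property score so that the model only
ever sees improving edits.

The score is deliberately simple. Each compound is ranked separately per
property (rank 1 = worst, N = best; tied values share the minimum rank of
their block, so inactives pinned at the surrogate IC50 of 1 mM form one
block at rank 1) and the multiobjective score is the unweighted rank sum.
Rank sums need no scale harmonisation between an IC50 spanning six decades
and a half-life spanning two, and integer ranks keep the augmentation
weights (below) exactly reproducible. Weighted sums are a natural extension
but out of scope here.

Pairs are oriented worse → better; exact ties are kept in both directions,
which reduces to the undirected base-model convention for uninformative
pairs. Augmentation then expands pair *i* with score difference $d_i$ into

$$ n_i = \left\lfloor \frac{d_i - d_\min}{d_\max - d_\min}\, n \right\rfloor $$

examples (default $n = 200$), each pairing a freshly randomized SMILES of
the source with one of the target, converted to SELFIES. The floor is taken
literally: the least-improving pair receives 0 examples and drops out of
training. When all differences are equal the formula is undefined; the
package falls back to one example per pair and warns. Randomized source and
target encodings are drawn independently — there is nothing to align between
the two enumeration orders — and the example list is shuffled so batches mix
transformations.

At inference time each input molecule contributes its canonical SMILES plus
five randomized variants, i.e. six representations, with no score bias; one
nucleus sample is drawn per representation per epoch checkpoint. This "k
randomized + 1 canonical" reading makes the bookkeeping exact: 160 molecules
× 6 representations × 30 checkpoints = 28 800 prediction records.

## The string layer

The package carries its own molecular-string layer: a SMILES parser and
graph model, a canonical writer, seeded randomized SMILES enumeration, a
SELFIES codec, single-cut fragmentation, and radius-2 circular (ECFP4-type)
fingerprints. Stereochemistry is removed on input (the congeneric series is
modelled stereo-free) and multi-fragment inputs keep their largest fragment
with a logged message.

Canonicalization refines atom invariants (element, degree, charge, hydrogen
count, aromaticity) to a stable partition and resolves remaining symmetry by
individualization, emitting the lexicographically smallest of the candidate
labelings' strings; equivalence of the resulting classes is cross-checked in
the test suite against an independent toolkit on randomized re-encodings.
Aromaticity is re-perceived from the kekulé graph with a pragmatic sp2
coverage rule over 5- and 6-membered rings; exotic aromatic systems
(pyridones written as aromatic, fused non-benzenoid polycycles) are outside
its scope, which is acceptable for the benzenoid/azole chemistry the
generator produces but a real limitation for arbitrary external input.

The SELFIES codec follows the published grammar conventions (index alphabet,
`[BranchN]`/`[RingN]` length encoding) with a valence-capped derivation:
bonds that would exceed an atom's capacity are truncated and unrealizable
branch or ring specifications are skipped, so *every* token sequence over
the vocabulary decodes to a valid molecule. That robustness is what makes
nucleus sampling safe — the model cannot produce an invalid structure, only
an implausible one.

## The model

The sequence model is a small pre-layer-norm encoder–decoder transformer
(default 2+2 layers, width 128, 4 heads, feed-forward 256) written directly
against one compiled batched-matrix-multiply kernel, with manual
backpropagation verified against finite differences at tolerance 1e-6.
Optimization is Adam under the inverse-square-root warmup/decay schedule;
the conventional "learning rate 1" is the scale factor of that schedule, not
a raw step size. Perplexity — exp(mean per-token negative log-likelihood) —
is reported per epoch on a held-out slice (5% by default). Pretraining on
undirected corpus pairs stops when that perplexity fails to improve
(patience 1, cap 10 epochs); fine-tuning always starts from the best
pretraining checkpoint and runs 30 epochs with one checkpoint per epoch,
each reloadable to bit-identical behaviour.

Nucleus sampling implements the smallest-prefix rule strictly: the candidate
set is the smallest probability-sorted prefix whose cumulative probability
*strictly exceeds* p, renormalized before drawing. p → 0 degenerates to
greedy decoding; p = 1 keeps the whole vocabulary (no prefix strictly
exceeds 1). The implementation is checked against an exhaustive
cumulative-sum oracle on random categorical distributions.

## The synthetic series

No public accession exists for the assay data the method was developed on,
so the generator emulates their structure rather than their values: a
spiro-bicyclic diamine scaffold with two substituent pools (30 acyl/sulfonyl
groups and 24 aryl/alkyl groups by default), additive per-substituent
contributions on log10(IC50) (base −6.5, contributions ~ Normal(0, 0.8),
assay noise 0.3 log units) and on log10(t1/2/min) (base log10(60),
contributions ~ Normal(0, 0.35), noise 0.15), IC50 clipped to span roughly
1 nM – 1 mM and half-lives 5 – 400 min. The compounds with the worst
noise-free model potency are flagged inactive and pinned at 1 mM, mirroring
the activity cliff at the bottom of a real series and making
"bottom-stratum" sampling meaningful. A parameter-recovery test regresses
generated log-potencies on substituent indicators and requires the
contributions back within 3 noise standard deviations at n ≥ 200.

What the generator does *not* emulate: real SAR non-additivity (interaction
terms between the two sites), scaffold hops, assay-to-assay drift,
stereochemistry, and the actual chemotypes of any real inhibitor series.
Passing tests on this synthetic series therefore demonstrate that the
pipeline's machinery is correct and that directed fine-tuning steers
generation toward the rewarded chemistry under a known ground truth — not
that the method will improve any particular real series.

## Problem sizes and numerical choices

The package's own studies are desk-scale by design. The split-accounting
checks use the full 554-compound/66-inactive series layout; the
prediction-count checks use the full 160 × 6 × 30 layout with a deliberately
small model; the learning-behaviour checks (memorization, directed
enrichment) use compact study designs that keep each run in the minutes
range on one CPU while leaving the learning signal intact.

The enrichment study deserves detail, because its design is what makes the
check meaningful. It uses a *dense* congeneric series — a piperazine core
with two family-structured substituent pools (seven para-substituted
benzoyl groups, six para-substituted aryl groups), 30 of the 42 possible
combinations drawn — whose potency model rewards one specific acyl
substituent by −2 log10 units. Density matters twice over: nearly every
member then has a ≥ 0.8-Tanimoto neighbour, so similarity transfer has
assignable targets (in a sparse random draw from large pools, nearest
neighbours sit around 0.65 and the transfer threshold assigns nothing); and
the rewarded-substituent ground truth makes "did the model learn the
direction" unambiguous. The model is a width-48 single-layer
encoder–decoder trained 30 epochs at batch 32 on score-weighted examples
(scale 12); predictions are drawn from the last five checkpoints for the
ten weakest molecules. Assigned predictions concentrate on the rewarded
low-nanomolar chemistry and the median-shift statistic comes out clearly
negative across seeds.

Numerical details worth knowing: ranks use competition (minimum) ranking
within ties; the similarity-transfer tie-break chooses the lowest IC50 among
equally similar references; enrichment histograms bin log10(IC50) one bin
per decade from 10^−9.5 with the inactive surrogate pinned in its own
terminal bin; the shift statistic is the difference in median log10(IC50)
between assigned predictions and the measured distribution (negative =
enrichment toward potency) with a one-sided Wilcoxon rank test alongside;
fingerprints are radius-2, 2048-bit folded circular fingerprints with binary
counts; and all randomness flows through per-stage seeds derived from one
master seed by stable string hashing, recorded in the run manifest.

Empty generations (a sampled sequence containing no atom token) are kept in
the prediction record with an empty canonical form so that counts conserve,
and are excluded from chemistry-level evaluation. Deduplication counts them
under the empty key.

## Design choices where the ground was open

* **Single-cut MMPs only.** Substituent-level edits are what the directed
  ordering is meant to capture; single cuts keep every fragmentation
  hand-verifiable and the constant-part ≥ 2/3 heavy-atom rule keeps pairs
  congeneric. Double cuts and hydrogen-swap pairs are out of scope.
* **Rank orientation vs raw-value orientation.** For a single property both
  give identical pair orientations; ranks are used throughout for
  uniformity with the multiobjective case.
* **PAINS screening** delegates to the OpenBabel SMARTS engine with a
  packaged, curated subset of the published PAINS families (the full
  catalogue numbers in the hundreds; the subset covers the motifs most
  relevant to this chemistry and the list is a plain-text file users can
  extend). The screen is monotone by construction: adding patterns can only
  remove molecules.
* **Novelty window** `[0.5, 0.95]` Tanimoto to the lead is the programmatic
  proxy for the manual "novel groups, small scaffold changes" triage; the
  final human inspection step of a real campaign is explicitly not
  automated.
* **Reachability** is decided by fragment matching: a prediction is one step
  away from a training molecule iff both split on a common constant part
  such that the training molecule exposes the transformation's left fragment
  and the prediction its right fragment. This is exact for single-cut
  transformations and avoids enumerating the full combinatorial product set,
  which is still available (capped) via `enumerateProducts()`.

## Known limitations

Training is CPU-bound R + BLAS with a compiled attention kernel; it is meant
for the desk-scale models above, not for million-molecule pretraining. The
aromaticity model and valence tables cover the organic subset (B, C, N, O,
P, S, halogens) without radicals or isotopes. The PAINS list is a subset,
not the full published catalogue. And the multiobjective score is the
unweighted rank sum — weighting schemes, additional properties, and
synthetic-accessibility triage are natural extensions that the data
structures already accommodate but the package does not implement.
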