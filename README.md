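# PairTune

Directed matched-molecular-pair fine-tuning of a SELFIES
sequence-to-sequence transformer for multiobjective lead optimization.

## The problem

In the lead-optimization phase of a drug-discovery campaign a congeneric
series of inhibitors — compounds sharing one scaffold and differing in their
substituents — must be improved on several axes at once, typically potency
(IC50 in a biochemical assay) and ADME properties such as microsomal
metabolic stability (half-life t1/2 in liver-microsome incubations). The
available measurements (a few hundred compounds) are far too few to train a
generative chemical language model from scratch.

PairTune implements a transfer-learning recipe for exactly this setting:

1. **Matched molecular pairs (MMPs).** Every molecule is fragmented at each
   acyclic single bond into a constant part (≥ 2/3 of the heavy atoms) and a
   variable part; molecules sharing an identical constant part form a pair
   that differs by one substituent swap.
2. **Directed ordering.** Each compound is ranked per property (1 = worst,
   N = best; ties share the minimum rank). The multiobjective score is the
   unweighted rank sum `score = rank_potency + rank_stability`. Every pair is
   oriented worse → better, so the model only sees property-improving
   transformations; tied pairs are kept in both orders.
3. **Score-weighted augmentation.** Pair *i* with score difference *d_i* is
   expanded into

       n_i = floor( (d_i − d_min) / (d_max − d_min) · n )

   training examples (default scale n = 200), each a freshly randomized
   SMILES of source and target converted to SELFIES — so strongly improving
   transformations dominate the training set, and the least-improving pairs
   drop out.
4. **Fine-tuning.** A small encoder–decoder transformer over SELFIES tokens,
   pretrained on undirected matched pairs from a scaffold-diverse corpus, is
   fine-tuned for 30 epochs (batch size 128, warmup/decay learning-rate
   schedule at scale 1).
5. **Generation.** New candidates are sampled per epoch checkpoint by
   nucleus (top-p) sampling at p = 0.9: each next token is drawn from the
   smallest probability-sorted vocabulary prefix whose cumulative
   probability exceeds 0.9. SELFIES guarantees every sample decodes to a
   valid molecule.
6. **Evaluation.** Retrospectively: hold out the top-20 most potent
   compounds, fine-tune on the rest, and count how often the model
   regenerates them; transfer potencies from fingerprint-nearest known
   compounds (Tanimoto on radius-2 circular fingerprints, threshold 0.8)
   and test whether the predicted distribution is enriched in potency.
   Prospectively: deduplicate predictions, remove PAINS matches, keep
   molecules inside a novelty window around the lead, and check whether any
   prediction is more than one known fragment swap away from the training
   set.

Because the assay data behind the original application are proprietary, the
package ships a synthetic congeneric-series generator (spiro-bicyclic
scaffold, two substituent pools, additive log-scale property models with an
inactive block pinned at IC50 = 1 mM) that reproduces the statistical
structure the pipeline assumes — all examples, tests and the acceptance
script run on it.

## Worked example

```r
library(PairTune)

ms <- generateSeries(seriesSpec(n_molecules = 40, n_inactive = 4, seed = 11))
ms
#> MoleculeSet with 40 molecules (4 inactive at 0.001 M)
#>   IC50 range: 1e-10 - 0.001 M; t1/2 range: 6.97 - 451 min

mp <- buildPairs(ms)
mp
#> MatchedPairSet with 60 pairs over 31 constant parts

st <- scoreMolecules(ms, "multi")         # rank-sum score, range [2, 2N]
dp <- orientPairs(mp, st)                 # worse -> better
dp
#> DirectedPairSet with 62 directed pairs (2 ties kept in both orders)

counts <- weightedCounts(directedPairs(dp)$score_diff, n = 20)
ex <- shuffleExamples(augmentPairs(dp, ms, counts, seed = 3), seed = 4)
fit <- trainModel(ex, modelConfig(n_layers = 1, d_model = 32, n_heads = 4,
                                  d_ff = 64, epochs = 20, dropout = 0,
                                  batch_size = 64, seed = 5), quiet = TRUE)
tail(fit$history, 1)
#>    epoch train_ppl val_ppl
#> 20    20  5.469759 5.89319

reps <- inferenceRepresentations(ms[1:5], k = 5, seed = 9)   # 5 x 6 inputs
ps <- predictBatch(fit$checkpoints, reps, seed = 11)
ps
#> PredictionSet: 600 records, 521 unique molecules, 19 empty generations
```

The perplexity is the exponential of the mean per-token negative
log-likelihood (1 = perfect next-token prediction; this one-minute toy run
is still far from converged — the studies in the test suite train deeper
models to perplexities below 1.5). The 600 records are one nucleus sample
per (30 input representations × 20 epoch checkpoints); the unique molecules
are their deduplicated canonical forms, and empty generations are sampled
sequences that emitted no atom token before the end sentinel.

`runPipeline(runConfig(...), "retrospective")` chains all stages — data,
pairing, orientation, augmentation, pretraining, fine-tuning, prediction,
evaluation — and writes per-stage CSV artifacts plus a JSON manifest with
derived per-stage seeds and record counts. A thin command-line front end
with per-stage subcommands is installed at `inst/cli/pairtune`.

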