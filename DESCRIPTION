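Package: PairTune
Title: Directed Matched Molecular Pair Fine-Tuning for Multiobjective
    Lead Optimization
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fine-tunes a small sequence-to-sequence transformer over
    SELFIES strings on property-ordered matched molecular pairs drawn
    from a congeneric inhibitor series, so that sampled analogues move
    toward better potency and/or microsomal stability. Provides the full
    pipeline: synthetic congeneric-series generation, canonical and
    randomized SMILES, SELFIES encoding, single-cut matched-pair
    fragmentation and transformation extraction, rank-sum multiobjective
    scoring, score-difference-weighted augmentation, transformer
    pretraining and fine-tuning with per-epoch checkpoints, nucleus
    (top-p) sampling, retrospective holdout-recovery and
    similarity-transfer evaluation, PAINS and novelty filtering, and
    one-step transformation-reachability analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    igraph,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel (obabel on PATH) for PAINS substructure
    screening
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'PairTune-package.R'
    'RcppExports.R'
    'augmentation.R'
    'chem-fingerprint.R'
    'chem-fragment.R'
    'chem-mol.R'
    'chem-selfies.R'
    'chem-write.R'
    'evaluation.R'
    'filters.R'
    'mmp.R'
    'pipeline.R'
    'sample.R'
    'scoring.R'
    'synthetic-data.R'
    'train.R'
    'vocab.R'
    'transformer.R'
    'utils.R'
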