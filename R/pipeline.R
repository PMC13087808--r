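## End-to-end orchestration of the two study designs.
##
## retrospective: split off the top molecules as a holdout, fine-tune on the
##   remainder ordered by potency alone (uniform augmentation), predict from
##   weak/inactive inference molecules at every epoch, then measure holdout
##   recovery and similarity-transferred potency enrichment.
## prospective: fine-tune on the whole series ordered by the rank-sum score
##   with score-difference-weighted augmentation, predict from all molecules,
##   then deduplicate, PAINS-screen, apply the novelty window and the
##   one-step reachability analysis.
##
## Per-stage seeds are derived from one master seed by stable hashing and
## recorded, with stage record counts, in the run manifest.

#' Pipeline run configuration
#'
#' Every stage parameter in one serializable list. `input_csv = NULL`
#' generates a synthetic congeneric series (see [seriesSpec()]).
#'
#' @param out_dir output directory for stage artifacts and the manifest.
#' @param input_csv optional molecule table (CSV schema of
#'   [writeMoleculeCsv()]); NULL generates synthetic data.
#' @param n_molecules,n_inactive synthetic series size (used when
#'   `input_csv` is NULL).
#' @param n_holdout,n_inference,n_inference_inactive,bottom_frac
#'   retrospective split parameters.
#' @param aug_times uniform augmentation count per pair (retrospective).
#' @param aug_scale Eq-style weighted augmentation scale (prospective).
#' @param inference_times randomized inference representations per molecule
#'   (the molecule additionally contributes its canonical SMILES).
#' @param pretrain_n pretraining corpus size.
#' @param pretrain_epochs pretraining epoch cap (default 10).
#' @param pretrain_patience early-stop patience on held-out perplexity (1).
#' @param model a [modelConfig()] for pretraining/fine-tuning.
#' @param sim_threshold similarity-transfer threshold.
#' @param sim_window novelty window around the lead.
#' @param lead_smiles optional lead compound; defaults to the best-scoring
#'   training molecule.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return a list of class `"RunConfig"`.
#' @export
runConfig <- function(out_dir = tempfile("pairtune_run_"), input_csv = NULL,
                      n_molecules = 160L, n_inactive = 16L,
                      n_holdout = 20L, n_inference = 30L,
                      n_inference_inactive = 10L, bottom_frac = 0.4,
                      aug_times = 30L, aug_scale = 200L,
                      inference_times = 5L,
                      pretrain_n = 300L, pretrain_epochs = 10L,
                      pretrain_patience = 1L,
                      model = modelConfig(),
                      sim_threshold = 0.8, sim_window = c(0.5, 0.95),
                      lead_smiles = NULL, seed = 1L) {
  structure(as.list(environment()), class = "RunConfig")
}

.stage_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[pipeline] ", fmt), ...))
}

#' Run the full pipeline
#'
#' Executes data (generation) -> pairing -> orientation -> augmentation ->
#' pretraining -> fine-tuning -> prediction -> evaluation/filtering, writing
#' each stage's artifact and a JSON manifest into `config$out_dir`.
#'
#' @param config a [runConfig()].
#' @param design `"retrospective"` or `"prospective"`.
#' @param quiet suppress stage progress messages.
#' @return (invisibly) a list with all stage objects: `molecules`, `split`
#'   (retrospective), `pairs`, `directed`, `examples`, `pretrain`,
#'   `finetune`, `predictions`, `evaluation`, `manifest`.
#' @export
runPipeline <- function(config, design = c("retrospective", "prospective"),
                        quiet = FALSE) {
  design <- match.arg(design)
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list()
  sd <- function(stage) {
    seeds[[stage]] <<- derive_seed(config$seed, stage)
    seeds[[stage]]
  }
  manifest <- list(design = design,
                   config = config[setdiff(names(config), "model")],
                   model = unclass(config$model), stages = list())
  note <- function(stage, ...) manifest$stages[[stage]] <<- list(...)

  ## -- data -------------------------------------------------------------
  if (is.null(config$input_csv)) {
    spec <- seriesSpec(n_molecules = config$n_molecules,
                       n_inactive = config$n_inactive, seed = sd("gen-data"))
    ms <- generateSeries(spec)
  } else {
    ms <- readMoleculeCsv(config$input_csv)
  }
  writeMoleculeCsv(ms, file.path(config$out_dir, "molecules.csv"))
  .stage_log(quiet, "data: %d molecules (%d inactive)", nMolecules(ms),
             sum(molecules(ms)$is_inactive))
  note("data", n = nMolecules(ms), n_inactive = sum(molecules(ms)$is_inactive))

  split <- NULL
  if (design == "retrospective") {
    split <- makeRetrospectiveSplit(ms, seed = sd("split"),
                                    n_holdout = config$n_holdout,
                                    n_inference = config$n_inference,
                                    n_inference_inactive = config$n_inference_inactive,
                                    bottom_frac = config$bottom_frac)
    train_ms <- ms[match(split$train, molecules(ms)$id)]
    note("split", train = length(split$train), holdout = length(split$holdout),
         inference = length(split$inference))
    .stage_log(quiet, "split: %d train / %d holdout / %d inference",
               length(split$train), length(split$holdout), length(split$inference))
  } else {
    train_ms <- ms
  }

  ## -- pairs / orientation / augmentation -------------------------------
  mps <- buildPairs(train_ms)
  utils::write.csv(pairs_df(mps), file.path(config$out_dir, "pairs.csv"),
                   row.names = FALSE)
  objective <- if (design == "prospective") "multi" else "potency"
  st <- scoreMolecules(train_ms, objective)
  writeScoreTable(st, file.path(config$out_dir, "scores.csv"))
  dps <- orientPairs(mps, st)
  utils::write.csv(directedPairs(dps), file.path(config$out_dir, "directed_pairs.csv"),
                   row.names = FALSE)
  .stage_log(quiet, "pairs: %d matched, %d directed", nrow(pairs_df(mps)),
             nrow(directedPairs(dps)))

  counts <- if (design == "prospective")
    weightedCounts(directedPairs(dps)$score_diff, config$aug_scale)
  else rep(config$aug_times, nrow(directedPairs(dps)))
  examples <- shuffleExamples(
    augmentPairs(dps, train_ms, counts, seed = sd("augment")),
    seed = sd("shuffle"))
  writeParallelCorpus(examples, file.path(config$out_dir, "train_src.txt"),
                      file.path(config$out_dir, "train_tgt.txt"))
  note("pairs", matched = nrow(pairs_df(mps)), directed = nrow(directedPairs(dps)),
       examples = nrow(examples))
  .stage_log(quiet, "augmentation: %d training examples", nrow(examples))

  ## -- pretraining -------------------------------------------------------
  corpus <- generatePretrainCorpus(config$pretrain_n, seed = sd("pretrain-corpus"))
  pre_examples <- pretrainExamples(corpus, seed = sd("pretrain-aug"))
  vocab <- buildVocabulary(pre_examples$source_selfies, pre_examples$target_selfies,
                           examples$source_selfies, examples$target_selfies)
  pre_cfg <- config$model
  pre_cfg$epochs <- config$pretrain_epochs
  pre_cfg$seed <- sd("pretrain")
  pre_fit <- trainModel(pre_examples, pre_cfg, vocab = vocab,
                        phase = "pretrain", patience = config$pretrain_patience,
                        quiet = quiet)
  base <- bestCheckpoint(pre_fit)
  note("pretrain", corpus = length(corpus), examples = nrow(pre_examples),
       epochs_run = nrow(pre_fit$history), start_epoch = base@epoch)
  .stage_log(quiet, "pretraining: stopped at epoch %d, fine-tuning from epoch %d",
             nrow(pre_fit$history), base@epoch)

  ## -- fine-tuning -------------------------------------------------------
  ft_cfg <- config$model
  ft_cfg$seed <- sd("finetune")
  ft_fit <- trainModel(examples, ft_cfg, init = base, phase = "finetune",
                       checkpoint_dir = file.path(config$out_dir, "checkpoints"),
                       quiet = quiet)
  utils::write.csv(ft_fit$history, file.path(config$out_dir, "finetune_history.csv"),
                   row.names = FALSE)
  note("finetune", epochs = nrow(ft_fit$history))

  ## -- prediction --------------------------------------------------------
  infer_ms <- if (design == "retrospective")
    ms[match(split$inference, molecules(ms)$id)] else ms
  reps <- inferenceRepresentations(infer_ms, k = config$inference_times,
                                   seed = sd("inference-reps"))
  preds <- predictBatch(ft_fit$checkpoints, reps, seed = sd("predict"))
  utils::write.csv(predictions(preds), file.path(config$out_dir, "predictions.csv"),
                   row.names = FALSE)
  note("predict", inputs = nrow(reps), checkpoints = length(ft_fit$checkpoints),
       records = nrow(predictions(preds)))
  .stage_log(quiet, "prediction: %d records (%d inputs x %d checkpoints)",
             nrow(predictions(preds)), nrow(reps), length(ft_fit$checkpoints))

  ## -- evaluation / filtering -------------------------------------------
  counts_map <- dedupPredictions(preds)
  evaluation <- list(unique_predictions = sum(nzchar(names(counts_map))))
  if (design == "retrospective") {
    holdout_ms <- ms[match(split$holdout, molecules(ms)$id)]
    rec <- holdoutRecovery(counts_map, holdout_ms)
    tr <- similarityTransfer(setdiff(names(counts_map), ""), ms,
                             threshold = config$sim_threshold)
    enr <- enrichmentSummary(tr$ic50_assigned, molecules(ms)$ic50_molar,
                             inactive_ic50 = inactiveIC50(ms))
    utils::write.csv(tr, file.path(config$out_dir, "similarity_transfer.csv"),
                     row.names = FALSE)
    evaluation$holdout_recovery <- rec
    evaluation$recovered <- sum(rec > 0)
    evaluation$enrichment <- enr
    note("evaluate", unique = evaluation$unique_predictions,
         recovered = evaluation$recovered,
         shift = if (is.null(enr$shift)) NA else enr$shift)
    .stage_log(quiet, "evaluation: %d unique, %d/%d holdout recovered, shift %.3f",
               evaluation$unique_predictions, evaluation$recovered,
               length(rec), if (is.null(enr$shift)) NA else enr$shift)
  } else {
    uniq <- setdiff(names(counts_map), "")
    pains <- painsFilter(uniq)
    surv <- pains$smiles[pains$passed]
    lead <- config$lead_smiles
    if (is.null(lead)) {
      tab <- scores_df(st)
      lead <- molecules(train_ms)$smiles[match(tab$id[which.max(tab$score)],
                                               molecules(train_ms)$id)]
    }
    nov <- noveltyFilter(surv, train_ms, lead, config$sim_window)
    short <- nov$smiles[nov$passed]
    trans <- extractTransformations(mps)
    top <- utils::head(short[order(-counts_map[short])], 10L)
    reach <- lapply(top, oneStepReachable, training = train_ms,
                    transformations = trans)
    utils::write.csv(pains, file.path(config$out_dir, "pains_report.csv"),
                     row.names = FALSE)
    utils::write.csv(nov, file.path(config$out_dir, "novelty_report.csv"),
                     row.names = FALSE)
    evaluation$pains_survivors <- length(surv)
    evaluation$novelty_survivors <- length(short)
    evaluation$lead <- lead
    evaluation$reachability <- data.frame(
      smiles = top,
      reachable = vapply(reach, `[[`, logical(1), "reachable"))
    note("filter", unique = evaluation$unique_predictions,
         pains_pass = length(surv), novelty_pass = length(short),
         one_step_reachable = sum(evaluation$reachability$reachable))
    .stage_log(quiet, "funnel: %d unique -> %d PAINS-pass -> %d in novelty window",
               evaluation$unique_predictions, length(surv), length(short))
  }

  manifest$seeds <- seeds
  manifest$vocab_hash <- str_hash32(paste(vocabTokens(vocab), collapse = " "))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(molecules = ms, split = split, pairs = mps, directed = dps,
                 examples = examples, pretrain = pre_fit, finetune = ft_fit,
                 predictions = preds, evaluation = evaluation,
                 manifest = manifest))
}

#' Build undirected pretraining examples from a corpus
#'
#' Matched pairs from the corpus are used in both orders (no property
#' direction), each pair once per direction with one randomized SMILES
#' per side -- the hit-expansion style base-model training set.
#'
#' @param corpus character vector of canonical SMILES.
#' @param times augmentations per direction (default 1).
#' @param seed integer seed.
#' @return data.frame with `source_selfies`, `target_selfies`.
#' @export
pretrainExamples <- function(corpus, times = 1L, seed = 1L) {
  ms <- MoleculeSet(sprintf("P%05d", seq_along(corpus)), corpus,
                    canonicalize = FALSE)
  mps <- buildPairs(ms)
  pr <- pairs_df(mps)
  if (!nrow(pr)) stop("pretraining corpus yielded no matched pairs")
  both <- data.frame(source_id = c(pr$id_a, pr$id_b),
                     target_id = c(pr$id_b, pr$id_a),
                     score_diff = 0,
                     constant = c(pr$constant, pr$constant),
                     variable_source = c(pr$variable_a, pr$variable_b),
                     variable_target = c(pr$variable_b, pr$variable_a))
  dps <- new("DirectedPairSet", pairs = both)
  augmentPairs(dps, ms, rep(as.integer(times), nrow(both)), seed = seed)
}
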