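## Training: token-level cross-entropy over (source, target) SELFIES pairs,
## Adam with the inverse-sqrt warmup schedule, one checkpoint per epoch, and
## per-epoch perplexity (exp of the mean per-token negative log-likelihood)
## on a held-out slice. Pretraining can stop early when the held-out
## perplexity stops improving.

.encode_examples <- function(vocab, examples) {
  src <- lapply(examples$source_selfies, function(s) c(.encode_tokens(vocab, s), .EOS_ID))
  tin <- lapply(examples$target_selfies, function(s) c(.BOS_ID, .encode_tokens(vocab, s)))
  tout <- lapply(examples$target_selfies, function(s) c(.encode_tokens(vocab, s), .EOS_ID))
  list(src = src, tin = tin, tout = tout)
}

.batch_nll <- function(params, cfg, enc, idx, drop_fn = NULL) {
  src <- .pad_batch(enc$src[idx])
  tin <- .pad_batch(enc$tin[idx])
  tout <- .pad_batch(enc$tout[idx])
  ec <- .encoder_fwd(params, cfg, src, drop_fn)
  dc <- .decoder_fwd(params, cfg, ec$out, src, tin, drop_fn)
  labels <- as.vector(t(tout))
  ce <- .ce_loss(dc$logits, labels)
  list(ec = ec, dc = dc, ce = ce, src = src, tin = tin)
}

## held-out perplexity (no dropout)
.eval_ppl <- function(params, cfg, enc, idx) {
  if (!length(idx)) return(NA_real_)
  tot <- 0; ntok <- 0L
  for (chunk in split(idx, ceiling(seq_along(idx) / cfg$batch_size))) {
    r <- .batch_nll(params, cfg, enc, chunk)
    tot <- tot + sum(r$ce$nll[r$ce$valid])
    ntok <- ntok + r$ce$n_tokens
  }
  exp(tot / ntok)
}

#' Train or fine-tune the transformer
#'
#' Runs `config$epochs` epochs of cross-entropy training and returns one
#' checkpoint per epoch plus the perplexity history. Fine-tuning starts from
#' the supplied pretraining checkpoint (`init`); a fresh model is initialized
#' when `init` is NULL. With `patience` set (pretraining), training stops
#' after the held-out perplexity has failed to improve for that many
#' consecutive epochs.
#'
#' @param examples data.frame with columns `source_selfies`,
#'   `target_selfies` (see [augmentPairs()]).
#' @param config a [modelConfig()].
#' @param init a [TransformerModel] checkpoint to start from, or NULL.
#' @param phase label stored in the checkpoints (`"pretrain"`/`"finetune"`).
#' @param patience early-stopping patience in epochs (NULL = run all epochs).
#' @param checkpoint_dir optional directory for `{phase}_epoch{NN}.rds`
#'   checkpoint files.
#' @param vocab optional [Vocabulary]; defaults to the checkpoint's (when
#'   fine-tuning) or one built from `examples`.
#' @param quiet suppress per-epoch progress messages.
#' @return list with `checkpoints` (list of [TransformerModel], one per
#'   epoch), `history` (data.frame epoch/train_ppl/val_ppl) and `vocab`.
#' @export
trainModel <- function(examples, config = modelConfig(), init = NULL,
                       phase = if (is.null(init)) "pretrain" else "finetune",
                       patience = NULL, checkpoint_dir = NULL, vocab = NULL,
                       quiet = FALSE) {
  stopifnot(nrow(examples) >= 1L)
  cfg <- config
  if (is.null(vocab))
    vocab <- if (!is.null(init)) init@vocab
             else buildVocabulary(examples$source_selfies, examples$target_selfies)
  enc <- .encode_examples(vocab, examples)
  n <- nrow(examples)

  rng <- local_rng(derive_seed(cfg$seed, paste0("train-", phase)))
  n_val <- min(max(if (n >= 20L) ceiling(cfg$val_frac * n) else 0L, 0L), n - 1L)
  perm <- rng$sample_int(n)
  val_idx <- if (n_val > 0L) perm[seq_len(n_val)] else integer(0)
  train_idx <- setdiff(perm, val_idx)

  params <- if (!is.null(init)) init@params
            else .init_params(cfg, vocabSize(vocab), cfg$seed)
  state <- list(params = params, m = .tree_zero(params), v = .tree_zero(params),
                t = 0L)
  drop_fn <- if (cfg$dropout > 0) {
    function(len) ifelse(rng$runif(len) < cfg$dropout, 0, 1 / (1 - cfg$dropout))
  } else NULL

  checkpoints <- list()
  history <- data.frame(epoch = integer(), train_ppl = numeric(),
                        val_ppl = numeric())
  best_val <- Inf; stale <- 0L
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE)

  for (ep in seq_len(cfg$epochs)) {
    ord <- train_idx[rng$sample_int(length(train_idx))]
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    tot_nll <- 0; tot_tok <- 0L
    for (bt in batches) {
      r <- .batch_nll(state$params, cfg, enc, bt, drop_fn)
      if (!is.finite(r$ce$loss))
        stop(sprintf("non-finite loss at epoch %d (step %d); try a smaller lr_scale",
                     ep, state$t + 1L))
      grads <- .model_bwd(state$params, cfg, r$ec, r$dc, r$ce$dlogits,
                          r$src, r$tin)
      lr <- .noam_lr(state$t + 1L, cfg)
      state <- .adam_step(state, grads, lr)
      tot_nll <- tot_nll + sum(r$ce$nll[r$ce$valid])
      tot_tok <- tot_tok + r$ce$n_tokens
    }
    train_ppl <- exp(tot_nll / tot_tok)
    val_ppl <- .eval_ppl(state$params, cfg, enc, val_idx)
    history <- rbind(history, data.frame(epoch = ep, train_ppl = train_ppl,
                                         val_ppl = val_ppl))
    ck <- new("TransformerModel", params = state$params, config = unclass(cfg),
              vocab = vocab, epoch = ep, phase = phase)
    checkpoints[[ep]] <- ck
    if (!is.null(checkpoint_dir))
      saveCheckpoint(ck, file.path(checkpoint_dir,
                                   sprintf("%s_epoch%02d.rds", phase, ep)))
    if (!quiet)
      message(sprintf("[%s] epoch %d/%d: train ppl %.3f, val ppl %.3f",
                      phase, ep, cfg$epochs, train_ppl, val_ppl))
    if (!is.null(patience) && is.finite(val_ppl)) {
      ## "improved" = at least 0.1% relative perplexity reduction
      if (val_ppl < best_val * (1 - 1e-3)) { best_val <- val_ppl; stale <- 0L }
      else {
        stale <- stale + 1L
        if (stale >= patience) {
          if (!quiet) message(sprintf("early stop at epoch %d (patience %d)", ep, patience))
          break
        }
      }
    }
  }
  list(checkpoints = checkpoints, history = history, vocab = vocab)
}

#' Select the pretraining checkpoint for fine-tuning
#'
#' Returns the checkpoint at the last epoch before the held-out perplexity
#' stopped improving (the epoch with the best perplexity).
#'
#' @param fit result of [trainModel()].
#' @return a [TransformerModel].
#' @export
bestCheckpoint <- function(fit) {
  ppl <- fit$history$val_ppl
  if (all(is.na(ppl))) ppl <- fit$history$train_ppl
  fit$checkpoints[[which.min(ppl)]]
}

#' Save / load a model checkpoint
#'
#' Round-trips bit-identically: a reloaded checkpoint reproduces identical
#' log-likelihoods and samples.
#'
#' @param model a [TransformerModel].
#' @param path file path.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(params = model@params, config = model@config,
               vocab = vocabTokens(model@vocab), epoch = model@epoch,
               phase = model@phase), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  new("TransformerModel", params = x$params, config = x$config,
      vocab = new("Vocabulary", tokens = x$vocab), epoch = x$epoch,
      phase = x$phase)
}

#' Log-likelihood of target given source under a checkpoint
#'
#' Used for checkpoint round-trip verification and model comparison.
#'
#' @param model a [TransformerModel].
#' @param examples data.frame with `source_selfies`, `target_selfies`.
#' @return total log-likelihood (sum over target tokens).
#' @export
logLikelihood <- function(model, examples) {
  cfg <- model@config
  enc <- .encode_examples(model@vocab, examples)
  tot <- 0
  for (chunk in split(seq_len(nrow(examples)),
                      ceiling(seq_len(nrow(examples)) / cfg$batch_size))) {
    r <- .batch_nll(model@params, cfg, enc, chunk)
    tot <- tot - sum(r$ce$nll[r$ce$valid])
  }
  tot
}
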