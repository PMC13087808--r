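## Nucleus (top-p) sampling and batched prediction.
##
## At each decoding step the candidate set is the smallest prefix of the
## probability-sorted vocabulary whose cumulative probability strictly
## exceeds p; probabilities are renormalized within the set and the next
## token drawn from it. p -> 0 reduces to greedy decoding; p = 1 keeps the
## whole vocabulary.

#' Nucleus candidate set of a categorical distribution
#'
#' @param probs numeric probability vector (sums to 1).
#' @param p nucleus threshold in (0, 1].
#' @return integer indices of the candidate set, most probable first.
#' @export
nucleusCandidates <- function(probs, p) {
  o <- order(probs, decreasing = TRUE)
  cs <- cumsum(probs[o])
  k <- which(cs > p)[1]
  if (is.na(k)) k <- length(probs)
  o[seq_len(k)]
}

## one sampling step for a batch: probs B x V, u B uniforms -> token ids
.nucleus_step <- function(probs, p, u) {
  nucleus_step_cpp(probs, p, u)
}

## grow a (t, dh, S) cube by one time step
.cube_append <- function(old, new) {
  if (is.null(old)) return(new)
  d <- dim(old)
  out <- array(0, c(d[1] + 1L, d[2], d[3]))
  out[seq_len(d[1]), , ] <- old
  out[d[1] + 1L, , ] <- new
  out
}

## Batched autoregressive decoding with per-layer key/value caches (the
## pre-layer-norm architecture is strictly causal, so each step only needs
## the new position's activations). Returns a list of generated id vectors.
## Logit equivalence with the full re-forward decoder is covered in tests.
.decode_batch <- function(model, src_ids, p, rng, max_len) {
  cfg <- model@config
  params <- model@params
  H <- cfg$n_heads
  D <- cfg$d_model
  dh <- D %/% H
  L <- cfg$n_layers
  B <- nrow(src_ids)
  Ts <- ncol(src_ids)
  ec <- .encoder_fwd(params, cfg, src_ids)
  enc_out <- ec$out

  ## fixed cross-attention keys/values and source pad mask
  crossK <- lapply(params$dec, function(w) .to_heads(enc_out %*% w$cross$Wk, B, Ts, H))
  crossV <- lapply(params$dec, function(w) .to_heads(enc_out %*% w$cross$Wv, B, Ts, H))
  smask <- .pad_mask(src_ids) %||% matrix(0, 0, 0)
  selfK <- vector("list", L)
  selfV <- vector("list", L)

  pos <- .pos_encoding(max_len + 1L, D)
  gen <- vector("list", B)
  orig <- seq_len(B)                 # original index of each active row
  last_tok <- rep(.BOS_ID, B)
  toks <- lapply(seq_len(B), function(i) integer(0))

  for (step in seq_len(max_len)) {
    nb <- length(orig)
    x <- params$embed[last_tok, , drop = FALSE] * sqrt(D) +
         pos[rep(step, nb), , drop = FALSE]
    for (l in seq_len(L)) {
      w <- params$dec[[l]]
      h <- .ln_fwd(x, w$ln1$g, w$ln1$b)$y
      q <- .to_heads(h %*% w$self$Wq, nb, 1L, H)
      selfK[[l]] <- .cube_append(selfK[[l]], .to_heads(h %*% w$self$Wk, nb, 1L, H))
      selfV[[l]] <- .cube_append(selfV[[l]], .to_heads(h %*% w$self$Wv, nb, 1L, H))
      P <- softmax_dim2(bmm(q, selfK[[l]], FALSE, TRUE) / sqrt(dh),
                        FALSE, matrix(0, 0, 0), H)
      x <- x + .from_heads(bmm(P, selfV[[l]]), nb, 1L, H) %*% w$self$Wo
      h2 <- .ln_fwd(x, w$ln2$g, w$ln2$b)$y
      q2 <- .to_heads(h2 %*% w$cross$Wq, nb, 1L, H)
      P2 <- softmax_dim2(bmm(q2, crossK[[l]], FALSE, TRUE) / sqrt(dh),
                         FALSE, smask, H)
      x <- x + .from_heads(bmm(P2, crossV[[l]]), nb, 1L, H) %*% w$cross$Wo
      h3 <- .ln_fwd(x, w$ln3$g, w$ln3$b)$y
      x <- x + .ff_fwd(h3, w$ff)$y
    }
    xf <- .ln_fwd(x, params$dec_ln$g, params$dec_ln$b)$y
    logits <- .lin_fwd(xf, params$Wout, params$bout)
    logits[, .PAD_ID] <- -1e30
    mx <- apply(logits, 1, max)
    e <- exp(logits - mx)
    probs <- e / rowSums(e)
    nxt <- .nucleus_step(probs, p, rng$runif(nb))

    for (i in seq_len(nb)) toks[[orig[i]]] <- c(toks[[orig[i]]], nxt[i])
    done <- nxt == .EOS_ID
    if (any(done)) {
      for (i in which(done)) {
        b <- orig[i]
        gen[[b]] <- toks[[b]][seq_len(length(toks[[b]]) - 1L)]
      }
      keep <- which(!done)
      if (!length(keep)) return(gen)
      slices <- as.vector(vapply(keep, function(i) (i - 1L) * H + seq_len(H),
                                 integer(H)))
      for (l in seq_len(L)) {
        selfK[[l]] <- selfK[[l]][, , slices, drop = FALSE]
        selfV[[l]] <- selfV[[l]][, , slices, drop = FALSE]
        crossK[[l]] <- crossK[[l]][, , slices, drop = FALSE]
        crossV[[l]] <- crossV[[l]][, , slices, drop = FALSE]
      }
      if (length(smask)) smask <- smask[, keep, drop = FALSE]
      orig <- orig[keep]
      nxt <- nxt[keep]
    }
    last_tok <- nxt
  }
  for (b in orig) gen[[b]] <- toks[[b]]
  gen
}

## reference decoder without caches (full re-forward each step); retained for
## the equivalence test against the incremental path
.decode_batch_full <- function(model, src_ids, p, rng, max_len) {
  cfg <- model@config
  params <- model@params
  B <- nrow(src_ids)
  ec <- .encoder_fwd(params, cfg, src_ids)
  gen <- vector("list", B)
  active <- seq_len(B)
  tgt <- matrix(.BOS_ID, B, 1L)
  Ts <- ncol(src_ids)
  enc_rows_of <- function(sel) as.vector(vapply(sel, function(b)
    (b - 1L) * Ts + seq_len(Ts), integer(Ts)))
  for (step in seq_len(max_len)) {
    sel <- active
    dc <- .decoder_fwd(params, cfg, ec$out[enc_rows_of(sel), , drop = FALSE],
                       src_ids[sel, , drop = FALSE], tgt[sel, , drop = FALSE])
    Tt <- ncol(tgt)
    logits <- dc$logits[(seq_along(sel) - 1L) * Tt + Tt, , drop = FALSE]
    logits[, .PAD_ID] <- -1e30
    mx <- apply(logits, 1, max)
    e <- exp(logits - mx)
    probs <- e / rowSums(e)
    nxt <- .nucleus_step(probs, p, rng$runif(length(sel)))
    tgt <- cbind(tgt, .PAD_ID)
    tgt[sel, ncol(tgt)] <- nxt
    done <- nxt == .EOS_ID
    for (i in which(done)) {
      b <- sel[i]
      ids <- unname(tgt[b, -1L])
      gen[[b]] <- ids[seq_len(which(ids == .EOS_ID)[1] - 1L)]
    }
    active <- sel[!done]
    if (!length(active)) break
  }
  for (b in active) {
    ids <- unname(tgt[b, -1L])
    gen[[b]] <- ids[ids != .PAD_ID]
  }
  gen
}

#' Sample one continuation by nucleus sampling
#'
#' @param model a [TransformerModel] checkpoint.
#' @param source_selfies a single SELFIES string (the input molecule).
#' @param p nucleus threshold; defaults to the model's configured value.
#' @param seed integer seed (same seed, same output).
#' @param max_len maximum generated tokens.
#' @return character vector of generated SELFIES tokens, with attribute
#'   `"ended"` (TRUE if `</s>` was emitted before `max_len`).
#' @export
nucleusSample <- function(model, source_selfies, p = model@config$nucleus_p,
                          seed = 1L, max_len = model@config$max_len) {
  stopifnot(p > 0, p <= 1)
  rng <- local_rng(derive_seed(seed, "nucleus"))
  src <- .pad_batch(list(c(.encode_tokens(model@vocab, source_selfies), .EOS_ID)))
  ids <- .decode_batch(model, src, p, rng, max_len)[[1]]
  out <- vocabTokens(model@vocab)[ids[ids > 4L]]
  attr(out, "ended") <- length(ids) < max_len || any(ids == .EOS_ID)
  out
}

#' Predict molecules from every checkpoint for every input representation
#'
#' Draws exactly one nucleus sample per (checkpoint, input representation)
#' and decodes it to a canonical SMILES. Empty generations (no atom before
#' `</s>`) are kept and flagged by an empty `smiles` string.
#'
#' @param checkpoints list of [TransformerModel] (e.g. the per-epoch
#'   checkpoints of a fine-tuning run).
#' @param inputs data.frame with columns `id`, `selfies` (see
#'   [inferenceRepresentations()]).
#' @param p nucleus threshold; defaults to the first checkpoint's configured
#'   value.
#' @param seed integer seed.
#' @param max_len maximum generated tokens per sample.
#' @return a [PredictionSet] with one record per (checkpoint, input).
#' @export
predictBatch <- function(checkpoints, inputs, p = NULL, seed = 1L,
                         max_len = NULL) {
  stopifnot(length(checkpoints) >= 1L, nrow(inputs) >= 1L)
  if (is.null(p)) p <- checkpoints[[1]]@config$nucleus_p
  if (is.null(max_len)) max_len <- checkpoints[[1]]@config$max_len
  rows <- vector("list", length(checkpoints))
  for (ci in seq_along(checkpoints)) {
    model <- checkpoints[[ci]]
    rng <- local_rng(derive_seed(seed, paste0("predict-", ci)))
    src <- .pad_batch(lapply(inputs$selfies, function(s)
      c(.encode_tokens(model@vocab, s), .EOS_ID)))
    gen <- .decode_batch(model, src, p, rng, max_len)
    toks <- vocabTokens(model@vocab)
    selfies <- vapply(gen, function(ids) pasteSelfies(toks[ids[ids > 4L]]),
                      character(1))
    smi <- vapply(selfies, selfies_canonical_one, character(1),
                  USE.NAMES = FALSE)
    rows[[ci]] <- data.frame(input_id = inputs$id, epoch = model@epoch,
                             smiles = smi, selfies = selfies)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  new("PredictionSet", records = out)
}
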