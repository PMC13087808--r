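## A small encoder-decoder transformer over SELFIES tokens.
##
## Pre-layer-norm architecture: token embedding (shared between encoder and
## decoder) with sinusoidal positions, multi-head attention (self-attention
## in the encoder; causal self-attention plus cross-attention in the
## decoder), position-wise feed-forward blocks with ReLU, and a linear output
## projection. Forward and backward passes are written against one compiled
## primitive (batched matrix multiply); everything else is R matrix algebra.
##
## Activations are laid out as (B*T) x D matrices with row (b-1)*T + t;
## attention reshapes them into (T, d_head, H*B) cubes, slice (b-1)*H + h.

#' @include vocab.R
NULL

#' Transformer configuration
#'
#' @param n_layers encoder and decoder layer count (default 2).
#' @param d_model model width (default 128); must be divisible by `n_heads`.
#' @param n_heads attention heads (default 4).
#' @param d_ff feed-forward width (default 256).
#' @param dropout dropout probability on embeddings and sublayer outputs.
#' @param batch_size training batch size (default 128).
#' @param epochs fine-tuning epochs (default 30).
#' @param nucleus_p nucleus sampling threshold in (0, 1] (default 0.9).
#' @param lr_scale scale factor of the warmup/decay learning-rate schedule
#'   (the "learning rate" in the OpenNMT convention; default 1).
#' @param warmup warmup steps of the schedule (default 400).
#' @param max_len maximum generated token count (default 80).
#' @param val_frac held-out fraction for the per-epoch perplexity (default
#'   0.05).
#' @param seed integer seed for initialization, batching and dropout.
#' @return a list of class `"ModelConfig"`.
#' @export
modelConfig <- function(n_layers = 2L, d_model = 128L, n_heads = 4L,
                        d_ff = 256L, dropout = 0.1, batch_size = 128L,
                        epochs = 30L, nucleus_p = 0.9, lr_scale = 1,
                        warmup = 400L, max_len = 80L, val_frac = 0.05,
                        seed = 1L) {
  stopifnot(d_model %% n_heads == 0L, nucleus_p > 0, nucleus_p <= 1,
            batch_size >= 1L, epochs >= 1L, dropout >= 0, dropout < 1)
  structure(list(n_layers = as.integer(n_layers), d_model = as.integer(d_model),
                 n_heads = as.integer(n_heads), d_ff = as.integer(d_ff),
                 dropout = dropout, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), nucleus_p = nucleus_p,
                 lr_scale = lr_scale, warmup = as.integer(warmup),
                 max_len = as.integer(max_len), val_frac = val_frac,
                 seed = as.integer(seed)),
            class = "ModelConfig")
}

#' TransformerModel: parameters, vocabulary and training phase
#'
#' @slot params nested list of weight matrices.
#' @slot config the `ModelConfig` used to build the model.
#' @slot vocab the [Vocabulary].
#' @slot epoch epoch index of this checkpoint (0 = untrained).
#' @slot phase `"fresh"`, `"pretrain"` or `"finetune"`.
#' @export
setClass("TransformerModel",
  representation(params = "list", config = "list", vocab = "Vocabulary",
                 epoch = "integer", phase = "character"))

setMethod("show", "TransformerModel", function(object) {
  np <- sum(vapply(rapply(object@params, identity, how = "unlist"),
                   length, integer(1)))
  cat(sprintf("TransformerModel (%s, epoch %d): %d layers, width %d, %d heads, vocab %d, %d parameters\n",
              object@phase, object@epoch, object@config$n_layers,
              object@config$d_model, object@config$n_heads,
              vocabSize(object@vocab), np))
})

## ---- initialization --------------------------------------------------------

.xavier <- function(rng, nin, nout) {
  matrix(rng$rnorm(nin * nout, 0, sqrt(2 / (nin + nout))), nin, nout)
}

.init_attn <- function(rng, D) {
  list(Wq = .xavier(rng, D, D), Wk = .xavier(rng, D, D),
       Wv = .xavier(rng, D, D), Wo = .xavier(rng, D, D))
}

.init_ln <- function(D) list(g = rep(1, D), b = rep(0, D))

.init_ff <- function(rng, D, F_) {
  list(W1 = .xavier(rng, D, F_), b1 = rep(0, F_),
       W2 = .xavier(rng, F_, D), b2 = rep(0, D))
}

.init_params <- function(cfg, V, seed) {
  rng <- local_rng(derive_seed(seed, "init"))
  D <- cfg$d_model
  enc <- lapply(seq_len(cfg$n_layers), function(l)
    list(ln1 = .init_ln(D), attn = .init_attn(rng, D),
         ln2 = .init_ln(D), ff = .init_ff(rng, D, cfg$d_ff)))
  dec <- lapply(seq_len(cfg$n_layers), function(l)
    list(ln1 = .init_ln(D), self = .init_attn(rng, D),
         ln2 = .init_ln(D), cross = .init_attn(rng, D),
         ln3 = .init_ln(D), ff = .init_ff(rng, D, cfg$d_ff)))
  list(embed = .xavier(rng, V, D), enc = enc, enc_ln = .init_ln(D),
       dec = dec, dec_ln = .init_ln(D),
       Wout = .xavier(rng, D, V), bout = rep(0, V))
}

## sinusoidal positions (T x D)
.pos_encoding <- function(T_, D) {
  pos <- matrix(0, T_, D)
  t <- seq_len(T_) - 1
  for (k in seq_len(D %/% 2)) {
    w <- 1 / 10000^((2 * (k - 1)) / D)
    pos[, 2 * k - 1] <- sin(t * w)
    pos[, 2 * k] <- cos(t * w)
  }
  pos
}

## ---- primitive layers ------------------------------------------------------

.lin_fwd <- function(x, W, b = NULL) {
  y <- x %*% W
  if (!is.null(b)) y <- sweep(y, 2, b, "+")
  y
}

.ln_fwd <- function(x, g, b) {
  D <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  iv <- 1 / sqrt(v + 1e-5)
  xhat <- xc * iv
  list(y = sweep(xhat, 2, g, "*") + rep(b, each = nrow(x)),
       xhat = xhat, iv = iv, g = g)
}

.ln_bwd <- function(dy, cache) {
  xhat <- cache$xhat; iv <- cache$iv
  dg <- colSums(dy * xhat); db <- colSums(dy)
  dxhat <- sweep(dy, 2, cache$g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- iv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = dg, db = db)
}

## reshape (B*T) x D  ->  (T, dh, H*B) and back (compiled)
.to_heads <- function(X, B, T_, H) heads_split(X, B, T_, H)
.from_heads <- function(Y, B, T_, H) heads_merge(Y, B, T_, H)

## multi-head attention; `padmask` is a (Tk x B) 0/1 key-padding matrix (or
## NULL) and `causal` masks future key positions (decoder self-attention)
.attn_fwd <- function(xq, xkv, w, B, Tq, Tk, H, causal = FALSE,
                      padmask = NULL, drop_fn = NULL) {
  dh <- ncol(w$Wq) %/% H
  Q <- .to_heads(xq %*% w$Wq, B, Tq, H)
  K <- .to_heads(xkv %*% w$Wk, B, Tk, H)
  V <- .to_heads(xkv %*% w$Wv, B, Tk, H)
  s <- bmm(Q, K, FALSE, TRUE) / sqrt(dh)
  P <- softmax_dim2(s, causal, if (is.null(padmask)) matrix(0, 0, 0) else padmask, H)
  ctx <- bmm(P, V)                      # Tq, dh, H*B
  ctx2 <- .from_heads(ctx, B, Tq, H)    # (B*Tq) x D
  y <- ctx2 %*% w$Wo
  dm <- NULL
  if (!is.null(drop_fn)) { dm <- drop_fn(length(y)); if (!is.null(dm)) y <- y * dm }
  list(y = y, Q = Q, K = K, V = V, P = P, ctx2 = ctx2, xq = xq, xkv = xkv,
       dm = dm, dh = dh)
}

.attn_bwd <- function(dy, cache, w, B, Tq, Tk, H) {
  if (!is.null(cache$dm)) dy <- dy * cache$dm
  dWo <- crossprod(cache$ctx2, dy)
  dctx2 <- tcrossprod(dy, w$Wo)
  dctx <- .to_heads(dctx2, B, Tq, H)
  dP <- bmm(dctx, cache$V, FALSE, TRUE)          # Tq, Tk, S
  dV <- bmm(cache$P, dctx, TRUE, FALSE)          # Tk, dh, S
  ds <- softmax_dim2_bwd(cache$P, dP, sqrt(cache$dh))
  dQ <- bmm(ds, cache$K)                         # Tq, dh, S
  dK <- bmm(ds, cache$Q, TRUE, FALSE)            # Tk, dh, S
  dQ2 <- .from_heads(dQ, B, Tq, H)
  dK2 <- .from_heads(dK, B, Tk, H)
  dV2 <- .from_heads(dV, B, Tk, H)
  dxq <- tcrossprod(dQ2, w$Wq)
  dxkv <- tcrossprod(dK2, w$Wk) + tcrossprod(dV2, w$Wv)
  list(dxq = dxq, dxkv = dxkv,
       grads = list(Wq = crossprod(cache$xq, dQ2), Wk = crossprod(cache$xkv, dK2),
                    Wv = crossprod(cache$xkv, dV2), Wo = dWo))
}

.ff_fwd <- function(x, w, drop_fn = NULL) {
  h <- .lin_fwd(x, w$W1, w$b1)
  hr <- pmax(h, 0)
  y <- .lin_fwd(hr, w$W2, w$b2)
  dm <- NULL
  if (!is.null(drop_fn)) { dm <- drop_fn(length(y)); if (!is.null(dm)) y <- y * dm }
  list(y = y, x = x, hr = hr, dm = dm)
}

.ff_bwd <- function(dy, cache, w) {
  if (!is.null(cache$dm)) dy <- dy * cache$dm
  dW2 <- crossprod(cache$hr, dy); db2 <- colSums(dy)
  dhr <- tcrossprod(dy, w$W2)
  dh <- dhr * (cache$hr > 0)
  dW1 <- crossprod(cache$x, dh); db1 <- colSums(dh)
  dx <- tcrossprod(dh, w$W1)
  list(dx = dx, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

## ---- masks -----------------------------------------------------------------

## (Tk x B) 0/1 key-padding matrix, or NULL when nothing is padded
.pad_mask <- function(ids) {
  if (!any(ids == .PAD_ID)) return(NULL)
  (t(ids) == .PAD_ID) * 1
}

## ---- embedding -------------------------------------------------------------

.embed_fwd <- function(params, cfg, ids, drop_fn = NULL) {
  B <- nrow(ids); T_ <- ncol(ids)
  flat <- as.vector(t(ids))                     # row (b-1)*T + t
  x <- params$embed[flat, , drop = FALSE] * sqrt(cfg$d_model)
  x <- x + .pos_encoding(T_, cfg$d_model)[rep(seq_len(T_), B), , drop = FALSE]
  dm <- NULL
  if (!is.null(drop_fn)) { dm <- drop_fn(length(x)); if (!is.null(dm)) x <- x * dm }
  list(x = x, flat = flat, dm = dm)
}

.embed_bwd <- function(dx, cache, cfg, V) {
  if (!is.null(cache$dm)) dx <- dx * cache$dm
  dx <- dx * sqrt(cfg$d_model)
  dE <- matrix(0, V, cfg$d_model)
  ## accumulate rows (rowsum groups duplicate token ids)
  agg <- rowsum(dx, cache$flat)
  dE[as.integer(rownames(agg)), ] <- agg
  dE
}

## ---- encoder / decoder forward & backward ----------------------------------

.encoder_fwd <- function(params, cfg, src_ids, drop_fn = NULL) {
  B <- nrow(src_ids); Ts <- ncol(src_ids); H <- cfg$n_heads
  emb <- .embed_fwd(params, cfg, src_ids, drop_fn)
  x <- emb$x
  mask <- .pad_mask(src_ids)
  layers <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    w <- params$enc[[l]]
    ln1 <- .ln_fwd(x, w$ln1$g, w$ln1$b)
    at <- .attn_fwd(ln1$y, ln1$y, w$attn, B, Ts, Ts, H, FALSE, mask, drop_fn)
    x1 <- x + at$y
    ln2 <- .ln_fwd(x1, w$ln2$g, w$ln2$b)
    ff <- .ff_fwd(ln2$y, w$ff, drop_fn)
    x2 <- x1 + ff$y
    layers[[l]] <- list(ln1 = ln1, at = at, ln2 = ln2, ff = ff)
    x <- x2
  }
  lnf <- .ln_fwd(x, params$enc_ln$g, params$enc_ln$b)
  list(out = lnf$y, emb = emb, layers = layers, lnf = lnf, mask = mask,
       B = B, Ts = Ts)
}

.decoder_fwd <- function(params, cfg, enc_out, src_ids, tgt_ids, drop_fn = NULL) {
  B <- nrow(tgt_ids); Tt <- ncol(tgt_ids); Ts <- ncol(src_ids); H <- cfg$n_heads
  emb <- .embed_fwd(params, cfg, tgt_ids, drop_fn)
  x <- emb$x
  tmask <- .pad_mask(tgt_ids)
  xmask <- .pad_mask(src_ids)
  layers <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    w <- params$dec[[l]]
    ln1 <- .ln_fwd(x, w$ln1$g, w$ln1$b)
    sa <- .attn_fwd(ln1$y, ln1$y, w$self, B, Tt, Tt, H, TRUE, tmask, drop_fn)
    x1 <- x + sa$y
    ln2 <- .ln_fwd(x1, w$ln2$g, w$ln2$b)
    ca <- .attn_fwd(ln2$y, enc_out, w$cross, B, Tt, Ts, H, FALSE, xmask, drop_fn)
    x2 <- x1 + ca$y
    ln3 <- .ln_fwd(x2, w$ln3$g, w$ln3$b)
    ff <- .ff_fwd(ln3$y, w$ff, drop_fn)
    x3 <- x2 + ff$y
    layers[[l]] <- list(ln1 = ln1, sa = sa, ln2 = ln2, ca = ca, ln3 = ln3, ff = ff)
    x <- x3
  }
  lnf <- .ln_fwd(x, params$dec_ln$g, params$dec_ln$b)
  logits <- .lin_fwd(lnf$y, params$Wout, params$bout)
  list(logits = logits, emb = emb, layers = layers, lnf = lnf,
       B = B, Tt = Tt, Ts = Ts)
}

## full backward; returns nested grads mirroring params
.model_bwd <- function(params, cfg, enc_cache, dec_cache, dlogits, src_ids, tgt_ids) {
  H <- cfg$n_heads
  B <- dec_cache$B; Tt <- dec_cache$Tt; Ts <- dec_cache$Ts
  V <- nrow(params$embed)
  g <- list(enc = vector("list", cfg$n_layers),
            dec = vector("list", cfg$n_layers))

  ## output projection
  g$Wout <- crossprod(dec_cache$lnf$y, dlogits)
  g$bout <- colSums(dlogits)
  dx <- tcrossprod(dlogits, params$Wout)
  lb <- .ln_bwd(dx, dec_cache$lnf)
  g$dec_ln <- list(g = lb$dg, b = lb$db)
  dx <- lb$dx
  denc <- matrix(0, nrow(enc_cache$out), ncol(enc_cache$out))

  for (l in rev(seq_len(cfg$n_layers))) {
    w <- params$dec[[l]]; cc <- dec_cache$layers[[l]]
    ## x3 = x2 + ff(ln3(x2))
    fb <- .ff_bwd(dx, cc$ff, w$ff)
    lb <- .ln_bwd(fb$dx, cc$ln3)
    dx2 <- dx + lb$dx
    ## x2 = x1 + cross(ln2(x1), enc_out)
    ab <- .attn_bwd(dx2, cc$ca, w$cross, B, Tt, Ts, H)
    denc <- denc + ab$dxkv
    lb2 <- .ln_bwd(ab$dxq, cc$ln2)
    dx1 <- dx2 + lb2$dx
    ## x1 = x + self(ln1(x))
    sb <- .attn_bwd(dx1, cc$sa, w$self, B, Tt, Tt, H)
    lb1 <- .ln_bwd(sb$dxq + sb$dxkv, cc$ln1)
    dx <- dx1 + lb1$dx
    g$dec[[l]] <- list(ln1 = list(g = lb1$dg, b = lb1$db), self = sb$grads,
                       ln2 = list(g = lb2$dg, b = lb2$db), cross = ab$grads,
                       ln3 = list(g = lb$dg, b = lb$db), ff = fb$grads)
  }
  dE_dec <- .embed_bwd(dx, dec_cache$emb, cfg, V)

  ## encoder backward
  lb <- .ln_bwd(denc, enc_cache$lnf)
  g$enc_ln <- list(g = lb$dg, b = lb$db)
  dx <- lb$dx
  for (l in rev(seq_len(cfg$n_layers))) {
    w <- params$enc[[l]]; cc <- enc_cache$layers[[l]]
    fb <- .ff_bwd(dx, cc$ff, w$ff)
    lb2 <- .ln_bwd(fb$dx, cc$ln2)
    dx1 <- dx + lb2$dx
    ab <- .attn_bwd(dx1, cc$at, w$attn, B, enc_cache$Ts, enc_cache$Ts, H)
    lb1 <- .ln_bwd(ab$dxq + ab$dxkv, cc$ln1)
    dx <- dx1 + lb1$dx
    g$enc[[l]] <- list(ln1 = list(g = lb1$dg, b = lb1$db), attn = ab$grads,
                       ln2 = list(g = lb2$dg, b = lb2$db), ff = fb$grads)
  }
  g$embed <- dE_dec + .embed_bwd(dx, enc_cache$emb, cfg, V)
  g
}

## ---- loss ------------------------------------------------------------------

## softmax cross-entropy over valid (non-pad) target positions
.ce_loss <- function(logits, labels_flat) {
  valid <- labels_flat != .PAD_ID
  n <- sum(valid)
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  z <- rowSums(ex)
  p <- ex / z
  picked <- p[cbind(seq_along(labels_flat), labels_flat)]
  nll <- -log(pmax(picked, 1e-12))
  loss <- sum(nll[valid]) / n
  dlogits <- p
  dlogits[cbind(seq_along(labels_flat), labels_flat)] <-
    dlogits[cbind(seq_along(labels_flat), labels_flat)] - 1
  dlogits[!valid, ] <- 0
  dlogits <- dlogits / n
  list(loss = loss, dlogits = dlogits, n_tokens = n, nll = nll, valid = valid)
}

## ---- parameter-tree utilities ----------------------------------------------

## walk parallel parameter trees; subtrees are matched by name where named
## (gradient trees may order their components differently)
.tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) {
      bi <- if (!is.null(names(a)) && nzchar(names(a)[i])) b[[names(a)[i]]] else b[[i]]
      out[[i]] <- .tree_map2(f, a[[i]], bi)
    }
    out
  } else f(a, b)
}

.tree_map3 <- function(f, a, b, d) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) {
      nm <- if (!is.null(names(a)) && nzchar(names(a)[i])) names(a)[i] else i
      out[[i]] <- .tree_map3(f, a[[i]], b[[nm]], d[[nm]])
    }
    out
  } else f(a, b, d)
}

.tree_zero <- function(a) {
  if (is.list(a)) lapply(a, .tree_zero) else a * 0
}

## Adam with the inverse-sqrt warmup schedule
.noam_lr <- function(step, cfg) {
  cfg$lr_scale * cfg$d_model^(-0.5) *
    min(step^(-0.5), step * cfg$warmup^(-1.5))
}

.adam_step <- function(state, grads, lr, beta1 = 0.9, beta2 = 0.998, eps = 1e-9) {
  state$t <- state$t + 1L
  state$m <- .tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- .tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  state$params <- .tree_map3(function(p, m, v)
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
    state$params, state$m, state$v)
  state
}
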