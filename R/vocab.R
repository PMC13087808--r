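## SELFIES vocabulary.

.SPECIALS <- c("<pad>", "<unk>", "<s>", "</s>")

#' Vocabulary: SELFIES token to index mapping
#'
#' Indices are contiguous from 0; the four specials `<pad>`, `<unk>`, `<s>`,
#' `</s>` always occupy indices 0-3, followed by the observed tokens ordered
#' by descending corpus frequency, ties broken lexicographically.
#'
#' @slot tokens character vector (specials first).
#' @export
setClass("Vocabulary", representation(tokens = "character"))

setValidity("Vocabulary", function(object) {
  if (!identical(object@tokens[1:4], .SPECIALS))
    return("the first four tokens must be the specials <pad>, <unk>, <s>, </s>")
  if (anyDuplicated(object@tokens)) return("tokens must be unique")
  TRUE
})

setMethod("show", "Vocabulary", function(object) {
  cat(sprintf("Vocabulary with %d tokens (4 specials + %d SELFIES tokens)\n",
              length(object@tokens), length(object@tokens) - 4L))
})

#' Build a vocabulary from SELFIES corpora
#'
#' @param ... character vectors of SELFIES strings.
#' @return a [Vocabulary].
#' @export
buildVocabulary <- function(...) {
  corpora <- unlist(list(...), use.names = FALSE)
  stopifnot(length(corpora) >= 1L)
  toks <- unlist(lapply(corpora, tokenizeSelfies), use.names = FALSE)
  tab <- table(toks)
  ord <- order(-as.integer(tab), names(tab))
  new("Vocabulary", tokens = c(.SPECIALS, names(tab)[ord]))
}

#' @describeIn buildVocabulary vocabulary size
#' @param vocab a Vocabulary.
#' @export
vocabSize <- function(vocab) length(vocab@tokens)

#' @describeIn buildVocabulary tokens in index order (index 0 first)
#' @export
vocabTokens <- function(vocab) vocab@tokens

## encode one selfies string to 1-based token ids (unknowns -> <unk>)
.encode_tokens <- function(vocab, selfies) {
  ids <- match(tokenizeSelfies(selfies), vocab@tokens)
  ids[is.na(ids)] <- 2L  # <unk>
  ids
}

.PAD_ID <- 1L; .UNK_ID <- 2L; .BOS_ID <- 3L; .EOS_ID <- 4L

## pad a list of id vectors into a B x T matrix (pad id 1)
.pad_batch <- function(id_list, maxlen = NULL) {
  if (is.null(maxlen)) maxlen <- max(lengths(id_list))
  out <- matrix(.PAD_ID, nrow = length(id_list), ncol = maxlen)
  for (i in seq_along(id_list)) {
    v <- id_list[[i]]
    if (length(v) > maxlen) v <- v[seq_len(maxlen)]
    if (length(v)) out[i, seq_along(v)] <- v
  }
  out
}

## decode 1-based ids back to a selfies string, stopping at </s>, dropping
## specials
.decode_ids <- function(vocab, ids) {
  stop_at <- which(ids == .EOS_ID)
  if (length(stop_at)) ids <- ids[seq_len(stop_at[1] - 1L)]
  ids <- ids[ids > 4L]
  pasteSelfies(vocab@tokens[ids])
}
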