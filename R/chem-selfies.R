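## SELFIES codec.
##
## The model operates on SELFIES token strings: a molecular string grammar in
## which *every* token sequence decodes to a valid molecule. Encoding walks a
## kekulized SMILES of the molecule and translates atoms, branches and ring
## closures into tokens; decoding is a valence-constrained derivation in which
## bonds that would exceed an atom's capacity are truncated and unusable
## branch/ring specifications are skipped. The index alphabet and the
## [Branch]/[Ring] length conventions follow the published SELFIES grammar.

.SELFIES_INDEX_ALPHABET <- c(
  "[C]", "[Ring1]", "[Ring2]", "[Branch1]", "[=Branch1]", "[#Branch1]",
  "[Branch2]", "[=Branch2]", "[#Branch2]", "[O]", "[N]", "[=N]", "[=C]",
  "[#C]", "[S]", "[P]"
)

## decode-time bond capacities (upper bounds; implicit H are assigned after
## decoding from the standard valence lists)
.SELFIES_CAPACITY <- c(B = 3L, C = 4L, N = 3L, O = 2L, P = 5L, S = 6L,
                       F = 1L, Cl = 1L, Br = 1L, I = 1L, "*" = 1L)

.selfies_capacity <- function(elem, charge, hexp) {
  base <- unname(.SELFIES_CAPACITY[elem])
  if (is.na(base)) base <- 4L
  if (charge != 0L && elem %in% c("N", "P", "O", "S"))
    base <- max(base + charge, 0L)
  if (charge != 0L && elem == "C") base <- max(4L - abs(charge), 0L)
  max(base - (if (is.na(hexp)) 0L else hexp), 0L)
}

#' Split a SELFIES string into tokens
#'
#' @param selfies a single SELFIES string, e.g. `"[C][C][O]"`.
#' @return character vector of `[...]` tokens; `pasteSelfies()` is its exact
#'   inverse.
#' @export
tokenizeSelfies <- function(selfies) {
  stopifnot(is.character(selfies), length(selfies) == 1L)
  if (!nzchar(selfies)) return(character(0))
  toks <- regmatches(selfies, gregexpr("\\[[^][]*\\]", selfies))[[1]]
  if (nchar(paste(toks, collapse = "")) != nchar(selfies))
    stop(sprintf("malformed SELFIES string: '%s'", selfies))
  toks
}

#' @rdname tokenizeSelfies
#' @param tokens character vector of SELFIES tokens.
#' @export
pasteSelfies <- function(tokens) paste(tokens, collapse = "")

## encode an index value as index-alphabet tokens (width N digits, base 16)
.index_tokens <- function(v, width) {
  digits <- integer(width)
  for (k in width:1) { digits[k] <- v %% 16L; v <- v %/% 16L }
  .SELFIES_INDEX_ALPHABET[digits + 1L]
}

.index_width <- function(v) if (v < 16L) 1L else if (v < 256L) 2L else 3L

## value of an index token (official convention: any token has an index value;
## unknown tokens count 0)
.index_value <- function(tok) {
  i <- match(tok, .SELFIES_INDEX_ALPHABET)
  if (is.na(i)) 0L else i - 1L
}

## ---- encoder ---------------------------------------------------------------

.selfies_atom_token <- function(bracket_info, bond_prefix) {
  el <- bracket_info$elem
  h <- bracket_info$hexp
  chg <- bracket_info$charge
  spec <- el
  if (!is.na(h) && h > 0L) spec <- paste0(spec, "H", h)
  if (chg > 0L) spec <- paste0(spec, "+", chg)
  if (chg < 0L) spec <- paste0(spec, "-", -chg)
  paste0("[", bond_prefix, spec, "]")
}

## translate one kekulized SMILES token stream into SELFIES tokens
.smiles_tokens_to_selfies <- function(toks, smiles) {
  pos <- 0L                 # atoms emitted so far
  ring_open <- list()       # digit -> list(pos, sym)
  i <- 0L
  n <- length(toks)

  emit_seq <- function() {
    out <- character(0)
    pending <- ""
    repeat {
      if (i >= n) break
      tk <- toks[[i + 1L]]
      if (tk$type == ")") break
      i <<- i + 1L
      if (tk$type %in% c("atom", "bracket")) {
        info <- if (tk$type == "bracket") .parse_bracket_atom(tk$text, smiles)
                else list(elem = if (tk$text == "*") "*" else tk$text,
                          hexp = NA_integer_, charge = 0L)
        pref <- switch(pending, "=" = "=", "#" = "#", "")
        out <- c(out, .selfies_atom_token(info, pref))
        pos <<- pos + 1L
        pending <- ""
      } else if (tk$type == "bond") {
        pending <- tk$text
      } else if (tk$type == "ring") {
        d <- tk$text
        if (is.null(ring_open[[d]])) {
          ring_open[[d]] <<- list(pos = pos, sym = pending)
        } else {
          op <- ring_open[[d]]
          sym <- if (pending != "") pending else op$sym
          pref <- switch(sym, "=" = "=", "#" = "#", "")
          q <- pos - op$pos - 1L
          w <- .index_width(q)
          out <- c(out, paste0("[", pref, "Ring", w, "]"), .index_tokens(q, w))
          ring_open[[d]] <<- NULL
        }
        pending <- ""
      } else if (tk$type == "(") {
        inner <- emit_seq()
        if (i >= n || toks[[i + 1L]]$type != ")")
          stop("unbalanced branch while encoding SELFIES")
        i <<- i + 1L  # consume ')'
        if (length(inner)) {
          pref <- sub("^\\[([=#]?).*$", "\\1", inner[1])
          q <- length(inner) - 1L
          w <- .index_width(q)
          out <- c(out, paste0("[", pref, "Branch", w, "]"),
                   .index_tokens(q, w), inner)
        }
      } else {
        stop(sprintf("unexpected token '%s' while encoding SELFIES", tk$text))
      }
    }
    out
  }
  out <- emit_seq()
  if (i < n) stop("unbalanced parentheses while encoding SELFIES")
  out
}

#' SMILES to SELFIES
#'
#' Kekulizes the molecule and translates it into a SELFIES token string. The
#' traversal follows the atom order of the input SMILES, so different
#' randomized SMILES of one molecule yield different SELFIES encodings.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of SELFIES strings.
#' @export
smilesToSelfies <- function(smiles) {
  vapply(smiles, function(s) {
    mol <- parse_smiles(s)
    molk <- mol
    molk$arom[] <- FALSE
    molk$barom[] <- FALSE
    smi_k <- .emit_smiles(molk, seq_along(molk$elem), start = 1L)
    pasteSelfies(.smiles_tokens_to_selfies(.tokenize_smiles(smi_k), s))
  }, character(1), USE.NAMES = FALSE)
}

## ---- decoder ---------------------------------------------------------------

.ATOM_TOKEN_RE <- "^\\[([=#]?)(\\*|[A-Z][a-z]?)(?:H([0-9]))?(?:([+-])([0-9]))?\\]$"

## Decode a SELFIES token vector into a molecular graph. Never fails: tokens
## that cannot be realized under the valence constraints are truncated or
## skipped. Returns NULL when no atom could be derived.
.selfies_derive <- function(tokens) {
  elem <- character(); charge <- integer(); hexp <- integer()
  rem <- integer()          # remaining bond capacity per atom
  bi <- integer(); bj <- integer(); bord <- integer()

  add_bond <- function(a, b, o) {
    bi <<- c(bi, a); bj <<- c(bj, b); bord <<- c(bord, o)
  }

  ## derive a token subsequence; `prev` is the attachment atom (NA for root).
  ## Returns nothing; mutates the shared graph.
  derive <- function(toks, prev) {
    k <- 0L
    nt <- length(toks)
    take <- function(m) {
      got <- toks[seq_len(min(m, nt - k)) + k]
      k <<- k + length(got)
      got
    }
    while (k < nt) {
      k <- k + 1L
      tok <- toks[[k]]
      am <- regmatches(tok, regexec(.ATOM_TOKEN_RE, tok, perl = TRUE))[[1]]
      if (length(am)) {
        want <- switch(am[2], "=" = 2L, "#" = 3L, 1L)
        el <- am[3]
        h <- if (am[4] != "") as.integer(am[4]) else NA_integer_
        chg <- if (am[5] != "") as.integer(paste0(am[5], am[6])) else 0L
        cap <- .selfies_capacity(el, chg, h)
        if (!is.na(prev)) {
          b <- min(want, rem[prev], cap)
          if (b < 1L) return(invisible())   # chain cannot continue
          elem <<- c(elem, el); charge <<- c(charge, chg); hexp <<- c(hexp, h)
          rem <<- c(rem, cap - b)
          add_bond(prev, length(elem), b)
          rem[prev] <<- rem[prev] - b
        } else {
          elem <<- c(elem, el); charge <<- c(charge, chg); hexp <<- c(hexp, h)
          rem <<- c(rem, cap)
        }
        prev <- length(elem)
      } else if (grepl("^\\[[=#]?Branch[123]\\]$", tok)) {
        w <- as.integer(sub("^.*Branch([123])\\]$", "\\1", tok))
        idx <- take(w)
        q <- 0L
        for (t in idx) q <- q * 16L + .index_value(t)
        content <- take(q + 1L)
        if (!is.na(prev) && rem[prev] >= 2L && length(content))
          derive(content, prev)
      } else if (grepl("^\\[[=#]?Ring[123]\\]$", tok)) {
        w <- as.integer(sub("^.*Ring([123])\\]$", "\\1", tok))
        want <- if (startsWith(tok, "[=")) 2L else if (startsWith(tok, "[#")) 3L else 1L
        idx <- take(w)
        q <- 0L
        for (t in idx) q <- q * 16L + .index_value(t)
        if (is.na(prev)) next
        partner <- prev - (q + 1L)
        if (partner < 1L) partner <- 1L
        if (partner == prev) next
        dup <- any(bi == min(partner, prev) & bj == max(partner, prev)) ||
               any(bi == max(partner, prev) & bj == min(partner, prev))
        if (dup) next
        b <- min(want, rem[prev], rem[partner])
        if (b >= 1L) {
          add_bond(partner, prev, b)
          rem[prev] <<- rem[prev] - b
          rem[partner] <<- rem[partner] - b
        }
      }
      ## anything else ([nop], specials, unknown): skip
    }
    invisible()
  }
  derive(tokens, NA_integer_)
  if (!length(elem)) return(NULL)
  list(elem = elem, arom = rep(FALSE, length(elem)), charge = charge,
       hexp = hexp, map = rep(0L, length(elem)),
       nH = rep(NA_integer_, length(elem)),
       bonds = cbind(i = bi, j = bj, order = bord),
       barom = rep(FALSE, length(bi)))
}

## fast path: distinct randomized SELFIES straight from a parsed mol (one
## parse, many emissions); dedupes on the kekulized SMILES emission
.random_selfies_distinct <- function(mol, k, seed) {
  molk <- mol
  molk$arom[] <- FALSE
  molk$barom[] <- FALSE
  n <- length(mol$elem)
  rng <- local_rng(seed)
  smis <- character(0)
  tries <- 0L
  max_tries <- max(20L, 10L * k)
  while (length(smis) < k && tries < max_tries) {
    tries <- tries + 1L
    ranks <- rng$sample_int(n)
    s <- .emit_smiles(molk, ranks, start = which.min(ranks))
    if (!(s %in% smis)) smis <- c(smis, s)
  }
  vapply(smis, function(s)
    pasteSelfies(.smiles_tokens_to_selfies(.tokenize_smiles(s), s)),
    character(1), USE.NAMES = FALSE)
}

## direct SELFIES -> canonical SMILES (skips the intermediate SMILES
## emission/re-parse); agreement with canonicalizeSmiles(selfiesToSmiles(s))
## is covered in tests. Cached per token string.
.selfies_canon_cache <- new.env(parent = emptyenv())

selfies_canonical_one <- function(s) {
  if (!nzchar(s)) return("")
  hit <- get0(s, envir = .selfies_canon_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  mol <- .selfies_derive(tokenizeSelfies(s))
  out <- if (is.null(mol)) "" else {
    mol <- .assign_hydrogens(mol, s)
    mol <- .perceive_aromaticity(mol)
    .canonical_string(mol)
  }
  assign(s, out, envir = .selfies_canon_cache)
  out
}

#' SELFIES to SMILES
#'
#' Derives the molecular graph under valence constraints and writes it as a
#' (kekulized) SMILES string. By construction the derivation cannot produce an
#' invalid molecule: over-valent bonds are truncated and unrealizable branch
#' or ring specifications are skipped, so `selfiesToSmiles()` succeeds on any
#' token sequence drawn from the SELFIES vocabulary. A sequence containing no
#' atom token decodes to the empty string.
#'
#' @param selfies character vector of SELFIES strings.
#' @return character vector of SMILES (possibly `""` for atom-free input).
#' @export
selfiesToSmiles <- function(selfies) {
  vapply(selfies, function(s) {
    mol <- .selfies_derive(tokenizeSelfies(s))
    if (is.null(mol)) return("")
    mol <- .assign_hydrogens(mol, s)
    .emit_smiles(mol, seq_along(mol$elem), start = 1L)
  }, character(1), USE.NAMES = FALSE)
}
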