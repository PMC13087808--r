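## SMILES output: a deterministic DFS emitter driven by an atom ranking.
## Canonical SMILES = lexicographically smallest emission over the canonical
## labelings produced by invariant refinement with individualization;
## randomized SMILES = the same emitter driven by a seeded random ranking.

## bond code used by refinement and fingerprints: aromatic bonds are their own
## class so that the ranking is independent of the kekule assignment
.bond_code <- function(mol) ifelse(mol$barom, 4L, mol$bonds[, "order"])

## iterative partition refinement; `ranks` are dense integers starting at 1.
## Refinement only ever splits classes (each key is prefixed by the old rank),
## so the loop terminates when the class count stops growing.
.refine_ranks <- function(mol, ranks, inc = NULL) {
  n <- length(mol$elem)
  if (!nrow(mol$bonds)) return(ranks)
  bc <- .bond_code(mol)
  bi <- mol$bonds[, "i"]; bj <- mol$bonds[, "j"]
  at <- factor(c(bi, bj), levels = seq_len(n))
  nbr <- c(bj, bi)
  bcc <- c(bc, bc)
  repeat {
    code <- bcc * (n + 1L) + ranks[nbr]
    o <- order(at, code)
    nbkey <- vapply(split(code[o], at[o]), paste, character(1), collapse = ",")
    ## class numbering must itself be isomorphism-invariant (sorted keys):
    ## the individualization search selects cells by rank value
    keys <- paste0(sprintf("%05d", ranks), "|", nbkey)
    new_ranks <- match(keys, sort(unique(keys)))
    if (length(unique(new_ranks)) == length(unique(ranks))) return(new_ranks)
    ranks <- new_ranks
  }
}

.initial_ranks <- function(mol) {
  deg <- .mol_degree(mol)
  keys <- paste(mol$elem, deg, mol$charge, mol$nH, mol$arom, mol$map, sep = "/")
  match(keys, sort(unique(keys)))
}

## ---- emitter ---------------------------------------------------------------

## Writes a SMILES string visiting atoms by ascending `ranks` (children of each
## atom in ascending rank; start = lowest rank among `starts`). Ring-closure
## digits allocated in emission order with reuse.
.emit_smiles <- function(mol, ranks, start = NULL) {
  n <- length(mol$elem)
  nb_tot <- nrow(mol$bonds)
  af <- factor(c(mol$bonds[, "i"], mol$bonds[, "j"]), levels = seq_len(n))
  adj_other <- split(c(mol$bonds[, "j"], mol$bonds[, "i"]), af)
  adj_bond <- split(rep.int(seq_len(nb_tot), 2L), af)
  inc <- adj_bond
  if (is.null(start)) start <- which.min(ranks)
  visited <- logical(n)
  bond_used <- logical(nrow(mol$bonds))
  visit_order <- integer(n); vcount <- 0L
  children <- vector("list", n)   # list of (atom, bond)
  closures <- vector("list", n)   # list of bond indices (ring closures at this atom)

  ## pass 1: DFS to fix tree structure and ring bonds
  dfs <- function(a) {
    vcount <<- vcount + 1L
    visited[a] <<- TRUE
    visit_order[a] <<- vcount
    nbr_bonds <- adj_bond[[a]]
    if (length(nbr_bonds)) {
      others <- adj_other[[a]]
      ord <- order(ranks[others], others)
      nbr_bonds <- nbr_bonds[ord]; others <- others[ord]
      for (k in seq_along(nbr_bonds)) {
        b <- nbr_bonds[k]; o <- others[k]
        if (bond_used[b]) next
        if (visited[o]) {
          bond_used[b] <<- TRUE
          closures[[a]] <<- c(closures[[a]], b)
          closures[[o]] <<- c(closures[[o]], b)
        } else {
          bond_used[b] <<- TRUE
          children[[a]] <<- c(children[[a]], list(c(o, b)))
          dfs(o)
        }
      }
    }
  }
  dfs(start)
  if (vcount < n) stop("disconnected molecule passed to emitter")

  ## assign ring-closure digits in emission order with reuse
  digit_of <- rep(NA_integer_, nrow(mol$bonds))
  free_digits <- 1:99
  open_count <- integer(0)
  emit_order <- order(visit_order)
  for (a in emit_order) {
    for (b in closures[[a]]) {
      if (is.na(digit_of[b])) {
        digit_of[b] <- free_digits[1]
        free_digits <- free_digits[-1]
      } else {
        free_digits <- sort(c(free_digits, digit_of[b]))
      }
    }
  }
  atom_token <- function(a) {
    el <- mol$elem[a]
    sym <- if (mol$arom[a]) tolower(el) else el
    bare_ok <- el %in% .ORGANIC_SUBSET && mol$charge[a] == 0L && mol$map[a] == 0L
    if (bare_ok) {
      ## would a bare atom imply the stored H count?
      bs <- 0L
      for (b in inc[[a]]) bs <- bs + if (mol$barom[b]) 1L else mol$bonds[b, "order"]
      if (mol$arom[a]) bs <- bs + 1L  # one kekule double somewhere
      vals <- .valence_options(el, 0L)
      v <- vals[vals >= bs][1]
      implied <- if (is.na(v)) -1L else v - bs
      if (mol$arom[a]) {
        ## aromatic atoms: trust kekule-derived nH; bare iff it matches the
        ## convention (C always bare; heteroatoms bare iff nH == 0)
        if (el == "C" || mol$nH[a] == 0L) return(sym)
      } else if (implied == mol$nH[a]) {
        return(sym)
      }
    }
    h <- if (mol$nH[a] > 0L) paste0("H", if (mol$nH[a] > 1L) mol$nH[a] else "") else ""
    chg <- if (mol$charge[a] > 0L) paste0("+", if (mol$charge[a] > 1L) mol$charge[a] else "")
           else if (mol$charge[a] < 0L) paste0("-", if (mol$charge[a] < -1L) -mol$charge[a] else "")
           else ""
    mp <- if (mol$map[a] > 0L) paste0(":", mol$map[a]) else ""
    paste0("[", sym, h, chg, mp, "]")
  }

  bond_sym <- function(b) {
    if (mol$barom[b]) return("")
    o <- mol$bonds[b, "order"]
    if (o == 2L) return("=")
    if (o == 3L) return("#")
    i <- mol$bonds[b, "i"]; j <- mol$bonds[b, "j"]
    if (mol$arom[i] && mol$arom[j]) return("-")  # single bond between aromatics
    ""
  }

  seen_digit <- rep(FALSE, nrow(mol$bonds))
  build <- function(a) {
    out <- atom_token(a)
    for (b in closures[[a]]) {
      d <- digit_of[b]
      sym <- if (!seen_digit[b]) bond_sym(b) else ""
      seen_digit[b] <<- TRUE
      out <- paste0(out, sym, if (d > 9) paste0("%", d) else d)
    }
    ch <- children[[a]]
    if (length(ch)) {
      for (k in seq_along(ch)) {
        o <- ch[[k]][1]; b <- ch[[k]][2]
        piece <- paste0(bond_sym(b), build(o))
        out <- paste0(out, if (k < length(ch)) paste0("(", piece, ")") else piece)
      }
    }
    out
  }
  build(start)
}

## ---- canonical labeling ----------------------------------------------------

## refinement + individualization; returns the minimal emission string
.canonical_string <- function(mol, max_labelings = 2000L) {
  n <- length(mol$elem)
  if (n == 1L) return(.emit_smiles(mol, 1L))
  best <- NULL
  count <- 0L
  seen <- new.env(parent = emptyenv())
  search <- function(ranks) {
    if (count >= max_labelings) return()
    ranks <- .refine_ranks(mol, ranks)
    if (length(unique(ranks)) == n) {
      ## the emitted string is a function of the relabeled graph only, so
      ## labelings with identical certificates (automorphic choices) are
      ## emitted once
      ord <- order(ranks)
      atom_part <- paste(mol$elem[ord], mol$charge[ord], mol$nH[ord],
                         mol$arom[ord], mol$map[ord], collapse = ";")
      ri <- ranks[mol$bonds[, "i"]]; rj <- ranks[mol$bonds[, "j"]]
      bkey <- sort((pmin(ri, rj) * (n + 1) + pmax(ri, rj)) * 8 +
                   ifelse(mol$barom, 4, mol$bonds[, "order"]))
      sig <- paste(atom_part, paste(bkey, collapse = ","))
      if (isTRUE(get0(sig, envir = seen, inherits = FALSE))) return()
      assign(sig, TRUE, envir = seen)
      count <<- count + 1L
      s <- .emit_smiles(mol, ranks)
      if (is.null(best) || s < best) best <<- s
      return()
    }
    ## first (lowest-rank) non-singleton cell
    tab <- table(ranks)
    cell_rank <- as.integer(names(tab)[tab > 1][1])
    cell <- which(ranks == cell_rank)
    for (a in cell) {
      r2 <- as.numeric(ranks)
      r2[a] <- cell_rank - 0.5  # individualize: a gets its own class below the cell
      search(match(r2, sort(unique(r2))))
      if (count >= max_labelings) return()
    }
  }
  search(.initial_ranks(mol))
  best
}

## small memo cache: raw SMILES string -> canonical form
.canon_cache <- new.env(parent = emptyenv())

canonical_smiles_one <- function(s) {
  hit <- get0(s, envir = .canon_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  out <- .canonical_string(parse_smiles(s))
  assign(s, out, envir = .canon_cache)
  assign(out, out, envir = .canon_cache)  # canonical form is a fixed point
  out
}

#' Canonical stereochemistry-free SMILES
#'
#' Parses each SMILES, strips stereochemical annotations (tetrahedral and
#' double-bond marks), keeps the largest fragment of multi-fragment inputs,
#' re-perceives aromaticity, and emits a canonical SMILES string. The output
#' is a fixed point: `canonicalizeSmiles(canonicalizeSmiles(x))` equals
#' `canonicalizeSmiles(x)`, and any two encodings of the same molecule map to
#' the same string.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, same length as `smiles`.
#' @examples
#' canonicalizeSmiles(c("OCC", "C[C@@H](N)O"))
#' @export
canonicalizeSmiles <- function(smiles) {
  stopifnot(is.character(smiles))
  vapply(smiles, canonical_smiles_one, character(1), USE.NAMES = FALSE)
}

#' Randomized SMILES enumeration
#'
#' Writes up to `k` distinct non-canonical SMILES encodings of one molecule by
#' emitting the molecular graph in seeded random atom orders. Every returned
#' string canonicalizes back to the canonical form of `smiles`. If the
#' molecule admits fewer than `k` distinct encodings (small or highly
#' symmetric structures), all distinct encodings found are returned and the
#' shortfall is reported via the `"shortfall"` attribute and a warning.
#'
#' @param smiles a single SMILES string.
#' @param k number of encodings requested.
#' @param seed integer seed; the same seed reproduces the same sequence.
#' @return character vector of length at most `k` with attribute
#'   `"shortfall"` (0 when `k` strings were found).
#' @export
randomSmiles <- function(smiles, k, seed = 1L) {
  stopifnot(length(smiles) == 1L, k >= 1L)
  mol <- parse_smiles(smiles)
  n <- length(mol$elem)
  out <- character(0)
  rng <- local_rng(seed)
  max_tries <- max(20L, 10L * k)
  tries <- 0L
  while (length(out) < k && tries < max_tries) {
    tries <- tries + 1L
    ranks <- rng$sample_int(n)
    s <- .emit_smiles(mol, ranks, start = which.min(ranks))
    if (!(s %in% out)) out <- c(out, s)
  }
  shortfall <- k - length(out)
  if (shortfall > 0L)
    warning(sprintf("molecule '%s' yielded only %d of %d requested distinct SMILES",
                    smiles, length(out), k))
  attr(out, "shortfall") <- shortfall
  out
}
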