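## Molecular graph layer: a light, self-contained representation parsed from
## SMILES. Atoms carry element, aromatic flag, formal charge, explicit-H count
## (bracket atoms), atom-map number (attachment points) and a derived total
## hydrogen count. Bonds carry a kekule order (1/2/3) plus an aromatic flag;
## aromaticity is re-perceived after parsing so that different input forms of
## the same molecule converge to one internal graph.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_OK    <- c("C", "N", "O", "S", "P", "B")
.VALENCES <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = c(1L, 3L, 5L, 7L),
  "*" = 1L,
  ## counter-ion elements accepted so that salt forms parse before the
  ## largest-fragment rule strips them
  Na = 1L, K = 1L, Li = 1L, Ca = 2L, Mg = 2L, Zn = 2L
)

parse_error <- function(smiles, msg) {
  stop(structure(
    class = c("pairtune_parse_error", "error", "condition"),
    list(message = sprintf("cannot parse SMILES '%s': %s", smiles, msg),
         call = NULL, smiles = smiles)
  ))
}

## valence targets used for kekulization and implicit-H assignment
.valence_options <- function(elem, charge) {
  base <- .VALENCES[[elem]]
  if (is.null(base)) return(NULL)
  if (charge == 0L) return(base)
  if (elem %in% c("N", "P", "O", "S")) return(pmax(base[1] + charge, 0L))
  if (elem == "C") return(max(4L - abs(charge), 0L))
  if (elem == "B") return(max(3L + charge, 0L))
  base
}

.mol_degree <- function(mol) {
  d <- integer(length(mol$elem))
  if (nrow(mol$bonds)) {
    t1 <- tabulate(mol$bonds[, "i"], nbins = length(d))
    t2 <- tabulate(mol$bonds[, "j"], nbins = length(d))
    d <- t1 + t2
  }
  d
}

## bond indices incident to each atom
.mol_incidence <- function(mol) {
  n <- length(mol$elem)
  inc <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (b in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[b, "i"]; j <- mol$bonds[b, "j"]
      inc[[i]] <- c(inc[[i]], b)
      inc[[j]] <- c(inc[[j]], b)
    }
  }
  inc
}

.other_end <- function(mol, b, a) {
  i <- mol$bonds[b, "i"]; j <- mol$bonds[b, "j"]
  if (i == a) j else i
}

## ---- tokenizer -------------------------------------------------------------

.tokenize_smiles <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) parse_error(s, "unterminated bracket atom")
      toks[[length(toks) + 1L]] <- list(type = "bracket",
                                        text = paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      toks[[length(toks) + 1L]] <- list(type = "atom", text = paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else if (ch %in% c(.ORGANIC_SUBSET, "b", "c", "n", "o", "p", "s", "*")) {
      toks[[length(toks) + 1L]] <- list(type = "atom", text = ch)
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      toks[[length(toks) + 1L]] <- list(type = "bond", text = ch)
      i <- i + 1L
    } else if (ch == "(" || ch == ")") {
      toks[[length(toks) + 1L]] <- list(type = ch, text = ch)
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      toks[[length(toks) + 1L]] <- list(type = "ring", text = ch)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L])))
        parse_error(s, "malformed %nn ring closure")
      toks[[length(toks) + 1L]] <- list(type = "ring",
                                        text = paste0(chars[i + 1L], chars[i + 2L]))
      i <- i + 3L
    } else if (ch == ".") {
      toks[[length(toks) + 1L]] <- list(type = "dot", text = ".")
      i <- i + 1L
    } else {
      parse_error(s, sprintf("unexpected character '%s'", ch))
    }
  }
  toks
}

.parse_bracket_atom <- function(txt, smiles) {
  m <- regmatches(txt, regexec(
    "^\\[([0-9]+)?([A-Za-z][a-z]?|\\*)(@{1,2}|@TH[12])?(H([0-9]+)?)?(\\+{1,3}|-{1,3}|\\+[0-9]+|-[0-9]+)?(:([0-9]+))?\\]$",
    txt))[[1]]
  if (!length(m)) parse_error(smiles, sprintf("malformed bracket atom '%s'", txt))
  sym <- m[3]
  arom <- sym %in% c("b", "c", "n", "o", "p", "s")
  elem <- if (arom) toupper(sym) else sym
  h <- if (m[5] != "") { if (m[6] != "") as.integer(m[6]) else 1L } else 0L
  chg <- 0L
  if (m[7] != "") {
    cs <- m[7]
    if (grepl("^[+-][0-9]+$", cs)) {
      chg <- as.integer(cs)
    } else {
      chg <- nchar(cs) * if (substr(cs, 1, 1) == "+") 1L else -1L
    }
  }
  map <- if (m[9] != "") as.integer(m[9]) else 0L
  list(elem = elem, arom = arom, hexp = h, charge = chg, map = map)
}

## ---- parser ----------------------------------------------------------------

## returns a raw mol graph (pre-kekulization); internal
.parse_smiles_graph <- function(s) {
  toks <- .tokenize_smiles(s)
  elem <- character(); arom <- logical(); charge <- integer()
  hexp <- integer(); map <- integer(); comp <- integer()
  bi <- integer(); bj <- integer(); bord <- integer(); barom_exp <- character()
  prev <- NA_integer_
  stack <- integer()
  pending_bond <- ""
  ring_open <- list()  # digit -> list(atom, bond)
  comp_id <- 1L

  add_bond <- function(a, b, sym) {
    bi <<- c(bi, a); bj <<- c(bj, b)
    bord <<- c(bord, switch(sym, "=" = 2L, "#" = 3L, 1L))
    barom_exp <<- c(barom_exp, sym)
  }

  for (tk in toks) {
    if (tk$type %in% c("atom", "bracket")) {
      if (tk$type == "atom") {
        sym <- tk$text
        if (sym == "*") {
          at <- list(elem = "*", arom = FALSE, hexp = NA_integer_, charge = 0L, map = 0L)
        } else {
          ar <- sym %in% c("b", "c", "n", "o", "p", "s")
          at <- list(elem = if (ar) toupper(sym) else sym, arom = ar,
                     hexp = NA_integer_, charge = 0L, map = 0L)
        }
      } else {
        at <- .parse_bracket_atom(tk$text, s)
      }
      if (!(at$elem %in% names(.VALENCES)))
        parse_error(s, sprintf("unsupported element '%s'", at$elem))
      elem <- c(elem, at$elem); arom <- c(arom, at$arom)
      charge <- c(charge, at$charge); hexp <- c(hexp, at$hexp)
      map <- c(map, at$map); comp <- c(comp, comp_id)
      idx <- length(elem)
      if (!is.na(prev)) add_bond(prev, idx, pending_bond)
      pending_bond <- ""
      prev <- idx
    } else if (tk$type == "bond") {
      pending_bond <- tk$text
    } else if (tk$type == "(") {
      if (is.na(prev)) parse_error(s, "branch with no preceding atom")
      stack <- c(stack, prev)
    } else if (tk$type == ")") {
      if (!length(stack)) parse_error(s, "unbalanced parentheses")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tk$type == "ring") {
      if (is.na(prev)) parse_error(s, "ring closure with no preceding atom")
      d <- tk$text
      if (is.null(ring_open[[d]])) {
        ring_open[[d]] <- list(atom = prev, sym = pending_bond)
      } else {
        op <- ring_open[[d]]
        sym <- if (pending_bond != "") pending_bond else op$sym
        if (op$sym != "" && pending_bond != "" && op$sym != pending_bond)
          parse_error(s, sprintf("conflicting ring bond symbols for closure %s", d))
        if (op$atom == prev) parse_error(s, "ring closure to self")
        add_bond(op$atom, prev, sym)
        ring_open[[d]] <- NULL
      }
      pending_bond <- ""
    } else if (tk$type == "dot") {
      prev <- NA_integer_
      pending_bond <- ""
      comp_id <- comp_id + 1L
    }
  }
  if (length(stack)) parse_error(s, "unbalanced parentheses")
  open_left <- names(ring_open)[!vapply(ring_open, is.null, logical(1))]
  if (length(open_left))
    parse_error(s, sprintf("unclosed ring bond(s): %s", paste(open_left, collapse = ",")))
  if (!length(elem)) parse_error(s, "no atoms")

  ## keep largest component (salt stripping); ties broken by first occurrence
  if (comp_id > 1L) {
    sizes <- tabulate(comp, nbins = comp_id)
    keep_comp <- which.max(sizes)
    keep <- which(comp == keep_comp)
    remap <- match(seq_along(elem), keep)
    sel <- bi %in% keep & bj %in% keep
    bi <- remap[bi[sel]]; bj <- remap[bj[sel]]
    bord <- bord[sel]; barom_exp <- barom_exp[sel]
    elem <- elem[keep]; arom <- arom[keep]; charge <- charge[keep]
    hexp <- hexp[keep]; map <- map[keep]
    message(sprintf("multi-fragment SMILES '%s': kept largest fragment (%d atoms)",
                    s, length(keep)))
  }

  if (anyDuplicated(cbind(pmin(bi, bj), pmax(bi, bj))))
    parse_error(s, "duplicate bond")

  ## aromatic bond flag: explicit ':' or implicit default bond between two
  ## aromatic atoms
  barom <- barom_exp == ":" | (barom_exp == "" & arom[bi] & arom[bj])
  bord[barom_exp == ":"] <- 1L

  mol <- list(elem = elem, arom = arom, charge = charge, hexp = hexp,
              map = map, nH = rep(NA_integer_, length(elem)),
              bonds = cbind(i = bi, j = bj, order = bord), barom = barom)
  mol
}

## ---- rings -----------------------------------------------------------------

.mol_igraph <- function(mol) {
  g <- igraph::graph_from_edgelist(mol$bonds[, c("i", "j"), drop = FALSE],
                                   directed = FALSE)
  n <- length(mol$elem)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  g
}

## logical vector over bonds: TRUE if the bond lies in a cycle (non-bridge)
.ring_bonds <- function(mol) {
  nb <- nrow(mol$bonds)
  if (!nb) return(logical(0))
  g <- .mol_igraph(mol)
  res <- rep(TRUE, nb)
  res[as.integer(igraph::bridges(g))] <- FALSE
  res
}

## enumerate small rings (sizes in `sizes`) as atom-index vectors; found as the
## shortest cycle through each ring bond, deduplicated by atom set
.small_rings <- function(mol, sizes = c(5L, 6L)) {
  nb <- nrow(mol$bonds)
  if (!nb) return(list())
  rb <- which(.ring_bonds(mol))
  if (!length(rb)) return(list())
  g <- .mol_igraph(mol)
  rings <- list(); keys <- character()
  for (b in rb) {
    u <- mol$bonds[b, "i"]; v <- mol$bonds[b, "j"]
    g2 <- igraph::delete_edges(g, b)
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = u, to = v, output = "vpath")$vpath[[1]])
    ring <- as.integer(sp)
    if (length(ring) %in% sizes) {
      key <- paste(sort(ring), collapse = ",")
      if (!(key %in% keys)) {
        keys <- c(keys, key)
        rings[[length(rings) + 1L]] <- ring
      }
    }
  }
  rings
}

## ---- kekulization ----------------------------------------------------------

## backtracking perfect matching over the `need` atoms using candidate bonds
.match_doubles <- function(need, cand_bonds, mol) {
  need_set <- which(need)
  if (!length(need_set)) return(integer(0))
  partners <- lapply(seq_along(mol$elem), function(a) integer(0))
  for (b in cand_bonds) {
    i <- mol$bonds[b, "i"]; j <- mol$bonds[b, "j"]
    if (need[i] && need[j]) {
      partners[[i]] <- c(partners[[i]], b)
      partners[[j]] <- c(partners[[j]], b)
    }
  }
  matched <- rep(FALSE, length(mol$elem))
  chosen <- integer(0)
  rec <- function() {
    rem <- need_set[!matched[need_set]]
    if (!length(rem)) return(TRUE)
    ## pick the remaining atom with fewest open partners
    nopts <- vapply(rem, function(a) {
      sum(vapply(partners[[a]], function(b) !matched[.other_end(mol, b, a)], logical(1)))
    }, integer(1))
    a <- rem[which.min(nopts)]
    for (b in partners[[a]]) {
      o <- .other_end(mol, b, a)
      if (matched[o]) next
      matched[a] <<- TRUE; matched[o] <<- TRUE
      chosen <<- c(chosen, b)
      if (rec()) return(TRUE)
      matched[a] <<- FALSE; matched[o] <<- FALSE
      chosen <<- chosen[-length(chosen)]
    }
    FALSE
  }
  if (rec()) chosen else NULL
}

## assign kekule orders to aromatic bonds in place; may promote bare aromatic
## N to N-H when required for a consistent assignment
.kekulize <- function(mol, smiles) {
  in_ring <- .ring_bonds(mol)
  ## aromatic bonds outside rings (e.g. implicit biphenyl bridge) are single
  mol$barom[mol$barom & !in_ring] <- FALSE
  ar_atoms <- which(mol$arom)
  if (!length(ar_atoms)) return(mol)
  has_ar_bond <- rep(FALSE, length(mol$elem))
  ar_bonds <- which(mol$barom)
  has_ar_bond[mol$bonds[ar_bonds, "i"]] <- TRUE
  has_ar_bond[mol$bonds[ar_bonds, "j"]] <- TRUE
  if (any(!has_ar_bond[ar_atoms]))
    parse_error(smiles, "aromatic atom outside an aromatic ring")

  deg <- .mol_degree(mol)
  compute_need <- function(hexp) {
    need <- rep(FALSE, length(mol$elem))
    for (a in ar_atoms) {
      sigma <- deg[a] + if (!is.na(hexp[a])) hexp[a] else 0L
      ## count existing non-aromatic double/triple bonds toward valence
      extra <- 0L
      for (b in seq_len(nrow(mol$bonds))) {
        if (!mol$barom[b] && (mol$bonds[b, "i"] == a || mol$bonds[b, "j"] == a))
          extra <- extra + (mol$bonds[b, "order"] - 1L)
      }
      tgt <- .valence_options(mol$elem[a], mol$charge[a])[1]
      need[a] <- (sigma + extra) < tgt
    }
    need
  }

  hexp <- mol$hexp
  for (attempt in 0:length(ar_atoms)) {
    need <- compute_need(hexp)
    m <- .match_doubles(need, ar_bonds, mol)
    if (!is.null(m)) {
      mol$bonds[ar_bonds, "order"] <- 1L
      mol$bonds[m, "order"] <- 2L
      mol$hexp <- hexp
      return(mol)
    }
    ## promote one bare aromatic N (pyrrole-type written without H) and retry
    cand <- ar_atoms[mol$elem[ar_atoms] == "N" & is.na(hexp[ar_atoms]) &
                     compute_need(hexp)[ar_atoms]]
    cand <- cand[order(deg[cand])]
    if (!length(cand)) break
    hexp[cand[1]] <- 1L
  }
  parse_error(smiles, "kekulization failed")
}

## ---- hydrogens and aromatic re-perception ----------------------------------

.assign_hydrogens <- function(mol, smiles) {
  n <- length(mol$elem)
  bondsum <- integer(n)
  if (nrow(mol$bonds)) {
    for (b in seq_len(nrow(mol$bonds))) {
      bondsum[mol$bonds[b, "i"]] <- bondsum[mol$bonds[b, "i"]] + mol$bonds[b, "order"]
      bondsum[mol$bonds[b, "j"]] <- bondsum[mol$bonds[b, "j"]] + mol$bonds[b, "order"]
    }
  }
  nH <- integer(n)
  for (a in seq_len(n)) {
    if (!is.na(mol$hexp[a])) {
      nH[a] <- mol$hexp[a]
      if (bondsum[a] + nH[a] > max(.valence_options(mol$elem[a], mol$charge[a]), 6L))
        parse_error(smiles, sprintf("valence of atom %d (%s) exceeded", a, mol$elem[a]))
    } else {
      vals <- .valence_options(mol$elem[a], mol$charge[a])
      v <- vals[vals >= bondsum[a]][1]
      if (is.na(v))
        parse_error(smiles, sprintf("valence of atom %d (%s) exceeded", a, mol$elem[a]))
      nH[a] <- v - bondsum[a]
    }
  }
  mol$nH <- nH
  mol$bondsum <- bondsum
  mol
}

## re-perceive aromaticity from the kekule graph: a 5/6-ring is aromatic when
## every member is sp2-covered within its fused ring system or donates a lone
## pair (pyrrole/furan/thiophene type). A pragmatic subset of Hueckel
## perception; sufficient for the benzenoid/azole chemistry handled here.
.perceive_aromaticity <- function(mol) {
  n <- length(mol$elem)
  mol$arom <- rep(FALSE, n)
  mol$barom <- rep(FALSE, nrow(mol$bonds))
  rings <- .small_rings(mol, c(5L, 6L))
  if (!length(rings)) return(mol)
  ok_elem <- vapply(rings, function(r) all(mol$elem[r] %in% .AROMATIC_OK), logical(1))
  rings <- rings[ok_elem]
  if (!length(rings)) return(mol)

  ## fuse candidate rings sharing a bond into systems
  nr <- length(rings)
  parent <- seq_len(nr)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (a in seq_len(nr)) for (b in seq_len(nr)) {
    if (a < b && length(intersect(rings[[a]], rings[[b]])) >= 2L)
      parent[find(b)] <- find(a)
  }
  sys_id <- vapply(seq_len(nr), find, integer(1))

  deg <- .mol_degree(mol)
  dbl_partner <- vector("list", n)
  has_triple <- rep(FALSE, n)
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds[b, "i"]; j <- mol$bonds[b, "j"]
    if (mol$bonds[b, "order"] == 2L) {
      dbl_partner[[i]] <- c(dbl_partner[[i]], j)
      dbl_partner[[j]] <- c(dbl_partner[[j]], i)
    } else if (mol$bonds[b, "order"] == 3L) {
      has_triple[i] <- TRUE; has_triple[j] <- TRUE
    }
  }

  aromatic_rings <- list()
  for (sid in unique(sys_id)) {
    sys_rings <- rings[sys_id == sid]
    sys_atoms <- unique(unlist(sys_rings))
    qualifies <- function(a) {
      if (has_triple[a]) return(FALSE)
      dp <- dbl_partner[[a]]
      if (length(dp) > 1L) return(FALSE)
      if (length(dp) == 1L) return(dp %in% sys_atoms)  # sp2 within the system
      ## no double bond: lone-pair donors
      if (mol$elem[a] == "N" && (mol$nH[a] >= 1L || deg[a] == 3L)) return(TRUE)
      if (mol$elem[a] %in% c("O", "S") && deg[a] == 2L) return(TRUE)
      FALSE
    }
    q <- vapply(sys_atoms, qualifies, logical(1))
    names(q) <- sys_atoms
    for (r in sys_rings) {
      if (all(q[as.character(r)]))
        aromatic_rings[[length(aromatic_rings) + 1L]] <- r
    }
  }
  for (r in aromatic_rings) {
    mol$arom[r] <- TRUE
    rset <- r
    for (b in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[b, "i"]; j <- mol$bonds[b, "j"]
      if (i %in% rset && j %in% rset) {
        ## bond must be a ring edge (consecutive members)
        pi_ <- match(i, r); pj <- match(j, r)
        k <- length(r)
        if (abs(pi_ - pj) == 1L || abs(pi_ - pj) == k - 1L)
          mol$barom[b] <- TRUE
      }
    }
  }
  mol
}

## full SMILES -> internal mol
parse_smiles <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s))
    parse_error(if (is.character(s) && length(s) == 1L) s else "<non-string>",
                "input must be a single non-empty string")
  mol <- .parse_smiles_graph(s)
  mol <- .kekulize(mol, s)
  mol <- .assign_hydrogens(mol, s)
  mol <- .perceive_aromaticity(mol)
  mol$smiles_input <- s
  mol
}

heavy_atom_count <- function(mol) sum(mol$elem != "*")

## molecular formula key (heavy atoms + total H), used in tests/invariants
mol_formula <- function(mol) {
  keep <- mol$elem != "*"
  tab <- table(mol$elem[keep])
  h <- sum(mol$nH[keep])
  parts <- paste0(names(tab), as.integer(tab))
  paste0(paste(parts[order(names(tab))], collapse = ""), "H", h)
}
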