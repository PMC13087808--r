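## Graph surgery: single-cut fragmentation into (constant, variable) parts with
## a dummy-atom attachment marker, and reattachment of fragments. This is the
## substrate for matched-molecular-pair construction and for transformation
## application.

## subset a mol graph to `atoms` (renumbered in their order)
.mol_subset <- function(mol, atoms) {
  remap <- match(seq_along(mol$elem), atoms)
  sel <- mol$bonds[, "i"] %in% atoms & mol$bonds[, "j"] %in% atoms
  list(elem = mol$elem[atoms], arom = mol$arom[atoms],
       charge = mol$charge[atoms], hexp = mol$hexp[atoms],
       map = mol$map[atoms], nH = mol$nH[atoms],
       bonds = cbind(i = remap[mol$bonds[sel, "i"]],
                     j = remap[mol$bonds[sel, "j"]],
                     order = mol$bonds[sel, "order"]),
       barom = mol$barom[sel])
}

## atoms reachable from `start` without traversing bond `skip`
.reachable <- function(mol, start, skip) {
  inc <- .mol_incidence(mol)
  seen <- logical(length(mol$elem)); seen[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nxt <- integer()
    for (a in frontier) for (b in inc[[a]]) {
      if (b == skip) next
      o <- .other_end(mol, b, a)
      if (!seen[o]) { seen[o] <- TRUE; nxt <- c(nxt, o) }
    }
    frontier <- nxt
  }
  which(seen)
}

## append a map-1 dummy atom bonded (single) to atom `at`
.add_marker <- function(mol, at) {
  mol$elem <- c(mol$elem, "*"); mol$arom <- c(mol$arom, FALSE)
  mol$charge <- c(mol$charge, 0L); mol$hexp <- c(mol$hexp, NA_integer_)
  mol$map <- c(mol$map, 1L); mol$nH <- c(mol$nH, 0L)
  mol$bonds <- rbind(mol$bonds, c(i = at, j = length(mol$elem), order = 1L))
  mol$barom <- c(mol$barom, FALSE)
  mol
}

## enumerate all single cuts of acyclic single bonds between heavy atoms;
## returns list of list(side_i, side_j) canonical fragment SMILES (marker on
## the cut atom of each side)
.enumerate_cuts <- function(mol) {
  nb <- nrow(mol$bonds)
  if (!nb) return(list())
  ringb <- .ring_bonds(mol)
  out <- list()
  for (b in seq_len(nb)) {
    if (ringb[b] || mol$bonds[b, "order"] != 1L || mol$barom[b]) next
    i <- mol$bonds[b, "i"]; j <- mol$bonds[b, "j"]
    if (mol$elem[i] == "*" || mol$elem[j] == "*") next
    atoms_i <- .reachable(mol, i, b)
    atoms_j <- setdiff(seq_along(mol$elem), atoms_i)
    side_i <- .add_marker(.mol_subset(mol, atoms_i), match(i, atoms_i))
    side_j <- .add_marker(.mol_subset(mol, atoms_j), match(j, atoms_j))
    out[[length(out) + 1L]] <- list(
      smiles_i = .canonical_string(side_i),
      smiles_j = .canonical_string(side_j),
      heavy_i = sum(side_i$elem != "*"),
      heavy_j = sum(side_j$elem != "*")
    )
  }
  out
}

## join two one-marker fragments into one molecule; returns canonical SMILES.
## `map` selects the marker in `smiles_a` when it carries several (scaffolds
## with numbered attachment points); the marker in `smiles_b` must be unique.
join_fragments <- function(smiles_a, smiles_b, map = NULL, canonical = TRUE) {
  A <- parse_smiles(smiles_a); B <- parse_smiles(smiles_b)
  ma <- which(A$elem == "*" & (if (is.null(map)) TRUE else A$map == map))
  mb <- which(B$elem == "*")
  if (length(ma) < 1L) stop("no attachment marker in fragment A")
  if (length(mb) != 1L) stop("fragment B must carry exactly one attachment marker")
  ma <- ma[1]
  inc_a <- .mol_incidence(A); inc_b <- .mol_incidence(B)
  if (length(inc_a[[ma]]) != 1L || length(inc_b[[mb]]) != 1L)
    stop("attachment markers must be terminal atoms")
  na <- .other_end(A, inc_a[[ma]][1], ma)
  nb <- .other_end(B, inc_b[[mb]][1], mb)

  keep_a <- setdiff(seq_along(A$elem), ma)
  keep_b <- setdiff(seq_along(B$elem), mb)
  Asub <- .mol_subset(A, keep_a); Bsub <- .mol_subset(B, keep_b)
  na2 <- match(na, keep_a); nb2 <- match(nb, keep_b) + length(keep_a)
  mol <- list(
    elem = c(Asub$elem, Bsub$elem), arom = c(Asub$arom, Bsub$arom),
    charge = c(Asub$charge, Bsub$charge), hexp = c(Asub$hexp, Bsub$hexp),
    map = c(Asub$map, Bsub$map), nH = c(Asub$nH, Bsub$nH),
    bonds = rbind(Asub$bonds,
                  cbind(i = Bsub$bonds[, "i"] + length(keep_a),
                        j = Bsub$bonds[, "j"] + length(keep_a),
                        order = Bsub$bonds[, "order"]),
                  c(na2, nb2, 1L)),
    barom = c(Asub$barom, Bsub$barom, FALSE)
  )
  if (canonical) .canonical_string(mol)
  else .emit_smiles(mol, seq_along(mol$elem), start = 1L)
}

## assemble a scaffold with numbered attachment points ([*:1], [*:2], ...) and
## one substituent fragment per attachment; returns canonical SMILES
assemble_scaffold <- function(scaffold, substituents) {
  s <- scaffold
  for (k in seq_along(substituents))
    s <- join_fragments(s, substituents[[k]], map = k, canonical = FALSE)
  canonicalizeSmiles(s)
}
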