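## Post-generation triage: PAINS substructure screening (via the OpenBabel
## SMARTS engine), a novelty window around the lead compound, and the
## one-step transformation-reachability analysis that asks whether a
## prediction could have been produced by a single known fragment swap
## applied to a training molecule.

#' Load the packaged PAINS pattern list
#'
#' @param path optional user list (two-column `name<TAB>smarts` text file;
#'   `#` comments allowed).
#' @return data.frame with columns `name`, `smarts`.
#' @export
painsPatterns <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pains_smarts.tsv", package = "PairTune")
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop(sprintf("malformed pattern line(s): %s",
                 paste(lines[bad], collapse = "; ")))
  data.frame(name = vapply(parts, `[`, character(1), 1L),
             smarts = vapply(parts, `[`, character(1), 2L))
}

## run one SMARTS filter over a SMILES file with obabel; returns matching ids
.obabel_smarts <- function(smi_file, smarts, pattern_name) {
  out <- suppressWarnings(system2("obabel",
    c(smi_file, "-osmi", paste0("-s", shQuote(smarts))),
    stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (any(grepl("SMARTS Error|cannot be interpreted|Invalid SMARTS", out,
                ignore.case = TRUE)) ||
      (status != 0L && !any(grepl("molecules converted", out))))
    stop(sprintf("malformed SMARTS pattern '%s': %s", pattern_name, smarts))
  hits <- out[!grepl("molecule", out) & nzchar(out)]
  vapply(strsplit(hits, "[ \t]+"), function(x) x[length(x)], character(1))
}

#' PAINS substructure screen
#'
#' A molecule fails when it matches at least one pattern; matched pattern
#' names are recorded. Matching uses the OpenBabel SMARTS engine (`obabel`
#' must be on the PATH).
#'
#' @param smiles character vector of SMILES.
#' @param patterns data.frame from [painsPatterns()] (default: packaged
#'   list).
#' @return data.frame with columns `smiles`, `pains_flags` (comma-separated
#'   pattern names, `""` when clean) and `passed`.
#' @export
painsFilter <- function(smiles, patterns = painsPatterns()) {
  if (!length(smiles))
    return(data.frame(smiles = character(), pains_flags = character(),
                      passed = logical()))
  if (!nzchar(Sys.which("obabel")))
    stop("obabel not found on PATH; PAINS screening requires OpenBabel")
  smi_file <- tempfile(fileext = ".smi")
  on.exit(unlink(smi_file), add = TRUE)
  ids <- sprintf("m%06d", seq_along(smiles))
  writeLines(paste(smiles, ids, sep = "\t"), smi_file)
  flags <- vector("list", length(smiles))
  for (k in seq_len(nrow(patterns))) {
    hit_ids <- .obabel_smarts(smi_file, patterns$smarts[k], patterns$name[k])
    for (i in match(hit_ids, ids))
      if (!is.na(i)) flags[[i]] <- c(flags[[i]], patterns$name[k])
  }
  fl <- vapply(flags, function(x) paste(x, collapse = ","), character(1))
  data.frame(smiles = smiles, pains_flags = fl, passed = !nzchar(fl))
}

#' Novelty window around the lead
#'
#' Keeps predictions whose Tanimoto similarity to the lead lies inside
#' `[low, high]` (novel groups, but small scaffold changes) and which are not
#' identical to any training molecule.
#'
#' @param pred_smiles character vector of canonical prediction SMILES.
#' @param training a [MoleculeSet].
#' @param lead_smiles the lead compound's SMILES.
#' @param sim_window numeric `c(low, high)` with `0 <= low < high <= 1`
#'   (default `c(0.5, 0.95)`).
#' @return data.frame with columns `smiles`, `similarity_to_lead`,
#'   `in_training_set`, `passed`.
#' @export
noveltyFilter <- function(pred_smiles, training, lead_smiles,
                          sim_window = c(0.5, 0.95)) {
  stopifnot(length(sim_window) == 2L, sim_window[1] >= 0,
            sim_window[1] < sim_window[2], sim_window[2] <= 1)
  if (!length(pred_smiles))
    return(data.frame(smiles = character(), similarity_to_lead = numeric(),
                      in_training_set = logical(), passed = logical()))
  lead <- canonicalizeSmiles(lead_smiles)
  fp_l <- morganFingerprint(lead)
  sims <- as.vector(tanimotoMatrix(morganFingerprint(pred_smiles), fp_l))
  in_train <- pred_smiles %in% molecules(training)$smiles
  data.frame(smiles = pred_smiles, similarity_to_lead = sims,
             in_training_set = in_train,
             passed = sims >= sim_window[1] & sims <= sim_window[2] & !in_train)
}

## canonical single-cut splits of a molecule, markers normalized to [*:1];
## returns two-column matrix (side_a, side_b)
.cut_table <- function(smiles) {
  cuts <- .enumerate_cuts(parse_smiles(smiles))
  if (!length(cuts)) return(matrix(character(), ncol = 2))
  do.call(rbind, lapply(cuts, function(ct) c(ct$smiles_i, ct$smiles_j)))
}

#' One-step transformation reachability
#'
#' Is the prediction exactly one known fragment swap away from some training
#' molecule? True iff a transformation `lhs -> rhs` applied at a shared
#' constant part of a training molecule yields the prediction: equivalently,
#' some training molecule splits into `(C, lhs)` while the prediction splits
#' into `(C, rhs)`.
#'
#' @param pred_smiles one canonical prediction SMILES.
#' @param training a [MoleculeSet].
#' @param transformations data.frame from [extractTransformations()] (plus
#'   any user-supplied catalogue with columns `lhs`, `rhs`).
#' @return list with `reachable` (logical) and `witnesses` (data.frame `id`,
#'   `lhs`, `rhs`: the training molecules and swaps that produce the
#'   prediction).
#' @export
oneStepReachable <- function(pred_smiles, training, transformations) {
  pred_cuts <- .cut_table(canonicalizeSmiles(pred_smiles))
  wit <- list()
  if (nrow(pred_cuts)) {
    ## constant -> rhs fragments exposed by the prediction
    pred_pairs <- rbind(pred_cuts, pred_cuts[, 2:1, drop = FALSE])
    df <- molecules(training)
    for (i in seq_len(nrow(df))) {
      tc <- .cut_table(df$smiles[i])
      if (!nrow(tc)) next
      tr_pairs <- rbind(tc, tc[, 2:1, drop = FALSE])  # (constant, variable)
      for (k in seq_len(nrow(transformations))) {
        lhs <- transformations$lhs[k]; rhs <- transformations$rhs[k]
        consts <- tr_pairs[tr_pairs[, 2] == lhs, 1]
        if (!length(consts)) next
        hit <- consts %in% pred_pairs[pred_pairs[, 2] == rhs, 1]
        if (any(hit))
          wit[[length(wit) + 1L]] <- data.frame(id = df$id[i], lhs = lhs,
                                                rhs = rhs)
      }
    }
  }
  witnesses <- if (length(wit)) unique(do.call(rbind, wit))
               else data.frame(id = character(), lhs = character(),
                               rhs = character())
  list(reachable = nrow(witnesses) > 0L, witnesses = witnesses)
}

#' Enumerate all one-step transformation products
#'
#' Applies every transformation to every training molecule (the purely
#' combinatorial approach) and returns the deduplicated canonical product
#' set, stopping with a warning once `cap` distinct products are collected.
#'
#' @param training a [MoleculeSet].
#' @param transformations data.frame with columns `lhs`, `rhs`.
#' @param cap maximum number of distinct products (default 10000).
#' @return character vector of distinct canonical product SMILES.
#' @export
enumerateProducts <- function(training, transformations, cap = 10000L) {
  stopifnot(cap >= 1L)
  df <- molecules(training)
  out <- character(0)
  for (i in seq_len(nrow(df))) {
    tc <- .cut_table(df$smiles[i])
    if (!nrow(tc)) next
    tr_pairs <- rbind(tc, tc[, 2:1, drop = FALSE])
    for (k in seq_len(nrow(transformations))) {
      sel <- tr_pairs[, 2] == transformations$lhs[k]
      if (!any(sel)) next
      for (const in tr_pairs[sel, 1]) {
        prod <- join_fragments(const, transformations$rhs[k])
        if (!(prod %in% out)) {
          out <- c(out, prod)
          if (length(out) >= cap) {
            warning(sprintf("product enumeration stopped at cap = %d", cap))
            return(out)
          }
        }
      }
    }
  }
  out
}
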