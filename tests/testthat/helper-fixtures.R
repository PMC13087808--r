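# Shared fixtures, built once per test session and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  v <- get0(name, envir = .fixture_env, inherits = FALSE)
  if (is.null(v)) {
    v <- build()
    assign(name, v, envir = .fixture_env)
  }
  v
}

## a small congeneric series with both properties
small_series <- function() {
  fixture("small_series", function() {
    generateSeries(seriesSpec(n_molecules = 40L, n_inactive = 4L, seed = 11L))
  })
}

## a series whose potency strongly rewards the first R1 substituent
rewarded_series <- function(n = 80L, seed = 21L) {
  fixture(sprintf("rewarded_%d_%d", n, seed), function() {
    pc <- list(c(-2, rep(0, 29)), rep(0, 24))
    generateSeries(seriesSpec(n_molecules = n, n_inactive = n %/% 10,
                              potency_contrib = pc, seed = seed))
  })
}

## assorted drug-like molecules exercising rings, heteroatoms, fused systems
chem_fixture_smiles <- function() c(
  "CCO", "c1ccccc1", "Cc1ccccc1", "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
  "CC(=O)Nc1ccc(O)cc1", "c1cc[nH]c1", "c1ccncc1", "c1ccc2ccccc2c1",
  "N#Cc1ccccc1", "O=S(=O)(N)c1ccccc1", "Clc1ccc(Br)cc1F", "CC1(C)CCC1",
  "c1csc(c1)C(=O)N1CCOCC1", "OCc1ccco1", "CN1CCN(CC1)c1ccc(N)cc1",
  "C#CCN", "CC(=O)OC(C)C", "c1cnc2[nH]ccc2c1", "CC12CCC(CC1)CC2",
  "O=C(N1CCC2(C1)CCN(C2)S(=O)(=O)C)c1ccc(F)cc1"
)

## canonicalize a batch of SMILES with RDKit (independent oracle); returns
## NULL if no python/rdkit is available
rdkit_canonical <- function(smiles) {
  py <- Sys.which("python")
  if (!nzchar(py)) return(NULL)
  fin <- tempfile(fileext = ".smi"); fout <- tempfile()
  writeLines(smiles, fin)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from rdkit import Chem, RDLogger",
    "RDLogger.DisableLog('rdApp.*')",
    "out = []",
    sprintf("lines = open(%s).read().splitlines()", deparse(fin)),
    "for s in lines:",
    "    m = Chem.MolFromSmiles(s)",
    "    if m is None:",
    "        out.append('PARSE_FAIL')",
    "    else:",
    "        Chem.RemoveStereochemistry(m)",
    "        out.append(Chem.MolToSmiles(m))",
    sprintf("open(%s, 'w').write('\\n'.join(out) + '\\n')", deparse(fout))
  ), script)
  status <- system2(py, script, stdout = FALSE, stderr = FALSE)
  if (status != 0L) return(NULL)
  readLines(fout)
}

tiny_config <- function(...) {
  defaults <- list(n_layers = 1L, d_model = 16L, n_heads = 2L, d_ff = 32L,
                   dropout = 0, batch_size = 64L, epochs = 2L, warmup = 100L,
                   max_len = 40L, val_frac = 0, seed = 7L)
  do.call(modelConfig, utils::modifyList(defaults, list(...)))
}
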