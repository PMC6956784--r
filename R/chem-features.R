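#' Ligand-based features: molecular descriptors, MACCS keys, Tanimoto
#'
#' Chemistry (parsing, aromaticity perception, descriptor algorithms,
#' MACCS keys) is delegated to the RDKit toolkit, called through the
#' `python` interpreter on the PATH. Set `options(dockrf.python = ...)` to
#' point at a specific interpreter.
#'
#' Conventions frozen by the test suite:
#' * `nAtom` counts all atoms including implicit hydrogens; `nBond` counts
#'   heavy-atom bonds only.
#' * Rotatable bond: non-ring single bond between two heavy atoms that each
#'   have at least two heavy neighbours, excluding amide C-N bonds
#'   (SMARTS-equivalent: `[!D1;!$(*#*)]-!@[!D1;!$(*#*)]` minus
#'   `[NX3]-[CX3]=[OX1]` pairs).
#' * `HybRatio` = nSP3 / (nSP2 + nSP3) over carbon atoms, 0 when the
#'   denominator is 0.
#' * The `XLogP` column carries the toolkit's Wildman-Crippen logP; logP
#'   values are regression features, not contracts, and cross-toolkit drift
#'   up to ~0.5 log units is expected.
#' * `VABC` is the Zhao-Abraham-Zissimos additive van der Waals volume with
#'   explicit hydrogens.
#'
#' @name chem_features
NULL

#: names of the 11 ligand descriptors, in table order
LIGAND_DESCRIPTORS <- c("MW", "VABC", "nAtom", "nBond", "nRotBond",
                        "nAromBond", "nHBDon", "nHBAcc", "TPSA", "XLogP",
                        "HybRatio")

#' Construct a molecule set from SMILES strings
#'
#' @param smiles character vector of SMILES strings.
#' @param ligand_id unique identifiers; defaults to `mol1..molN`.
#' @param tag representation tag recording 3D-generator / charge-model
#'   provenance (e.g. `"BDB"`, `"Gast"`, `"MMFF"`, `"OB3D"`, `"Frog3D"`, or
#'   any user label).
#' @return a `dockrf_molecules` data frame.
#' @export
molecules <- function(smiles, ligand_id = NULL, tag = "user") {
  if (length(smiles) == 0L)
    stop_dockrf("empty molecule set", class = "dockrf_validation_error")
  ligand_id <- ligand_id %||% paste0("mol", seq_along(smiles))
  if (anyDuplicated(ligand_id))
    stop_dockrf("duplicated ligand_id within one representation tag: %s",
                paste(unique(ligand_id[duplicated(ligand_id)]), collapse = ", "),
                class = "dockrf_validation_error")
  out <- data.frame(ligand_id = as.character(ligand_id),
                    smiles = as.character(smiles),
                    representation_tag = tag,
                    stringsAsFactors = FALSE)
  class(out) <- c("dockrf_molecules", "data.frame")
  out
}

#' Read ligands from a SMILES, SDF (V2000) or MOL2 file
#'
#' The structures are parsed and canonicalized by the chemistry backend; the
#' returned molecule set carries canonical SMILES, so downstream descriptor
#' calls are invariant to the atom order of the input file.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"smiles"`, `"sdf"` or `"mol2"`.
#' @inheritParams molecules
#' @return a `dockrf_molecules` data frame.
#' @export
read_ligands <- function(path, format = c("auto", "smiles", "sdf", "mol2"),
                         tag = "user") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, smi = , smiles = , txt = "smiles",
                     sdf = , sd = , mol = "sdf", mol2 = "mol2",
                     stop_dockrf("cannot infer format from extension '%s'",
                                 ext, class = "dockrf_io_error"))
  }
  tab <- run_chem_backend(path, format)
  bad <- tab$status != "ok"
  if (any(bad))
    stop_dockrf("chemistry backend failed for record(s): %s",
                paste(sprintf("%s (%s)", tab$ligand_id[bad], tab$message[bad]),
                      collapse = "; "),
                class = "dockrf_parse_error")
  mols <- molecules(tab$canonical_smiles, tab$ligand_id, tag = tag)
  attr(mols, "chem_table") <- tab
  mols
}

# Resolve the python interpreter used for chemistry.
chem_python <- function() {
  py <- getOption("dockrf.python", Sys.which("python"))
  if (!nzchar(py))
    stop_dockrf("no 'python' interpreter found on PATH (needed for RDKit)",
                class = "dockrf_backend_error")
  py
}

run_chem_backend <- function(infile, format) {
  script <- system.file("python", "chem_descriptors.py", package = "dockrf")
  if (!nzchar(script))
    stop_dockrf("chem_descriptors.py not found in installed package",
                class = "dockrf_backend_error")
  out <- tempfile(fileext = ".csv")
  on.exit(unlink(out))
  status <- system2(chem_python(),
                    c(shQuote(script), "--infile", shQuote(infile),
                      "--format", format, "--out", shQuote(out)),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status") %||% 0L
  if (code != 0L || !file.exists(out))
    stop_dockrf("chemistry backend exited with status %d:\n%s", code,
                paste(status, collapse = "\n"),
                class = "dockrf_backend_error")
  read.csv(out, stringsAsFactors = FALSE,
           colClasses = c(ligand_id = "character", maccs = "character",
                          message = "character"))
}

chem_table_for <- function(mols) {
  tab <- attr(mols, "chem_table")
  if (!is.null(tab) && identical(tab$ligand_id, mols$ligand_id)) return(tab)
  smi <- tempfile(fileext = ".smi")
  on.exit(unlink(smi))
  writeLines(paste(mols$smiles, mols$ligand_id), smi)
  tab <- run_chem_backend(smi, "smiles")
  bad <- tab$status != "ok"
  if (any(bad))
    stop_dockrf("descriptor computation failed for record(s): %s",
                paste(sprintf("%s (%s)", tab$ligand_id[bad], tab$message[bad]),
                      collapse = "; "),
                class = "dockrf_parse_error")
  tab
}

#' Compute the 11 ligand descriptors plus the rotatable-bond fraction
#'
#' Returns one row per molecule with columns `ligand_id`,
#' `representation_tag`, the 11 descriptors (`MW`, `VABC`, `nAtom`, `nBond`,
#' `nRotBond`, `nAromBond`, `nHBDon`, `nHBAcc`, `TPSA`, `XLogP`, `HybRatio`)
#' and the engineered flexibility ratio `nRotB_nB` = nRotBond / nBond.
#'
#' @param mols a `dockrf_molecules` set (see [molecules()], [read_ligands()]).
#' @return a `dockrf_descriptors` data frame.
#' @export
compute_descriptors <- function(mols) {
  stopifnot(inherits(mols, "dockrf_molecules"))
  tab <- chem_table_for(mols)
  out <- data.frame(ligand_id = mols$ligand_id,
                    representation_tag = mols$representation_tag,
                    stringsAsFactors = FALSE)
  for (d in LIGAND_DESCRIPTORS) out[[d]] <- as.numeric(tab[[d]])
  out$nRotB_nB <- ifelse(out$nBond > 0, out$nRotBond / out$nBond, NA_real_)
  class(out) <- c("dockrf_descriptors", "data.frame")
  out
}

#' Ligand-flexibility ratio nRotBond / nBond
#'
#' Engineered feature summarizing flexibility (entropic cost of binding) as
#' the fraction of rotatable bonds among heavy-atom bonds.
#'
#' @param n_rot_bond number of rotatable bonds.
#' @param n_bond number of heavy-atom bonds; must be positive.
#' @return the ratio in `[0, 1]`.
#' @export
flexibility_ratio <- function(n_rot_bond, n_bond) {
  if (any(n_bond == 0))
    stop_dockrf("nBond is 0: flexibility ratio undefined",
                class = "dockrf_degenerate_error")
  if (any(n_rot_bond < 0) || any(n_bond < 0) || any(n_rot_bond > n_bond))
    stop_dockrf("need 0 <= nRotBond <= nBond",
                class = "dockrf_validation_error")
  n_rot_bond / n_bond
}

#' MACCS fingerprints (166 substructure keys)
#'
#' @param mols a `dockrf_molecules` set.
#' @return a named list of sorted integer vectors (on-bit indices in 1..166),
#'   each of class `dockrf_fingerprint`.
#' @export
maccs_fingerprints <- function(mols) {
  stopifnot(inherits(mols, "dockrf_molecules"))
  tab <- chem_table_for(mols)
  out <- lapply(tab$maccs, function(s) {
    bits <- if (nzchar(s)) sort(as.integer(strsplit(s, ";")[[1]])) else integer(0)
    structure(bits, class = "dockrf_fingerprint")
  })
  names(out) <- mols$ligand_id
  out
}

#' @rdname maccs_fingerprints
#' @param mol a single-row molecule set.
#' @export
maccs_fingerprint <- function(mol) {
  fps <- maccs_fingerprints(mol)
  if (length(fps) != 1L)
    stop_dockrf("maccs_fingerprint() expects exactly one molecule",
                class = "dockrf_validation_error")
  fps[[1L]]
}

#' Tanimoto similarity of two fingerprints
#'
#' |A intersect B| / |A union B|. Two empty fingerprints compare as 0 (with a
#' warning) rather than NaN so that similarity rankings stay total.
#'
#' @param a,b fingerprints as integer bit-index vectors.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- unique(as.integer(a)); b <- unique(as.integer(b))
  u <- length(union(a, b))
  if (u == 0L) {
    warning("both fingerprints empty; Tanimoto defined as 0")
    return(0)
  }
  length(intersect(a, b)) / u
}

#' Write a descriptor table as CSV
#'
#' Header (exact): `ligand_id, representation_tag, MW, VABC, nAtom, nBond,
#' nRotBond, nAromBond, nHBDon, nHBAcc, TPSA, XLogP, HybRatio, nRotB_nB`.
#'
#' @param desc a `dockrf_descriptors` table.
#' @param path output path.
#' @export
write_descriptor_table <- function(desc, path) {
  cols <- c("ligand_id", "representation_tag", LIGAND_DESCRIPTORS, "nRotB_nB")
  write.csv(desc[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a descriptor table written by [write_descriptor_table()]
#' @param path CSV path.
#' @return a `dockrf_descriptors` data frame.
#' @export
read_descriptor_table <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(ligand_id = "character",
                                 representation_tag = "character"))
  need <- c("ligand_id", "representation_tag", LIGAND_DESCRIPTORS, "nRotB_nB")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop_dockrf("descriptor table missing column(s): %s",
                paste(miss, collapse = ", "), class = "dockrf_schema_error")
  class(out) <- c("dockrf_descriptors", "data.frame")
  out
}

#' Fixture molecules
#'
#' A small in-package set of real drug-like and xenobiotic SMILES (steroids,
#' bisphenols, phytoestrogen-like scaffolds, simple probes) used by the test
#' suite and examples; no external downloads.
#'
#' @return named character vector of SMILES.
#' @export
fixture_molecules <- function() {
  c(benzene        = "c1ccccc1",
    methane        = "C",
    ethanol        = "CCO",
    n_pentane      = "CCCCC",
    cyclohexane    = "C1CCCCC1",
    phenol         = "Oc1ccccc1",
    toluene        = "Cc1ccccc1",
    aspirin        = "CC(=O)Oc1ccccc1C(=O)O",
    caffeine       = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    ibuprofen      = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
    acetamide      = "CC(=O)N",
    bisphenol_a    = "CC(C)(c1ccc(O)cc1)c1ccc(O)cc1",
    estradiol      = "C[C@]12CC[C@H]3[C@@H](CCc4cc(O)ccc34)[C@@H]1CC[C@@H]2O",
    estrone        = "C[C@]12CC[C@H]3[C@@H](CCc4cc(O)ccc34)[C@@H]1CCC2=O",
    diethylstilbestrol = "CC/C(=C(\\CC)c1ccc(O)cc1)/c1ccc(O)cc1",
    genistein      = "Oc1ccc(cc1)C1=COc2cc(O)cc(O)c2C1=O",
    tamoxifen_core = "CC/C(=C(\\c1ccccc1)c1ccc(OCCN(C)C)cc1)/c1ccccc1",
    coumestrol_like = "Oc1ccc2c(c1)oc1c(c2=O)ccc(O)c1",
    chlorophenol   = "Oc1ccc(Cl)cc1",
    naproxen       = "COc1ccc2cc(ccc2c1)C(C)C(=O)O")
}
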