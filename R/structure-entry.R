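#' @keywords internal
"_PACKAGE"

#' @importFrom stats median sd setNames
#' @importFrom utils read.csv write.csv head
#' @importFrom Rcpp sourceCpp
#' @useDynLib pocketome, .registration = TRUE
NULL

.water_resids <- c("HOH", "WAT", "H2O", "DOD", "D2O")
.hydrogen_elements <- c("H", "D")

.atom_cols <- c("eleno", "elety", "alt", "resid", "chain", "resno",
                "x", "y", "z", "elesy", "hetero")

#' Construct a structure entry
#'
#' A `structure_entry` is the unit of curation: one PDB entry holding its
#' atom table, per-chain UniProt mapping, and the experimental metadata the
#' quality filters act on (method, resolution, R-free minus R-factor for
#' X-ray, Fourier shell correlation for cryo-EM).
#'
#' @param entry_id Four-character PDB-style code (any non-empty label is
#'   accepted for synthetic entries).
#' @param atoms Data frame with columns `eleno`, `elety`, `alt`, `resid`,
#'   `chain`, `resno`, `x`, `y`, `z`, `elesy`, `hetero`.  `alt` is a single
#'   character (`""` when no alternative location), `hetero` is logical.
#' @param method One of `"XRAY"`, `"CRYOEM"`, `"NMR"`, `"OTHER"`.
#' @param resolution Resolution in Angstrom, or `NA`.
#' @param r_free_minus_r_factor Difference R-free - R-factor, or `NA`.
#' @param fsc Fourier shell correlation criterion value, or `NA`.
#' @param uniprot Named character vector mapping chain identifiers to
#'   UniProt accessions; unmapped chains may be absent or `NA`.
#' @param ligand_occurrence Optional named integer vector giving, per HET
#'   code, its occurrence count in the source archive (used by the
#'   frequent-ligand exclusion rule).
#'
#' @return An object of class `structure_entry`.
#' @export
structure_entry <- function(entry_id, atoms,
                            method = c("XRAY", "CRYOEM", "NMR", "OTHER"),
                            resolution = NA_real_,
                            r_free_minus_r_factor = NA_real_,
                            fsc = NA_real_,
                            uniprot = character(),
                            ligand_occurrence = NULL) {
  if (!is.character(entry_id) || length(entry_id) != 1L || !nzchar(entry_id))
    stop("'entry_id' must be a non-empty character scalar")
  method <- match.arg(method)
  if (!is.data.frame(atoms))
    stop("'atoms' must be a data frame")
  missing_cols <- setdiff(.atom_cols, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  atoms <- atoms[, .atom_cols]
  atoms$alt[is.na(atoms$alt)] <- ""
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("atom coordinates must be finite")
  if (!is.na(resolution) && resolution <= 0)
    stop("'resolution' must be positive when present")
  atoms$elesy <- toupper(atoms$elesy)
  entry <- list(
    entry_id = entry_id,
    method = method,
    resolution = resolution,
    r_free_minus_r_factor = r_free_minus_r_factor,
    fsc = fsc,
    atoms = atoms,
    uniprot = uniprot,
    ligand_occurrence = ligand_occurrence
  )
  class(entry) <- "structure_entry"
  entry
}

#' @export
print.structure_entry <- function(x, ...) {
  ch <- protein_chains(x)
  ligs <- entry_ligands(x)
  cat(sprintf("structure_entry %s [%s]\n", x$entry_id, x$method))
  if (!is.na(x$resolution))
    cat(sprintf("  resolution: %.2f A\n", x$resolution))
  cat(sprintf("  %d atoms; protein chains: %s; %d ligand(s)\n",
              nrow(x$atoms),
              if (length(ch)) paste(ch, collapse = ",") else "none",
              length(ligs)))
  invisible(x)
}

#' Protein chain identifiers of an entry
#'
#' Chains that contain at least one non-hetero (polymer) atom.
#'
#' @param entry A `structure_entry`.
#' @return Character vector of chain identifiers, in order of appearance.
#' @export
protein_chains <- function(entry) {
  stopifnot(inherits(entry, "structure_entry"))
  unique(entry$atoms$chain[!entry$atoms$hetero])
}

#' Extract the atoms of one chain
#'
#' @param entry A `structure_entry`.
#' @param chain Chain identifier.
#' @param heavy If `TRUE` (default) drop hydrogen and deuterium atoms.
#' @param protein_only If `TRUE` (default) drop hetero atoms (ligands,
#'   waters) so only polymer atoms remain.
#' @return Atom data frame (possibly zero rows).
#' @export
chain_atoms <- function(entry, chain, heavy = TRUE, protein_only = TRUE) {
  stopifnot(inherits(entry, "structure_entry"))
  a <- entry$atoms[entry$atoms$chain == chain, , drop = FALSE]
  if (protein_only) a <- a[!a$hetero, , drop = FALSE]
  if (heavy) a <- a[!(a$elesy %in% .hydrogen_elements), , drop = FALSE]
  a
}

#' Number of residues in a chain
#'
#' Counts distinct (residue number, residue name) pairs among polymer atoms.
#'
#' @inheritParams chain_atoms
#' @return Integer count.
#' @export
chain_residue_count <- function(entry, chain) {
  a <- chain_atoms(entry, chain, heavy = FALSE, protein_only = TRUE)
  if (!nrow(a)) return(0L)
  nrow(unique(a[, c("resno", "resid")]))
}

#' Ligand records of an entry
#'
#' Hetero residues that are not water, grouped by (chain, residue number,
#' HET code).  Each record carries its atom table and, when the entry holds
#' an occurrence table, the archive-wide occurrence count of its HET code.
#'
#' @param entry A `structure_entry`.
#' @return List of `ligand_record` objects.
#' @export
entry_ligands <- function(entry) {
  stopifnot(inherits(entry, "structure_entry"))
  het <- entry$atoms[entry$atoms$hetero &
                       !(entry$atoms$resid %in% .water_resids), , drop = FALSE]
  if (!nrow(het)) return(list())
  key <- paste(het$chain, het$resno, het$resid, sep = "\r")
  lapply(split(seq_len(nrow(het)), key)[unique(key)], function(idx) {
    a <- het[idx, , drop = FALSE]
    occ <- NA_integer_
    if (!is.null(entry$ligand_occurrence) &&
        a$resid[1L] %in% names(entry$ligand_occurrence))
      occ <- as.integer(entry$ligand_occurrence[[a$resid[1L]]])
    ligand_record(het_code = a$resid[1L], residue_number = a$resno[1L],
                  chain_id = a$chain[1L], atoms = a, pdb_occurrence = occ)
  })
}

#' Construct a ligand record
#'
#' @param het_code Chemical component identifier (1-3 characters).
#' @param residue_number Residue sequence number of the ligand.
#' @param chain_id Chain holding the ligand.
#' @param atoms Atom data frame for the ligand.
#' @param pdb_occurrence Archive-wide occurrence count of the HET code, or
#'   `NA` when unknown.
#' @return An object of class `ligand_record`.
#' @export
ligand_record <- function(het_code, residue_number, chain_id, atoms,
                          pdb_occurrence = NA_integer_) {
  stopifnot(is.data.frame(atoms))
  out <- list(het_code = het_code, residue_number = as.integer(residue_number),
              chain_id = chain_id, atoms = atoms,
              pdb_occurrence = pdb_occurrence)
  class(out) <- "ligand_record"
  out
}

#' Heavy atoms of a ligand
#'
#' Hydrogen and deuterium are excluded; deuterium counts as hydrogen by
#' chemical convention.
#'
#' @param lig A `ligand_record`.
#' @return Atom data frame of the heavy atoms.
#' @export
ligand_heavy_atoms <- function(lig) {
  stopifnot(inherits(lig, "ligand_record"))
  a <- lig$atoms
  a[!(toupper(a$elesy) %in% .hydrogen_elements), , drop = FALSE]
}

# coordinate matrix helper (heavy-atom data frame -> n x 3 matrix)
.xyz <- function(atoms) {
  cbind(x = atoms$x, y = atoms$y, z = atoms$z)
}

# squared distance matrix between two n x 3 coordinate matrices
.dist2_xyz <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  d2 <- outer(rowSums(p^2), rep(1, nrow(q))) +
    outer(rep(1, nrow(p)), rowSums(q^2)) - 2 * tcrossprod(p, q)
  d2[d2 < 0] <- 0
  d2
}
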