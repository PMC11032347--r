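.pocket_annotations <- c("orthosteric", "nonorthosteric",
                         "liganded_orthosteric_competitive",
                         "liganded_orthosteric_noncompetitive",
                         "liganded_allosteric", "unliganded", "")

#' Compose a pocket negative-image file name
#'
#' File names follow the published pattern
#' `"<pdb>-<chains>-<uniprots>[-<lig>-<resnum>]_CAVITY_N<k>_ALL_<annotation>.mol2"`,
#' e.g. `"1bxl-AB-Q07817-Q16611_CAVITY_N1_ALL_orthosteric.mol2"` for a
#' heterodimer pocket or
#' `"1t4e-A-Q00987-DIZ-112_CAVITY_N1_ALL_liganded_orthosteric_competitive.mol2"`
#' for a liganded one.  An empty annotation yields the `"_ALL__.mol2"`
#' ligand-agnostic variant.
#'
#' @param pdb PDB entry code.
#' @param chains Chain identifier(s), concatenated (e.g. `"AB"`).
#' @param uniprots Character vector of UniProt accessions.
#' @param cavity_index Positive integer `k` of `CAVITY_N<k>`.
#' @param annotation One of the pocket-class labels (see Details) or `""`.
#' @param lig,resnum Optional ligand HET code and residue number.
#' @param within Optional chain tag appended as `"-within<chain>"`.
#' @return File name (no directory component).
#' @export
pocket_file_name <- function(pdb, chains, uniprots, cavity_index,
                             annotation = "", lig = NULL, resnum = NULL,
                             within = NULL) {
  if (!annotation %in% .pocket_annotations)
    stop("unknown pocket annotation: '", annotation, "'")
  stem <- paste(c(pdb, chains, uniprots), collapse = "-")
  if (!is.null(lig)) {
    if (is.null(resnum)) stop("'resnum' required when 'lig' is given")
    stem <- paste(stem, lig, resnum, sep = "-")
  }
  if (!is.null(within)) stem <- paste0(stem, "-within", within)
  ann_tok <- if (nzchar(annotation)) annotation else "_"
  sprintf("%s_CAVITY_N%d_ALL_%s.mol2", stem, as.integer(cavity_index), ann_tok)
}

#' Validate a pocket negative-image file name
#'
#' @param name File name (with or without directory part).
#' @return Logical: does `name` match the documented pattern?
#' @export
validate_pocket_file_name <- function(name) {
  name <- basename(name)
  ann_alt <- paste(c(setdiff(.pocket_annotations, ""), "_"), collapse = "|")
  pat <- paste0("^[A-Za-z0-9]+(-[A-Za-z0-9]+)+(-within[A-Za-z0-9]+)?",
                "_CAVITY_N[0-9]+_ALL_(", ann_alt, ")\\.mol2$")
  grepl(pat, name)
}

#' Pocket row identifier for descriptor tables
#'
#' Row IDs follow the published pattern
#' `"<pdb>-<chain>-<uniprot>[-<lig>-<resnum>]_CAVITY_N<k>_<class>"`, e.g.
#' `"4lgu-A-Q13490-1YH-402_CAVITY_N2_liganded_orthosteric_competitive"`.
#'
#' @inheritParams pocket_file_name
#' @param class_label Pocket class label appended after the cavity token.
#' @return Character row identifier.
#' @export
pocket_row_id <- function(pdb, chains, uniprots, cavity_index, class_label,
                          lig = NULL, resnum = NULL) {
  stem <- paste(c(pdb, chains, uniprots), collapse = "-")
  if (!is.null(lig)) {
    if (is.null(resnum)) stop("'resnum' required when 'lig' is given")
    stem <- paste(stem, lig, resnum, sep = "-")
  }
  sprintf("%s_CAVITY_N%d_%s", stem, as.integer(cavity_index), class_label)
}

#' Write a cavity as a Mol2 negative image
#'
#' One `@<TRIPOS>ATOM` record is written per cavity point; the atom name
#' and SYBYL type both carry the pharmacophoric probe label.  Probe
#' pseudo-atoms get zero charge and a single substructure named `CAV1`.
#'
#' @param cav A [cavity()] with probes assigned.
#' @param path Output file path (conventionally produced by
#'   [pocket_file_name()]).
#' @param annotation Pocket-class label recorded in the molecule comment.
#' @return Invisibly, `path`.
#' @export
write_pocket_mol2 <- function(cav, path, annotation = "") {
  stopifnot(inherits(cav, "cavity"))
  p <- cav$points
  if (!nrow(p)) stop("empty cavity")
  if (any(is.na(p$probe)))
    stop("cavity has unassigned probes; run assign_probes() first")
  if (!all(p$probe %in% probe_levels()))
    stop("unknown probe label in cavity")
  hdr <- c("@<TRIPOS>MOLECULE",
           sprintf("%s %s", cav$cavity_id,
                   if (nzchar(annotation)) annotation else "pocket"),
           sprintf("%5d %5d %5d %5d %5d", nrow(p), 0L, 1L, 0L, 0L),
           "SMALL",
           "NO_CHARGES",
           "",
           "@<TRIPOS>ATOM")
  atoms <- sprintf("%7d %-8s %9.4f %9.4f %9.4f %-8s %5d %-8s %9.4f",
                   seq_len(nrow(p)), p$probe, p$x, p$y, p$z, p$probe,
                   1L, "CAV1", 0)
  writeLines(c(hdr, atoms, "@<TRIPOS>SUBSTRUCTURE",
               sprintf("%6d %-8s %6d", 1L, "CAV1", 1L)), path)
  invisible(path)
}

#' Read a Mol2 pocket negative image
#'
#' Reads back a file written by [write_pocket_mol2()] (via bio3d's Mol2
#' parser): point coordinates and probe labels are recovered; buriedness
#' is not stored in Mol2 and comes back as `NA`.
#'
#' @param path Path to the Mol2 file.
#' @param cavity_id Cavity identifier; default taken from the molecule
#'   name record.
#' @param step Grid spacing to assume for the volume (default 1).
#' @return A [cavity()].
#' @export
read_pocket_mol2 <- function(path, cavity_id = NULL, step = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- suppressWarnings(bio3d::read.mol2(path))  # pockets have no bonds
  at <- m$atom
  probes <- trimws(at$elena)
  points <- data.frame(x = at$x, y = at$y, z = at$z,
                       buriedness = NA_integer_,
                       probe = probes, stringsAsFactors = FALSE)
  if (is.null(cavity_id)) {
    nm <- strsplit(trimws(m$name[1L]), "[[:space:]]+")[[1L]][1L]
    cavity_id <- if (grepl("^CAVITY_N[0-9]+$", nm)) nm else "CAVITY_N1"
  }
  cavity(points, cavity_id = cavity_id, step = step)
}
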