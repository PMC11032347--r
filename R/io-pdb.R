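#' Read a PDB coordinate file into a structure entry
#'
#' Parses ATOM/HETATM records (via bio3d) into the chain/residue/atom
#' hierarchy used throughout the toolkit.  Alternative-location characters
#' are preserved, hetero flags follow the record type, and coordinates are
#' kept exactly as printed (no re-centering).  Hydrogens present in the
#' file are retained; downstream distance logic works on heavy atoms.
#'
#' @param path Path to a PDB-format text file.
#' @param entry_id Entry identifier; defaults to the file stem.
#' @param metadata Optional metadata record (a list as returned by
#'   [read_metadata_json()] for one entry) used to populate method,
#'   resolution, R-free - R-factor, FSC and the chain-to-UniProt map.
#' @return A [structure_entry()].
#' @export
read_pdb <- function(path, entry_id = NULL, metadata = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_coord <- grepl("^(ATOM  |HETATM)", lines)
  if (!length(lines) || !any(is_coord))
    stop("no ATOM/HETATM records in '", path, "'")
  for (i in which(is_coord)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed coordinate line ", i, " in '", path,
           "': fewer than 54 columns")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop("malformed coordinate line ", i, " in '", path,
           "': non-numeric coordinates")
  }
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  elesy <- at$elesy
  guess <- toupper(substr(trimws(at$elety), 1L, 1L))
  elesy[is.na(elesy) | !nzchar(trimws(elesy))] <-
    guess[is.na(elesy) | !nzchar(trimws(elesy))]
  atoms <- data.frame(
    eleno = at$eleno,
    elety = trimws(at$elety),
    alt = ifelse(is.na(at$alt), "", at$alt),
    resid = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    x = at$x, y = at$y, z = at$z,
    elesy = toupper(trimws(elesy)),
    hetero = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  if (is.null(entry_id))
    entry_id <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  entry <- structure_entry(entry_id, atoms)
  if (!is.null(metadata)) entry <- apply_metadata(entry, metadata)
  entry
}

#' Write a structure entry as a PDB coordinate file
#'
#' Emits fixed-column ATOM/HETATM records (altloc in column 17, element in
#' columns 77-78) with a trailing END record.  Coordinates are printed to
#' three decimals, the PDB standard.
#'
#' @param entry A [structure_entry()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(entry, path) {
  stopifnot(inherits(entry, "structure_entry"))
  a <- entry$atoms
  if (!nrow(a)) stop("entry has no atoms to write")
  name4 <- ifelse(nchar(a$elety) < 4L, sprintf(" %-3s", a$elety),
                  substr(a$elety, 1L, 4L))
  rec <- sprintf("%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 ifelse(a$hetero, "HETATM", "ATOM"),
                 a$eleno %% 100000L, name4,
                 substr(paste0(a$alt, " "), 1L, 1L),
                 a$resid, substr(paste0(a$chain, " "), 1L, 1L),
                 a$resno %% 10000L, a$x, a$y, a$z, 1, 0,
                 substr(paste0(a$elesy, " "), 1L, 2L))
  writeLines(c(rec, "END"), path)
  invisible(path)
}

#' Read PDBe-style metadata records from JSON
#'
#' The expected layout is a JSON object keyed by entry identifier, each
#' value an object with optional fields `method`, `resolution`, `r_free`,
#' `r_factor` (or pre-computed `r_free_minus_r_factor`), `fsc`, `uniprot`
#' (object mapping chain to accession) and `ligand_occurrence` (object
#' mapping HET code to count).
#'
#' @param path Path to the JSON file.
#' @return Named list of metadata records.
#' @export
read_metadata_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Attach metadata to a structure entry
#'
#' @param entry A [structure_entry()].
#' @param meta One metadata record (list); see [read_metadata_json()].
#' @return The updated entry.
#' @export
apply_metadata <- function(entry, meta) {
  stopifnot(inherits(entry, "structure_entry"), is.list(meta))
  if (!is.null(meta$method)) {
    m <- toupper(meta$method)
    m <- switch(m,
                "X-RAY" = , "XRAY" = , "X-RAY DIFFRACTION" = "XRAY",
                "CRYOEM" = , "CRYO-EM" = , "ELECTRON MICROSCOPY" = "CRYOEM",
                "NMR" = , "SOLUTION NMR" = "NMR",
                "OTHER")
    entry$method <- m
  }
  num_or_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  if (!is.null(meta$resolution)) entry$resolution <- num_or_na(meta$resolution)
  if (!is.null(meta$r_free_minus_r_factor)) {
    entry$r_free_minus_r_factor <- num_or_na(meta$r_free_minus_r_factor)
  } else if (!is.null(meta$r_free) && !is.null(meta$r_factor)) {
    entry$r_free_minus_r_factor <- num_or_na(meta$r_free) - num_or_na(meta$r_factor)
  }
  if (!is.null(meta$fsc)) entry$fsc <- num_or_na(meta$fsc)
  if (!is.null(meta$uniprot))
    entry$uniprot <- unlist(meta$uniprot)
  if (!is.null(meta$ligand_occurrence))
    entry$ligand_occurrence <- unlist(meta$ligand_occurrence)
  entry
}
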