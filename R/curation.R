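#' Curation configuration
#'
#' Thresholds of the structure- and ligand-level filters.  X-ray entries
#' must have resolution <= 3.5 A and R-free - R-factor <= 0.07; cryo-EM
#' entries resolution <= 3.0 A and FSC <= 0.143; NMR entries carry no
#' resolution criterion.  Ligands must have at least five heavy atoms
#' made exclusively of drug-like elements (C, N, O, S, P, halogens,
#' boron); HET codes occurring fewer than `ligand_occurrence_exclusion_threshold`
#' times archive-wide are flagged for exclusion (crystallization
#' artefacts etc.), subject to a user-curated whitelist standing in for
#' visual inspection.
#'
#' @param max_res_xray,max_res_cryoem Resolution ceilings in Angstrom.
#' @param max_rfree_minus_rfactor Ceiling on R-free - R-factor (X-ray).
#' @param max_fsc Ceiling on the FSC criterion value (cryo-EM).
#' @param min_ligand_heavy_atoms Minimum ligand heavy-atom count.
#' @param allowed_elements Permitted heavy-atom element symbols.
#' @param ligand_occurrence_exclusion_threshold Strict occurrence cutoff.
#' @param exclusion_list HET codes always rejected.
#' @param whitelist HET codes exempted from the occurrence rule.
#' @return A list of class `curation_config`.
#' @export
curation_config <- function(max_res_xray = 3.5, max_res_cryoem = 3.0,
                            max_rfree_minus_rfactor = 0.07, max_fsc = 0.143,
                            min_ligand_heavy_atoms = 5L,
                            allowed_elements = c("C", "N", "O", "S", "P",
                                                 "I", "BR", "CL", "F", "B"),
                            ligand_occurrence_exclusion_threshold = 10L,
                            exclusion_list = character(),
                            whitelist = character()) {
  stopifnot(max_res_xray > 0, max_res_cryoem > 0,
            max_rfree_minus_rfactor > 0, max_fsc > 0,
            min_ligand_heavy_atoms > 0,
            ligand_occurrence_exclusion_threshold > 0,
            length(allowed_elements) > 0)
  out <- list(max_res_xray = max_res_xray, max_res_cryoem = max_res_cryoem,
              max_rfree_minus_rfactor = max_rfree_minus_rfactor,
              max_fsc = max_fsc,
              min_ligand_heavy_atoms = as.integer(min_ligand_heavy_atoms),
              allowed_elements = toupper(allowed_elements),
              ligand_occurrence_exclusion_threshold =
                as.integer(ligand_occurrence_exclusion_threshold),
              exclusion_list = toupper(exclusion_list),
              whitelist = toupper(whitelist))
  class(out) <- "curation_config"
  out
}

.filter_report <- function(entry_id, failed_rules, thresholds = list()) {
  out <- list(entry_id = entry_id,
              verdict = if (length(failed_rules)) "REJECT" else "ACCEPT",
              failed_rules = failed_rules,
              thresholds = thresholds)
  class(out) <- "filter_report"
  out
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("%s: %s", x$entry_id, x$verdict))
  if (length(x$failed_rules))
    cat(" [", paste(x$failed_rules, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Experimental-quality filter
#'
#' Applies the method-specific quality rules (see [curation_config()]).
#' Entries determined by methods other than X-ray, cryo-EM or NMR are
#' rejected; missing mandatory metadata is a rejection (rule
#' `missing_metadata`), not an error.
#'
#' @param entry A [structure_entry()].
#' @param cfg A [curation_config()].
#' @return A `filter_report`.
#' @export
filter_structure_quality <- function(entry, cfg = curation_config()) {
  stopifnot(inherits(entry, "structure_entry"))
  failed <- character()
  if (entry$method == "XRAY") {
    if (is.na(entry$resolution)) failed <- c(failed, "missing_metadata")
    else if (entry$resolution > cfg$max_res_xray) failed <- c(failed, "resolution")
    if (is.na(entry$r_free_minus_r_factor)) failed <- c(failed, "missing_metadata")
    else if (entry$r_free_minus_r_factor > cfg$max_rfree_minus_rfactor)
      failed <- c(failed, "r_free_minus_r_factor")
  } else if (entry$method == "CRYOEM") {
    if (is.na(entry$resolution)) failed <- c(failed, "missing_metadata")
    else if (entry$resolution > cfg$max_res_cryoem) failed <- c(failed, "resolution")
    if (is.na(entry$fsc)) failed <- c(failed, "missing_metadata")
    else if (entry$fsc > cfg$max_fsc) failed <- c(failed, "fsc")
  } else if (entry$method != "NMR") {
    failed <- c(failed, "method")
  }
  .filter_report(entry$entry_id, unique(failed),
                 list(max_res_xray = cfg$max_res_xray,
                      max_res_cryoem = cfg$max_res_cryoem,
                      max_rfree_minus_rfactor = cfg$max_rfree_minus_rfactor,
                      max_fsc = cfg$max_fsc))
}

#' Heterodimer selection
#'
#' Retains entries with exactly two protein molecules carrying distinct
#' UniProt accessions, each with more than three residues (i.e. >= 4).
#' Chains without a UniProt mapping reject the entry (`unmapped_chain`).
#'
#' @param entries List of [structure_entry()] objects.
#' @return List with `accepted` (entries) and `reports` (one
#'   `filter_report` per input entry).
#' @export
select_heterodimers <- function(entries) {
  reports <- lapply(entries, function(e) {
    failed <- character()
    ch <- protein_chains(e)
    if (length(ch) != 2L) failed <- c(failed, "chain_count")
    acc <- unname(e$uniprot[ch])
    if (length(ch) && (length(acc) < length(ch) || any(is.na(acc)) ||
                       any(!nzchar(acc))))
      failed <- c(failed, "unmapped_chain")
    if (length(ch) == 2L && !("unmapped_chain" %in% failed) &&
        acc[1L] == acc[2L])
      failed <- c(failed, "homodimer")
    if (any(vapply(ch, function(c0) chain_residue_count(e, c0) < 4L, logical(1L))))
      failed <- c(failed, "short_chain")
    .filter_report(e$entry_id, failed, list(min_residues = 4L))
  })
  list(accepted = entries[vapply(reports, function(r)
    r$verdict == "ACCEPT", logical(1L))],
    reports = reports)
}

#' Ligand drug-likeness filter
#'
#' Accepts a ligand iff it has at least `min_ligand_heavy_atoms` heavy
#' atoms, every heavy atom is a drug-like element, its HET code is not on
#' the exclusion list, and it does not fall to the frequent-artefact
#' occurrence rule (deuterium counts as hydrogen).
#'
#' @param lig A [ligand_record()].
#' @param cfg A [curation_config()].
#' @param occurrence_exclusions Optional HET-code set from
#'   [build_occurrence_exclusions()].
#' @return A `filter_report` (identified by `"<het>-<resno>"`).
#' @export
filter_ligand <- function(lig, cfg = curation_config(),
                          occurrence_exclusions = character()) {
  stopifnot(inherits(lig, "ligand_record"))
  failed <- character()
  heavy <- ligand_heavy_atoms(lig)
  if (nrow(heavy) < cfg$min_ligand_heavy_atoms)
    failed <- c(failed, "min_heavy_atoms")
  bad <- setdiff(unique(toupper(heavy$elesy)), cfg$allowed_elements)
  if (length(bad)) failed <- c(failed, "element")
  code <- toupper(lig$het_code)
  if (code %in% cfg$exclusion_list) failed <- c(failed, "exclusion_list")
  if (code %in% setdiff(toupper(occurrence_exclusions), cfg$whitelist))
    failed <- c(failed, "occurrence")
  .filter_report(paste0(lig$het_code, "-", lig$residue_number), failed,
                 list(min_heavy_atoms = cfg$min_ligand_heavy_atoms))
}

#' Candidate exclusion set from ligand occurrence counts
#'
#' HET codes occurring strictly fewer than the configured threshold times
#' are flagged (count 9 is flagged, count 10 is not).  The result is
#' meant to be reviewed: codes on the config whitelist are removed, the
#' configured hard exclusion list is not touched here.
#'
#' @param occurrence_table Named non-negative integer vector
#'   (HET code -> count).
#' @param cfg A [curation_config()].
#' @return Character vector of HET codes to exclude.
#' @export
build_occurrence_exclusions <- function(occurrence_table,
                                        cfg = curation_config()) {
  if (!length(occurrence_table)) return(character())
  if (any(occurrence_table < 0)) stop("occurrence counts must be non-negative")
  codes <- toupper(names(occurrence_table))
  flagged <- codes[occurrence_table < cfg$ligand_occurrence_exclusion_threshold]
  setdiff(flagged, cfg$whitelist)
}

#' Interface alternative-location filter
#'
#' Rejects an entry iff any atom of the given interface patch carries a
#' non-blank alternative-location indicator; altlocs away from the
#' interface are tolerated.
#'
#' @param entry A [structure_entry()].
#' @param interface An `interface_patch` (see [interface_patch()]).
#' @return A `filter_report`.
#' @export
check_interface_altlocs <- function(entry, interface) {
  stopifnot(inherits(entry, "structure_entry"),
            inherits(interface, "interface_patch"))
  failed <- character()
  if (nrow(interface$atoms) && any(nzchar(interface$atoms$alt)))
    failed <- "altloc"
  .filter_report(entry$entry_id, failed)
}

#' Cross-reference protein-ligand entries with the heterodimer set
#'
#' A PL entry is retained iff it contains exactly one protein molecule
#' and that molecule's UniProt accession occurs in at least one curated
#' heterodimer; retained entries are linked to all matching heterodimers.
#'
#' @param pl_entries,hd_entries Lists of [structure_entry()] objects.
#' @return List with `accepted` (each element a list `entry`,
#'   `linked_hd_ids`) and `reports`.
#' @export
cross_reference_pl <- function(pl_entries, hd_entries) {
  hd_acc <- lapply(hd_entries, function(e) unname(e$uniprot[protein_chains(e)]))
  reports <- list(); accepted <- list()
  for (e in pl_entries) {
    failed <- character()
    ch <- protein_chains(e)
    if (length(ch) != 1L) failed <- c(failed, "monomer_rule")
    acc <- if (length(ch) == 1L) unname(e$uniprot[ch]) else NA_character_
    if (length(ch) == 1L && (is.na(acc) || !nzchar(acc)))
      failed <- c(failed, "unmapped_chain")
    links <- character()
    if (!length(failed)) {
      hit <- vapply(hd_acc, function(a) acc %in% a, logical(1L))
      if (!any(hit)) failed <- c(failed, "no_hd_match")
      else links <- vapply(hd_entries[hit], `[[`, character(1L), "entry_id")
    }
    rep <- .filter_report(e$entry_id, failed)
    reports[[length(reports) + 1L]] <- rep
    if (rep$verdict == "ACCEPT")
      accepted[[length(accepted) + 1L]] <- list(entry = e,
                                                linked_hd_ids = links)
  }
  list(accepted = accepted, reports = reports)
}

#' Prepare a structure for pocket detection
#'
#' Water molecules are always removed; hetero atoms are additionally
#' removed for heterodimer (HD) entries only, so bound ligands survive in
#' protein-ligand (PL) mode.  An optional `prepare_hook` (e.g. a
#' side-chain repair or protonation step) is applied last; the default is
#' a no-op.
#'
#' @param entry A [structure_entry()].
#' @param mode `"HD"` or `"PL"`.
#' @param prepare_hook Function `structure_entry -> structure_entry`, or
#'   `NULL`.
#' @return The prepared entry.
#' @export
prepare_structure <- function(entry, mode = c("HD", "PL"),
                              prepare_hook = NULL) {
  stopifnot(inherits(entry, "structure_entry"))
  mode <- match.arg(mode)
  a <- entry$atoms
  keep <- !(a$hetero & a$resid %in% .water_resids)
  if (mode == "HD") keep <- keep & !a$hetero
  entry$atoms <- a[keep, , drop = FALSE]
  if (!is.null(prepare_hook)) entry <- prepare_hook(entry)
  entry
}

#' Write per-rule rejection reports
#'
#' Mirrors the rejection-file layout of curated datasets: one plain-text
#' file per rule, listing the identifiers rejected by it.
#'
#' @param reports List of `filter_report` objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_rejection_reports <- function(reports, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rules <- sort(unique(unlist(lapply(reports, `[[`, "failed_rules"))))
  paths <- character()
  for (rule in rules) {
    ids <- vapply(Filter(function(r) rule %in% r$failed_rules, reports),
                  `[[`, character(1L), "entry_id")
    p <- file.path(dir, paste0("rejected_", rule, ".txt"))
    writeLines(ids, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
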