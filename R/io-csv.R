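.burial_bin_labels <- c("40", "40.50", "50.60", "60.70", "70.80",
                        "80.90", "90.100", "100.110", "110.120", "120")

#' Canonical descriptor column names
#'
#' The 109 descriptor columns in schema order: `Volume`, the eight probe
#' totals (`CZ`, `CA`, `O`, `OD1`, `OG`, `N`, `NZ`, `DU`), the 80
#' probe-by-burial bins (`CZ40`, `CZ40.50`, ..., `DU120`; burial runs from
#' 40 = exposed to 120 = fully buried), the ten probe-aggregated burial
#' bins (`T40` ... `T120`), and the ten geometric shape descriptors
#' (`PMI1`, `PMI2`, `PMI3`, `NPR1`, `NPR2`, `Rgyr`, `Asphericity`,
#' `SpherocityIndex`, `Eccentricity`, `InertialShapeFactor`).
#'
#' @return Character vector of length 109.
#' @export
descriptor_names <- function() {
  bins <- as.vector(t(outer(probe_levels(), .burial_bin_labels, paste0)))
  c("Volume", probe_levels(), bins,
    paste0("T", .burial_bin_labels),
    c("PMI1", "PMI2", "PMI3", "NPR1", "NPR2", "Rgyr", "Asphericity",
      "SpherocityIndex", "Eccentricity", "InertialShapeFactor"))
}

.csv_id_cols <- c("pdb.chain", "Cavity")

#' Write a descriptor table in the published CSV schema
#'
#' Columns are `pdb.chain`, `Cavity` (the full pocket row identifier, see
#' [pocket_row_id()]), then the 109 descriptor columns of
#' [descriptor_names()].  Floats are written with six significant digits.
#'
#' @param table Data frame (or matrix with row names used as `Cavity`)
#'   containing all descriptor columns; a missing `pdb.chain` column is
#'   derived from the leading `<pdb>-<chain>` tokens of `Cavity`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_descriptor_csv <- function(table, path) {
  if (is.matrix(table)) {
    ids <- rownames(table)
    if (is.null(ids)) stop("matrix input needs row names as pocket IDs")
    table <- data.frame(Cavity = ids, as.data.frame(table),
                        check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (!"Cavity" %in% names(table)) stop("missing mandatory column: Cavity")
  if (!"pdb.chain" %in% names(table)) {
    tok <- strsplit(table$Cavity, "-")
    table$`pdb.chain` <- vapply(tok, function(t)
      paste(t[seq_len(min(2L, length(t)))], collapse = "-"), character(1L))
  }
  missing_cols <- setdiff(descriptor_names(), names(table))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  out <- table[, c(.csv_id_cols, descriptor_names())]
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], signif, digits = 6L)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a descriptor CSV written by [write_descriptor_csv()]
#'
#' @param path CSV path.
#' @return Data frame with `pdb.chain`, `Cavity` and the descriptor
#'   columns; row names set to `Cavity`.
#' @export
read_descriptor_csv <- function(path) {
  out <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(.csv_id_cols, descriptor_names()), names(out))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  rownames(out) <- out$Cavity
  out
}

#' Numeric descriptor matrix from a descriptor table
#'
#' @param table Data frame as returned by [read_descriptor_csv()].
#' @return Numeric matrix (pockets x 109) with pocket IDs as row names.
#' @export
descriptor_matrix <- function(table) {
  m <- as.matrix(table[, descriptor_names()])
  rownames(m) <- table$Cavity
  m
}
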