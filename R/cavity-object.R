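#' Pharmacophoric probe vocabulary
#'
#' Probe labels inherited from the nearest protein heavy atom: `CA`
#' hydrophobic, `CZ` aromatic, `O` hydrogen-bond acceptor, `OD1` anionic
#' acceptor, `OG` donor/acceptor, `N` donor, `NZ` cationic, `DU` dummy
#' (no protein atom within typing range).  The order given here is the
#' canonical column order of the descriptor schema.
#'
#' @return Character vector of the eight probe labels.
#' @export
probe_levels <- function() c("CZ", "CA", "O", "OD1", "OG", "N", "NZ", "DU")

#' Construct a cavity (pocket negative image)
#'
#' A cavity is one 26-connected component of retained grid points, each
#' carrying a buriedness count and (after typing) a pharmacophoric probe
#' label.  Volume is the point count times the grid-cell volume.
#'
#' @param points Data frame with columns `x`, `y`, `z` and optionally
#'   `buriedness` (integer ray count) and `probe` (see [probe_levels()]).
#' @param cavity_id Identifier of the form `"CAVITY_N<k>"`.
#' @param step Grid spacing in Angstrom (default 1).
#' @param source Free-text provenance tag (e.g. `"HD"` or `"PL"`).
#' @return An object of class `cavity`.
#' @export
cavity <- function(points, cavity_id = "CAVITY_N1", step = 1, source = NA_character_) {
  stopifnot(is.data.frame(points))
  if (!nrow(points)) stop("a cavity must contain at least one point")
  need <- c("x", "y", "z")
  if (!all(need %in% names(points)))
    stop("cavity points need columns x, y, z")
  if (is.null(points$buriedness)) points$buriedness <- NA_integer_
  if (is.null(points$probe)) points$probe <- NA_character_
  bad <- !is.na(points$probe) & !(points$probe %in% probe_levels())
  if (any(bad))
    stop("unknown probe label(s): ", paste(unique(points$probe[bad]), collapse = ", "))
  if (!grepl("^CAVITY_N[0-9]+$", cavity_id))
    stop("cavity_id must match 'CAVITY_N<k>'")
  out <- list(cavity_id = cavity_id,
              points = points[, c("x", "y", "z", "buriedness", "probe")],
              step = step,
              volume = nrow(points) * step^3,
              source = source)
  class(out) <- "cavity"
  out
}

#' @export
print.cavity <- function(x, ...) {
  cat(sprintf("cavity %s: %d points, volume %.1f A^3 (step %.2f A)\n",
              x$cavity_id, nrow(x$points), x$volume, x$step))
  if (!all(is.na(x$points$probe))) {
    tab <- table(factor(x$points$probe, levels = probe_levels()))
    cat("  probes:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' Cavity centroid
#'
#' @param cav A [cavity()].
#' @return Numeric length-3 vector (x, y, z).
#' @export
cavity_centroid <- function(cav) {
  stopifnot(inherits(cav, "cavity"))
  colMeans(.xyz(cav$points))
}

#' Solvent exposure of a cavity
#'
#' Fraction of cavity points with buriedness at or below `cutoff` rays.
#' This is a toolkit definition: low buriedness means rays escape to bulk
#' solvent, so a high fraction marks an exposed, shallow pocket.
#'
#' @param cav A [cavity()] with buriedness assigned.
#' @param cutoff Buriedness cutoff (default 60 of 120 rays).
#' @return Proportion in `[0, 1]`.
#' @export
cavity_exposure <- function(cav, cutoff = 60) {
  stopifnot(inherits(cav, "cavity"))
  b <- cav$points$buriedness
  if (all(is.na(b))) stop("cavity has no buriedness values")
  mean(b <= cutoff, na.rm = TRUE)
}
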