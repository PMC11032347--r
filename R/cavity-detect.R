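#' Cavity detection parameters
#'
#' Grid and filtering parameters for pocket detection.  The defaults are
#' tuned for the shallow pockets typical of protein-protein interfaces:
#' grid spacing `step` 1 A, main box edge `boxS` 20 A, minimal buriedness
#' `b` 65 (of `n_rays` cast rays), minimal retained 26-neighbours `n` 12,
#' and minimal cavity size `nPTS` 20 points.  `n_rays` is 120 so that the
#' burial scale runs from about 40 (exposed) to 120 (fully buried);
#' `ray_range` (8 A) bounds the ray-cast and the bulk-solvent prune, and
#' `clash_distance` (2.5 A) removes grid points overlapping protein atoms.
#'
#' @param step Grid spacing in Angstrom.
#' @param boxS Edge length of the search box in Angstrom.
#' @param b Minimal buriedness (blocked-ray count) to retain a point.
#' @param n Minimal number of retained 26-neighbours.
#' @param nPTS Minimal number of points for a component to count as a cavity.
#' @param n_rays Number of ray directions (deterministic Fibonacci set).
#' @param ray_range Maximal ray length / bulk-solvent distance, Angstrom.
#' @param clash_distance Protein-clash prune distance, Angstrom.
#' @return A list of class `cavity_params`.
#' @export
cavity_params <- function(step = 1, boxS = 20, b = 65, n = 12, nPTS = 20,
                          n_rays = 120, ray_range = 8, clash_distance = 2.5) {
  stopifnot(step > 0, boxS >= step, b >= 0, b <= n_rays,
            n >= 0, n <= 26, nPTS >= 1, n_rays >= 1,
            ray_range > 0, clash_distance >= 0)
  out <- list(step = step, boxS = boxS, b = b, n = n, nPTS = nPTS,
              n_rays = n_rays, ray_range = ray_range,
              clash_distance = clash_distance)
  class(out) <- "cavity_params"
  out
}

#' Deterministic near-uniform ray directions
#'
#' Spherical Fibonacci lattice of `n` unit vectors; fixed (no randomness)
#' so buriedness is reproducible across runs and platforms.
#'
#' @param n Number of directions.
#' @return `n x 3` matrix of unit vectors.
#' @export
fibonacci_directions <- function(n = 120) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

.vdw_table <- c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, B = 1.92)

#' Van der Waals radius by element
#'
#' Bondi-style radii; unknown elements default to 1.7 A.
#'
#' @param elements Character vector of element symbols.
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(elements) {
  r <- .vdw_table[toupper(elements)]
  r[is.na(r)] <- 1.7
  unname(r)
}

#' Build the candidate grid around a reference
#'
#' Lays a cubic lattice of spacing `step` inside a `boxS`-edged cube
#' centred on the centroid of the reference atoms (the bound ligand for a
#' monomer, the partner chain for a heterodimer), then removes points
#' clashing with target heavy atoms (within `clash_distance`) and points
#' in bulk solvent (farther than `ray_range` from every target atom).
#'
#' @param target_atoms Heavy-atom data frame of the chain being probed.
#' @param reference_atoms Heavy-atom data frame of the reference.
#' @param params A [cavity_params()].
#' @return Data frame of candidate points with lattice indices
#'   (`ix`, `iy`, `iz`) and coordinates.
#' @export
build_grid <- function(target_atoms, reference_atoms, params = cavity_params()) {
  if (!nrow(reference_atoms)) stop("empty reference atom set")
  centre <- colMeans(.xyz(reference_atoms))
  half <- params$boxS / 2
  offs <- seq(-half, half, by = params$step)
  idx <- seq_along(offs) - 1L
  g <- expand.grid(ix = idx, iy = idx, iz = idx, KEEP.OUT.ATTRS = FALSE)
  g$x <- centre[1L] + offs[g$ix + 1L]
  g$y <- centre[2L] + offs[g$iy + 1L]
  g$z <- centre[3L] + offs[g$iz + 1L]
  if (nrow(target_atoms)) {
    dmin <- sqrt(.min_dist2(cbind(g$x, g$y, g$z), .xyz(target_atoms)))
    keep <- dmin > params$clash_distance & dmin <= params$ray_range
    g <- g[keep, , drop = FALSE]
  } else {
    g <- g[0L, , drop = FALSE]
  }
  rownames(g) <- NULL
  g
}

#' Ray-cast buriedness of grid points
#'
#' For each point, counts how many of the `n_rays` fixed directions hit a
#' target heavy atom (sphere of its van der Waals radius) within
#' `ray_range`.  A fully enclosed point scores `n_rays`; a point in open
#' solvent scores 0.
#'
#' @param points Data frame (or matrix) of point coordinates `x`, `y`, `z`.
#' @param target_atoms Heavy-atom data frame with `elesy` for radii.
#' @param params A [cavity_params()].
#' @return Integer vector of blocked-ray counts, one per point.
#' @export
buriedness <- function(points, target_atoms, params = cavity_params()) {
  p <- if (is.data.frame(points)) .xyz(points) else as.matrix(points)
  np <- nrow(p)
  if (!np) return(integer(0))
  if (!nrow(target_atoms)) return(integer(np))
  .raycast_counts(p, .xyz(target_atoms), vdw_radius(target_atoms$elesy),
                  fibonacci_directions(params$n_rays), params$ray_range)
}

# integer lattice keys for 26-neighbourhood bookkeeping
.lattice_keys <- function(ix, iy, iz, base) {
  (ix + 1L) + base * ((iy + 1L) + base * (iz + 1L))
}

.neighbor_offsets <- local({
  o <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  o[!(o$dx == 0L & o$dy == 0L & o$dz == 0L), ]
})

#' Cluster retained grid points into cavities
#'
#' Applies the buriedness threshold `b`, iteratively erodes points with
#' fewer than `n` retained 26-neighbours until stable, splits survivors
#' into 26-connected components, discards components smaller than `nPTS`
#' points, and ranks the rest by size (descending) as `CAVITY_N1`,
#' `CAVITY_N2`, ...  Size ties are broken by lower centroid x, then y,
#' then z so identifiers are reproducible.
#'
#' @param candidates Grid data frame from [build_grid()] with a
#'   `buriedness` column.
#' @param params A [cavity_params()].
#' @param source Provenance tag stored on each cavity.
#' @return List of [cavity()] objects (possibly empty).
#' @export
detect_cavities <- function(candidates, params = cavity_params(),
                            source = NA_character_) {
  g <- candidates[!is.na(candidates$buriedness) &
                    candidates$buriedness >= params$b, , drop = FALSE]
  if (!nrow(g)) return(list())
  base <- max(g$ix, g$iy, g$iz) + 3L
  repeat {
    keys <- .lattice_keys(g$ix, g$iy, g$iz, base)
    nn <- integer(nrow(g))
    for (j in seq_len(nrow(.neighbor_offsets))) {
      off <- .neighbor_offsets[j, ]
      nk <- .lattice_keys(g$ix + off$dx, g$iy + off$dy, g$iz + off$dz, base)
      nn <- nn + (nk %in% keys)
    }
    keep <- nn >= params$n
    if (all(keep)) break
    g <- g[keep, , drop = FALSE]
    if (!nrow(g)) return(list())
  }
  # 26-connected components
  keys <- .lattice_keys(g$ix, g$iy, g$iz, base)
  edges <- NULL
  for (j in seq_len(nrow(.neighbor_offsets))) {
    off <- .neighbor_offsets[j, ]
    nk <- .lattice_keys(g$ix + off$dx, g$iy + off$dy, g$iz + off$dz, base)
    hit <- match(nk, keys)
    src <- which(!is.na(hit))
    if (length(src))
      edges <- rbind(edges, cbind(src, hit[src]))
  }
  if (is.null(edges)) {
    comp <- seq_len(nrow(g))
  } else {
    gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0L, nrow(g) - igraph::vcount(gr)))
    comp <- igraph::components(gr)$membership[seq_len(nrow(g))]
  }
  parts <- split(seq_len(nrow(g)), comp)
  parts <- parts[lengths(parts) >= params$nPTS]
  if (!length(parts)) return(list())
  cen <- t(vapply(parts, function(idx)
    colMeans(cbind(g$x[idx], g$y[idx], g$z[idx])), numeric(3L)))
  ord <- order(-lengths(parts), cen[, 1L], cen[, 2L], cen[, 3L])
  parts <- parts[ord]
  lapply(seq_along(parts), function(k) {
    idx <- parts[[k]]
    cavity(data.frame(x = g$x[idx], y = g$y[idx], z = g$z[idx],
                      buriedness = as.integer(g$buriedness[idx]),
                      probe = NA_character_, stringsAsFactors = FALSE),
           cavity_id = sprintf("CAVITY_N%d", k),
           step = params$step, source = source)
  })
}

#' Assign pharmacophoric probes to cavity points
#'
#' Each point inherits the pharmacophore of its nearest target heavy atom
#' within `max_dist`: hydrophobic carbons map to `CA`, aromatic ring
#' carbons to `CZ`, H-bond acceptors to `O`, anionic acceptors to `OD1`,
#' donor/acceptor hydroxyls to `OG`, donors to `N`, cationic nitrogens to
#' `NZ`.  Points with no atom within range, or whose nearest atom has no
#' table entry (a warning is issued), become dummy `DU` points.
#'
#' @param cav A [cavity()].
#' @param target_atoms Heavy-atom data frame of the probed chain.
#' @param max_dist Typing range in Angstrom (default 4).
#' @return The cavity with its `probe` column filled.
#' @export
assign_probes <- function(cav, target_atoms, max_dist = 4.0) {
  stopifnot(inherits(cav, "cavity"))
  if (!nrow(target_atoms)) {
    cav$points$probe <- "DU"
    return(cav)
  }
  d2 <- .dist2_xyz(.xyz(cav$points), .xyz(target_atoms))
  nearest <- max.col(-d2, ties.method = "first")
  dmin <- sqrt(d2[cbind(seq_len(nrow(d2)), nearest)])
  probes <- .atom_pharmacophore(target_atoms$resid[nearest],
                                target_atoms$elety[nearest],
                                target_atoms$elesy[nearest])
  probes[dmin > max_dist] <- "DU"
  cav$points$probe <- probes
  cav
}

# residue/atom-name pharmacophore table
.atom_pharmacophore <- function(resid, elety, elesy) {
  resid <- toupper(resid); elety <- toupper(elety); elesy <- toupper(elesy)
  n <- length(resid)
  out <- rep(NA_character_, n)
  aromatic <- (resid == "PHE" & elety %in% c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")) |
    (resid == "TYR" & elety %in% c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")) |
    (resid == "TRP" & elety %in% c("CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")) |
    (resid == "HIS" & elety %in% c("CG", "CD2", "CE1"))
  anionic <- (resid == "ASP" & elety %in% c("OD1", "OD2")) |
    (resid == "GLU" & elety %in% c("OE1", "OE2")) |
    elety == "OXT"
  donor_acceptor <- (resid == "SER" & elety == "OG") |
    (resid == "THR" & elety == "OG1") |
    (resid == "TYR" & elety == "OH")
  cationic <- (resid == "LYS" & elety == "NZ") |
    (resid == "ARG" & elety %in% c("NE", "NH1", "NH2"))
  out[elesy == "C"] <- "CA"                       # default carbon: hydrophobic
  out[elesy == "S"] <- "CA"                       # thioether/thiol: hydrophobic
  out[elesy == "N"] <- "N"                        # default nitrogen: donor
  out[elesy == "O"] <- "O"                        # default oxygen: acceptor
  out[aromatic] <- "CZ"
  out[anionic] <- "OD1"
  out[donor_acceptor] <- "OG"
  out[cationic] <- "NZ"
  unknown <- is.na(out)
  if (any(unknown)) {
    warning("no pharmacophore for atom type(s): ",
            paste(unique(paste(resid[unknown], elety[unknown])), collapse = ", "),
            "; using DU")
    out[unknown] <- "DU"
  }
  out
}

#' Detect and type pockets on one chain of an entry
#'
#' End-to-end driver: extracts the target chain's heavy atoms, builds the
#' grid around the reference (partner chain in heterodimer mode, bound
#' ligand in monomer mode), scores buriedness, clusters cavities and
#' assigns probes.
#'
#' @param entry A [structure_entry()].
#' @param target_chain Chain to probe for pockets.
#' @param reference_chain Partner chain used as grid reference
#'   (heterodimer mode); mutually exclusive with `ligand`.
#' @param ligand A [ligand_record()] used as grid reference (monomer mode).
#' @param params A [cavity_params()].
#' @return List of typed [cavity()] objects, ranked `CAVITY_N1`, ...
#' @export
detect_pockets <- function(entry, target_chain, reference_chain = NULL,
                           ligand = NULL, params = cavity_params()) {
  stopifnot(inherits(entry, "structure_entry"))
  if (is.null(reference_chain) == is.null(ligand))
    stop("give exactly one of 'reference_chain' or 'ligand'")
  target <- chain_atoms(entry, target_chain)
  if (!nrow(target)) stop("target chain '", target_chain, "' has no heavy atoms")
  if (!is.null(reference_chain)) {
    ref <- chain_atoms(entry, reference_chain)
    src <- "HD"
  } else {
    ref <- ligand_heavy_atoms(ligand)
    src <- "PL"
  }
  if (!nrow(ref)) stop("reference has no heavy atoms")
  g <- build_grid(target, ref, params)
  if (!nrow(g)) return(list())
  g$buriedness <- buriedness(g, target, params)
  cavs <- detect_cavities(g, params, source = src)
  lapply(cavs, assign_probes, target_atoms = target)
}
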