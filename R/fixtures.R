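# run expr with a temporary RNG seed, restoring global RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Toy heterodimer specification
#'
#' Controls the synthetic complex used to exercise the pipeline: a
#' concave pocket of radius `pocket_radius` on chain A, capped by a
#' convex chain-B plug, plus a second, partner-free pocket on the far
#' side of the chain (for allosteric-classification fixtures).
#'
#' @param pocket_radius Inner pocket radius in Angstrom.
#' @param wall_thickness Shell wall thickness in Angstrom (must be below
#'   `pocket_radius`).
#' @param ligand_offset Target minimum distance (Angstrom) between the
#'   toy ligand and the partner epitope in [make_toy_liganded()].
#' @param n_wall_atoms Fibonacci lattice size per shell layer (>= 50).
#' @param seed Integer seed; identical specs give identical coordinates.
#' @return A list of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(pocket_radius = 6, wall_thickness = 3,
                             ligand_offset = 1, n_wall_atoms = 250L,
                             seed = 1L) {
  if (pocket_radius <= 0) stop("'pocket_radius' must be positive")
  if (wall_thickness >= pocket_radius)
    stop("geometrically infeasible spec: wall_thickness >= pocket_radius")
  if (n_wall_atoms < 50L) stop("'n_wall_atoms' must be at least 50")
  if (ligand_offset < 0) stop("'ligand_offset' must be non-negative")
  out <- list(pocket_radius = pocket_radius, wall_thickness = wall_thickness,
              ligand_offset = ligand_offset,
              n_wall_atoms = as.integer(n_wall_atoms), seed = as.integer(seed))
  class(out) <- "toy_complex_spec"
  out
}

# internal geometry shared by the toy generators
.toy_geometry <- function(spec) {
  rc <- spec$pocket_radius + 1.7          # shell atom-centre radius
  list(rc = rc,
       cap = 0.45,                        # shell covers z_unit <= cap
       layer_gap = min(spec$wall_thickness / 2, 1.6),
       plug_z = 0.45 * rc + 0.6,          # bottom plug layer height
       plug_gap = 1.5,
       plug_radius = 0.75 * rc,
       far_centre = c(max(3.5 * spec$pocket_radius, 20), 0, 0))
}

# bowl of shell atoms: Fibonacci sphere layers, keeping z_unit <= cap
.toy_bowl <- function(centre, geom, n, jitter_sd) {
  pts <- NULL
  for (layer in 0:1) {
    r <- geom$rc + layer * geom$layer_gap
    f <- fibonacci_directions(n)
    keep <- f[, 3L] <= geom$cap
    p <- f[keep, , drop = FALSE] * r
    # offset the outer layer so it covers the gaps of the inner one
    if (layer == 1L) p <- p %*% .rot_z(pi / n)
    pts <- rbind(pts, p)
  }
  pts <- pts + matrix(stats::rnorm(length(pts), sd = jitter_sd), ncol = 3L)
  sweep(pts, 2L, centre, "+")
}

.rot_z <- function(a) {
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L, 3L)
}

# sunflower-packed disk of atoms (plug layer)
.toy_disk <- function(centre, radius, n) {
  i <- seq_len(n)
  r <- radius * sqrt(i / n)
  th <- i * pi * (3 - sqrt(5))
  cbind(centre[1L] + r * cos(th), centre[2L] + r * sin(th),
        rep(centre[3L], n))
}

.toy_atoms <- function(xyz, chain, start_eleno = 1L, start_resno = 1L,
                       hetero = FALSE, resid = "ALA", elety = "CA") {
  n <- nrow(xyz)
  data.frame(eleno = start_eleno + seq_len(n) - 1L,
             elety = elety, alt = "",
             resid = resid, chain = chain,
             resno = start_resno + (if (hetero) 0L else seq_len(n) - 1L),
             x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
             elesy = "C", hetero = hetero, stringsAsFactors = FALSE)
}

#' Generate a toy heterodimer
#'
#' Chain A is a double-layer hemispherical shell of carbon pseudo-atoms
#' (one residue per atom, residue name ALA) forming a concave pocket of
#' the requested radius around the origin, plus an identical partner-free
#' bowl on the far side of the chain.  Chain B is a sunflower-packed
#' two-layer plug seated over the main pocket mouth, within contact
#' distance of the rim.  The chains carry distinct synthetic UniProt
#' accessions (`TOYA01` / `TOYB01`).  Coordinates are a pure function of
#' the spec (a small seeded jitter breaks lattice symmetry).
#'
#' @param spec A [toy_complex_spec()].
#' @return A [structure_entry()] with chains A and B.
#' @export
make_toy_heterodimer <- function(spec = toy_complex_spec()) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  geom <- .toy_geometry(spec)
  .with_seed(spec$seed, {
    bowl_main <- .toy_bowl(c(0, 0, 0), geom, spec$n_wall_atoms, 0.02)
    bowl_far <- .toy_bowl(geom$far_centre, geom, spec$n_wall_atoms, 0.02)
    plug <- rbind(
      .toy_disk(c(0, 0, geom$plug_z), geom$plug_radius, 80L),
      .toy_disk(c(0, 0, geom$plug_z + geom$plug_gap), geom$plug_radius, 60L))
    a_xyz <- rbind(bowl_main, bowl_far)
    atoms <- rbind(
      .toy_atoms(a_xyz, "A"),
      .toy_atoms(plug, "B", start_eleno = nrow(a_xyz) + 1L))
    structure_entry(sprintf("toy%d", spec$seed %% 10000L), atoms,
                    method = "XRAY", resolution = 2.0,
                    r_free_minus_r_factor = 0.03,
                    uniprot = c(A = "TOYA01", B = "TOYB01"))
  })
}

#' Generate a toy liganded monomer
#'
#' Copies chain A of a toy heterodimer and adds a rigid six-carbon ring
#' ligand (HET code `LIG`).  With `placement = "pocket"` the ring is slid
#' along the main pocket axis until its minimum heavy-atom distance to
#' the partner-epitope positions (chain B of `partner`) equals
#' `spec$ligand_offset` to within 0.05 A.  With `placement = "far"` the
#' ring is seated deep in the partner-free far pocket, where the
#' enclosing cavity fails the orthosteric test.
#'
#' @param spec A [toy_complex_spec()].
#' @param partner Heterodimer from [make_toy_heterodimer()] (same spec).
#' @param placement `"pocket"` (default) or `"far"`.
#' @return A [structure_entry()] with protein chain A and one ligand.
#' @export
make_toy_liganded <- function(spec, partner = make_toy_heterodimer(spec),
                              placement = c("pocket", "far")) {
  stopifnot(inherits(spec, "toy_complex_spec"),
            inherits(partner, "structure_entry"))
  placement <- match.arg(placement)
  geom <- .toy_geometry(spec)
  prot <- partner$atoms[partner$atoms$chain == "A", , drop = FALSE]
  epitope <- .xyz(partner$atoms[partner$atoms$chain == "B", , drop = FALSE])
  ring0 <- cbind(1.4 * cos(2 * pi * (0:5) / 6), 1.4 * sin(2 * pi * (0:5) / 6), 0)
  ring_at <- function(centre) sweep(ring0, 2L, centre, "+")
  if (placement == "pocket") {
    mind <- function(z0) sqrt(min(.dist2_xyz(ring_at(c(0, 0, z0)), epitope)))
    lo <- -spec$pocket_radius * 0.8
    hi <- geom$plug_z - 0.05
    if (mind(lo) < spec$ligand_offset)
      stop("pocket too small for the requested ligand offset")
    # min epitope distance decreases monotonically as the ring rises
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (mind(mid) > spec$ligand_offset) lo <- mid else hi <- mid
    }
    centre <- c(0, 0, lo)
  } else {
    centre <- geom$far_centre + c(0, 0, -1)
  }
  lig_xyz <- ring_at(centre)
  lig <- .toy_atoms(lig_xyz, chain = "A",
                    start_eleno = max(prot$eleno) + 1L,
                    start_resno = 900L, hetero = TRUE, resid = "LIG")
  lig$elety <- paste0("C", seq_len(6L))
  structure_entry(paste0(partner$entry_id, "l"), rbind(prot, lig),
                  method = "XRAY", resolution = 2.0,
                  r_free_minus_r_factor = 0.03,
                  uniprot = c(A = "TOYA01"))
}

#' Descriptor sample specification
#'
#' @param n_pockets Number of rows (pockets).
#' @param n_descriptors Number of descriptor columns.
#' @param n_clusters Number of planted Gaussian clusters (>= 1).
#' @param cluster_separation Pairwise distance between cluster centres,
#'   in the (z-scored) descriptor units.
#' @param noise_sd Per-coordinate Gaussian noise standard deviation.
#' @param zero_fraction_per_column Numeric vector of proportions (one per
#'   leading column, or named by column name `D<j>`): the exact fraction
#'   of rows forced to zero in that column.
#' @param seed Integer seed.
#' @return A list of class `descriptor_sample_spec`.
#' @export
descriptor_sample_spec <- function(n_pockets = 60L, n_descriptors = 10L,
                                   n_clusters = 2L, cluster_separation = 6,
                                   noise_sd = 1,
                                   zero_fraction_per_column = numeric(),
                                   seed = 1L) {
  if (n_clusters < 1L) stop("'n_clusters' must be >= 1")
  if (cluster_separation < 0) stop("'cluster_separation' must be >= 0")
  if (n_descriptors < n_clusters)
    stop("'n_descriptors' must be >= 'n_clusters'")
  zf <- zero_fraction_per_column
  if (length(zf) && (any(zf < 0) || any(zf > 1)))
    stop("zero fractions must be proportions in [0, 1]")
  out <- list(n_pockets = as.integer(n_pockets),
              n_descriptors = as.integer(n_descriptors),
              n_clusters = as.integer(n_clusters),
              cluster_separation = cluster_separation,
              noise_sd = noise_sd,
              zero_fraction_per_column = zf,
              seed = as.integer(seed))
  class(out) <- "descriptor_sample_spec"
  out
}

#' Generate a planted-cluster descriptor sample
#'
#' Gaussian clusters whose centres sit pairwise `cluster_separation`
#' apart (scaled coordinate axes), with isotropic noise of standard
#' deviation `noise_sd`; selected columns are then forced to zero in the
#' exact stated fraction of rows (rows chosen by the seed).  Column `j`
#' is named `D<j>`, rows `toy_pocket_<i>`.
#'
#' @param spec A [descriptor_sample_spec()].
#' @return List with `matrix` (n_pockets x n_descriptors) and integer
#'   `labels` (true cluster of each row).
#' @export
make_descriptor_sample <- function(spec = descriptor_sample_spec()) {
  stopifnot(inherits(spec, "descriptor_sample_spec"))
  .with_seed(spec$seed, {
    n <- spec$n_pockets; d <- spec$n_descriptors; k <- spec$n_clusters
    centres <- matrix(0, k, d)
    if (k > 1L)
      centres[cbind(seq_len(k), seq_len(k))] <- spec$cluster_separation / sqrt(2)
    labels <- rep(seq_len(k), length.out = n)
    m <- centres[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * d, sd = spec$noise_sd), n, d)
    colnames(m) <- paste0("D", seq_len(d))
    rownames(m) <- paste0("toy_pocket_", seq_len(n))
    zf <- spec$zero_fraction_per_column
    if (length(zf)) {
      cols <- if (!is.null(names(zf))) match(names(zf), colnames(m))
      else seq_along(zf)
      if (any(is.na(cols))) stop("unknown column in zero_fraction_per_column")
      for (jj in seq_along(zf)) {
        nz <- round(zf[[jj]] * n)
        if (nz > 0L) m[sample.int(n, nz), cols[jj]] <- 0
      }
    }
    list(matrix = m, labels = labels)
  })
}
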