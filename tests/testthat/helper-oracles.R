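# Independent brute-force oracles, deliberately written with plain loops
# and textbook formulas so they share no code with the implementation.

# ray-sphere blocking count for one point: loop over rays and atoms
oracle_raycast <- function(point, atoms_xyz, radii, dirs, range) {
  blocked <- 0L
  for (k in seq_len(nrow(dirs))) {
    u <- dirs[k, ]
    hit <- FALSE
    for (a in seq_len(nrow(atoms_xyz))) {
      v <- atoms_xyz[a, ] - point
      t <- sum(v * u)
      if (t <= 0) next
      b2 <- sum(v * v) - t^2
      if (b2 > radii[a]^2) next
      if (t - sqrt(radii[a]^2 - b2) <= range) { hit <- TRUE; break }
    }
    if (hit) blocked <- blocked + 1L
  }
  blocked
}

# textbook shape descriptors with explicit accumulation loops
oracle_geometric <- function(pts) {
  n <- nrow(pts)
  cen <- colMeans(pts)
  I <- matrix(0, 3, 3)
  S <- matrix(0, 3, 3)
  sum_r2 <- 0
  for (i in seq_len(n)) {
    r <- as.numeric(pts[i, ]) - cen
    sum_r2 <- sum_r2 + sum(r^2)
    I <- I + (sum(r^2) * diag(3) - outer(r, r))
    S <- S + outer(r, r) / n
  }
  pm <- sort(eigen(I, symmetric = TRUE)$values)
  tv <- sort(eigen(S, symmetric = TRUE)$values, decreasing = TRUE)
  c(PMI1 = pm[1], PMI2 = pm[2], PMI3 = pm[3],
    NPR1 = pm[1] / pm[3], NPR2 = pm[2] / pm[3],
    Rgyr = sqrt(sum_r2 / n),
    Asphericity = 0.5 * ((tv[1] - tv[2])^2 + (tv[2] - tv[3])^2 +
                           (tv[3] - tv[1])^2) / sum(tv)^2,
    SpherocityIndex = 3 * tv[3] / sum(tv),
    Eccentricity = sqrt(pm[3]^2 - pm[1]^2) / pm[3],
    InertialShapeFactor = pm[2] / (pm[1] * pm[3]))
}

# all labelled trees on n nodes via Pruefer sequences -> edge index list
oracle_all_trees <- function(n) {
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  lapply(seq_len(nrow(seqs)), function(i) {
    s <- seqs[i, ]
    deg <- rep(1L, n)
    for (x in s) deg[x] <- deg[x] + 1L
    edges <- matrix(0L, n - 1L, 2L)
    for (k in seq_along(s)) {
      leaf <- which(deg == 1L)[1L]
      edges[k, ] <- c(leaf, s[k])
      deg[leaf] <- 0L
      deg[s[k]] <- deg[s[k]] - 1L
    }
    edges[n - 1L, ] <- which(deg == 1L)
    edges
  })
}

# minimum spanning weight by exhaustive enumeration over all trees
oracle_min_spanning_weight <- function(d, trees = oracle_all_trees(nrow(d))) {
  min(vapply(trees, function(e) sum(d[e]), numeric(1L)))
}

# random symmetric distance matrix with zero diagonal
random_distance_matrix <- function(n, seed) {
  set.seed(seed)
  pts <- matrix(runif(n * 3, 0, 10), n)
  as.matrix(dist(pts))
}

# synthetic cavity on a lattice with random buriedness and probes
random_cavity <- function(seed, n_min = 25L, n_max = 120L, step = 1) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1L)
  # distinct lattice sites inside a 10-cube
  key <- sample.int(11L^3, n)
  iz <- (key - 1L) %/% 121L; rem <- (key - 1L) %% 121L
  pts <- data.frame(x = rem %% 11L * step, y = rem %/% 11L * step,
                    z = iz * step,
                    buriedness = sample(0:120, n, replace = TRUE),
                    probe = sample(probe_levels(), n, replace = TRUE),
                    stringsAsFactors = FALSE)
  cavity(pts, "CAVITY_N1", step = step)
}

# small two-chain entry from explicit coordinates
toy_entry <- function(a_xyz, b_xyz = NULL, entry_id = "tst1",
                      uniprot = c(A = "P00001", B = "P00002"), ...) {
  mk <- function(xyz, chain, off) {
    n <- nrow(xyz)
    data.frame(eleno = off + seq_len(n), elety = "CA", alt = "",
               resid = "ALA", chain = chain, resno = seq_len(n),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               elesy = "C", hetero = FALSE, stringsAsFactors = FALSE)
  }
  atoms <- mk(a_xyz, "A", 0L)
  if (!is.null(b_xyz)) atoms <- rbind(atoms, mk(b_xyz, "B", nrow(a_xyz)))
  structure_entry(entry_id, atoms, uniprot = uniprot, ...)
}

# metadata-only entry (single dummy atom) for curation tests
meta_entry <- function(id, method = "XRAY", resolution = 2.0,
                       dr = 0.03, fsc = NA_real_) {
  e <- toy_entry(matrix(c(0, 0, 0), 1), entry_id = id,
                 uniprot = c(A = "P00001"))
  e$method <- method
  e$resolution <- resolution
  e$r_free_minus_r_factor <- dr
  e$fsc <- fsc
  e
}

# quick ligand record from coordinates
toy_ligand <- function(xyz, het = "LIG", resno = 900L, elements = "C") {
  n <- nrow(xyz)
  atoms <- data.frame(eleno = seq_len(n), elety = paste0("C", seq_len(n)),
                      alt = "", resid = het, chain = "A", resno = resno,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      elesy = rep_len(elements, n), hetero = TRUE,
                      stringsAsFactors = FALSE)
  ligand_record(het, resno, "A", atoms)
}

# wrap a plain symmetric matrix as a distance_matrix object
mst_from_matrix <- function(d) {
  ids <- rownames(d)
  if (is.null(ids)) dimnames(d) <- list(paste0("p", seq_len(nrow(d))),
                                        paste0("p", seq_len(nrow(d))))
  v <- d[lower.tri(d)]
  dm <- list(pocket_ids = rownames(d), d = d,
             sigma = if (length(v) == 1L) v else sqrt(mean((v - mean(v))^2)))
  class(dm) <- "distance_matrix"
  dm
}

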