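#' Pairwise Euclidean distances in descriptor space
#'
#' Computes the full N x N Euclidean distance matrix over standardized
#' descriptor rows, together with `sigma`, the population standard
#' deviation of the distances over the N(N-1)/2 unordered off-diagonal
#' pairs (the kernel bandwidth of the PSI).  With a single pair (N = 2)
#' the spread of one value is zero, so `sigma` degenerates to that single
#' distance.
#'
#' @param m Numeric matrix (pockets x descriptors), N >= 2 rows; row
#'   names are used as pocket IDs.
#' @return List of class `distance_matrix` with `pocket_ids`, `d`
#'   (symmetric matrix, zero diagonal) and `sigma`.
#' @export
pairwise_distances <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 pockets")
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("pocket", seq_len(nrow(m)))
  d <- as.matrix(stats::dist(m))
  dimnames(d) <- list(ids, ids)
  v <- d[lower.tri(d)]
  sigma <- if (length(v) == 1L) v else sqrt(mean((v - mean(v))^2))
  out <- list(pocket_ids = ids, d = d, sigma = sigma)
  class(out) <- "distance_matrix"
  out
}

#' Gaussian-kernel pocket similarity
#'
#' `PSI = exp(-d^2 / (2 sigma^2))`: distance 0 maps to similarity 1,
#' distance `sigma` to `exp(-1/2)`, distance `2 sigma` to `exp(-2)`.
#'
#' @param d Non-negative distance(s).
#' @param sigma Positive kernel bandwidth (standard deviation of the
#'   pairwise distances).
#' @return Similarity value(s) in `(0, 1]`.
#' @export
psi <- function(d, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a positive scalar")
  if (any(d < 0)) stop("distances must be non-negative")
  exp(-d^2 / (2 * sigma^2))
}

#' Pocket Similarity Index matrix
#'
#' Applies the Gaussian kernel elementwise to a distance matrix using its
#' own `sigma`; the diagonal is 1 by construction.
#'
#' @param dist A `distance_matrix` from [pairwise_distances()].
#' @return List of class `psi_matrix` with `pocket_ids`, `psi` and `sigma`.
#' @export
psi_matrix <- function(dist) {
  stopifnot(inherits(dist, "distance_matrix"))
  if (!is.finite(dist$sigma) || dist$sigma <= 0)
    stop("degenerate sigma (all pockets identical?): check the descriptor matrix")
  p <- psi(dist$d, dist$sigma)
  diag(p) <- 1
  out <- list(pocket_ids = dist$pocket_ids, psi = p, sigma = dist$sigma)
  class(out) <- "psi_matrix"
  out
}

#' Mean within- and between-group PSI
#'
#' Convenience summary for planted-cluster validation: averages the
#' off-diagonal PSI values over pairs sharing a label and pairs not
#' sharing one.
#'
#' @param psim A `psi_matrix`.
#' @param labels Vector of group labels, one per pocket.
#' @return Named numeric vector `c(within = ..., between = ...)`.
#' @export
psi_group_means <- function(psim, labels) {
  stopifnot(inherits(psim, "psi_matrix"))
  n <- length(psim$pocket_ids)
  if (length(labels) != n) stop("one label per pocket required")
  same <- outer(labels, labels, "==")
  lt <- lower.tri(same)
  c(within = mean(psim$psi[lt & same]),
    between = mean(psim$psi[lt & !same]))
}
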