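#' Burial bin label for a buriedness count
#'
#' Bins partition the burial scale: `"40"` collects buriedness <= 40
#' (exposed), `"x.y"` collects x < buriedness <= y in steps of 10, and
#' `"120"` collects only fully buried points (buriedness = 120).
#'
#' @param b Integer vector of buriedness counts (0..120).
#' @return Character vector of bin labels.
#' @export
burial_bin <- function(b) {
  out <- character(length(b))
  out[b <= 40] <- "40"
  out[b == 120] <- "120"
  mid <- b > 40 & b < 120
  lo <- 40 + 10 * pmin((b[mid] - 40 - 1) %/% 10, 7)
  out[mid] <- paste0(lo, ".", lo + 10)
  out
}

#' Probe/burial descriptor block (89 components)
#'
#' The pocket volume, the eight pharmacophoric probe totals, and the 80
#' probe-by-burial-bin counts, in the canonical order of
#' [descriptor_names()].
#'
#' @param cav A [cavity()] with buriedness and probes assigned.
#' @return Named numeric vector of length 89.
#' @export
volsite_descriptors <- function(cav) {
  stopifnot(inherits(cav, "cavity"))
  p <- cav$points
  if (any(is.na(p$probe))) stop("cavity has unassigned probes")
  if (any(is.na(p$buriedness))) stop("cavity has unassigned buriedness")
  pr <- factor(p$probe, levels = probe_levels())
  bn <- factor(burial_bin(p$buriedness), levels = .burial_bin_labels)
  totals <- as.vector(table(pr))
  grid_tab <- table(pr, bn)
  bins <- as.vector(t(grid_tab))     # probe-major, bin-minor
  out <- c(cav$volume, totals, bins)
  names(out) <- descriptor_names()[1:89]
  out
}

#' Probe-aggregated burial block (10 components)
#'
#' Amalgamates the probe-by-burial counts over the eight probe types: bin
#' `Tk` is the total number of pocket points in burial bin `k`
#' irrespective of probe polarity.
#'
#' @param block89 Named 89-vector from [volsite_descriptors()].
#' @return Named numeric vector of length 10 (`T40` ... `T120`).
#' @export
aggregate_descriptors <- function(block89) {
  if (length(block89) != 89L || !identical(names(block89), descriptor_names()[1:89]))
    stop("'block89' must be the named 89-component block")
  bins <- matrix(block89[10:89], nrow = length(probe_levels()), byrow = TRUE)
  out <- colSums(bins)
  names(out) <- paste0("T", .burial_bin_labels)
  out
}

#' Geometric shape descriptor block (10 components)
#'
#' Unit-mass shape descriptors of the cavity point cloud: principal
#' moments of inertia `PMI1 <= PMI2 <= PMI3` (eigenvalues of the inertia
#' tensor about the centroid), normalized ratios `NPR1 = PMI1/PMI3` and
#' `NPR2 = PMI2/PMI3`, radius of gyration (root mean squared centroid
#' distance), and, from the gyration (covariance) tensor eigenvalues
#' `t1 >= t2 >= t3`: asphericity
#' `((t1-t2)^2 + (t2-t3)^2 + (t3-t1)^2) / (2 (t1+t2+t3)^2)` and
#' spherocity index `3 t3 / (t1+t2+t3)`; plus molecular eccentricity
#' `sqrt(PMI3^2 - PMI1^2) / PMI3` and inertial shape factor
#' `PMI2 / (PMI1 * PMI3)`.
#'
#' For a degenerate (collinear) point set the eccentricity tends to its
#' rod limit 1, the spherocity to 0, and the inertial shape factor is
#' undefined (`NA`); a warning is issued.
#'
#' @param cav A [cavity()] or a data frame / matrix of point coordinates.
#' @return Named numeric vector of length 10.
#' @export
geometric_descriptors <- function(cav) {
  p <- if (inherits(cav, "cavity")) .xyz(cav$points) else as.matrix(cav)
  if (nrow(p) < 4L) stop("need at least 4 points for shape descriptors")
  cen <- colMeans(p)
  c0 <- sweep(p, 2L, cen)
  n <- nrow(c0)
  r2 <- rowSums(c0^2)
  # inertia tensor, unit masses
  I <- diag(sum(r2), 3L) - crossprod(c0)
  pm <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
  pm[pm < 0] <- 0
  # gyration tensor
  S <- crossprod(c0) / n
  tv <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  tv[tv < 0] <- 0
  rg <- sqrt(mean(r2))
  ts <- sum(tv)
  asph <- if (ts > 0)
    0.5 * ((tv[1] - tv[2])^2 + (tv[2] - tv[3])^2 + (tv[3] - tv[1])^2) / ts^2
  else 0
  spher <- if (ts > 0) 3 * tv[3] / ts else 0
  degenerate <- pm[1] <= 1e-10 * max(pm[3], 1)
  if (degenerate)
    warning("degenerate (collinear) point set: inertial shape factor undefined")
  ecc <- if (pm[3] > 0) sqrt(max(pm[3]^2 - pm[1]^2, 0)) / pm[3] else 0
  isf <- if (!degenerate && pm[1] > 0 && pm[3] > 0) pm[2] / (pm[1] * pm[3]) else NA_real_
  out <- c(pm[1], pm[2], pm[3],
           if (pm[3] > 0) pm[1] / pm[3] else 1,
           if (pm[3] > 0) pm[2] / pm[3] else 1,
           rg, asph, spher, ecc, isf)
  names(out) <- descriptor_names()[100:109]
  out
}

#' Full 109-component descriptor vector of a cavity
#'
#' @param cav A [cavity()] with buriedness and probes assigned.
#' @return Named numeric vector of length 109 in schema order.
#' @export
pocket_descriptors <- function(cav) {
  b89 <- volsite_descriptors(cav)
  out <- c(b89, aggregate_descriptors(b89), geometric_descriptors(cav))
  names(out) <- descriptor_names()
  out
}

#' Drop near-constant zero descriptor columns
#'
#' Discards every column whose value is zero for more than 95% of the
#' pockets (strictly more: a column zero in exactly 95% of rows is kept).
#'
#' @param m Numeric matrix (pockets x descriptors), >= 2 rows.
#' @param max_zero_fraction Threshold (default 0.95), strict.
#' @return List with `matrix` (kept columns), `kept_columns`,
#'   `zero_fractions` (all columns).
#' @export
filter_zero_columns <- function(m, max_zero_fraction = 0.95) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 pockets")
  zf <- colMeans(m == 0)
  keep <- zf <= max_zero_fraction
  if (!any(keep)) stop("all descriptor columns were dropped by the zero filter")
  list(matrix = m[, keep, drop = FALSE],
       kept_columns = colnames(m)[keep],
       zero_fractions = zf)
}

#' Conditionally rescale a skewed descriptor column to log scale
#'
#' A non-negative count-like column is replaced by `log(1 + x)` iff its
#' distribution is both high-dynamic-range and right-skewed: (i) mean
#' strictly below 15% of the maximum, and (ii) median strictly below 65%
#' of the mean.
#'
#' @param x Non-negative numeric vector with `max(x) > 0`.
#' @return List with `values` and logical `flag`.
#' @export
conditional_log_rescale <- function(x) {
  if (any(x < 0)) stop("log rescale expects non-negative values")
  mx <- max(x)
  if (mx <= 0) stop("log rescale expects a positive maximum")
  flag <- mean(x) < 0.15 * mx && median(x) < 0.65 * mean(x)
  list(values = if (flag) log1p(x) else x, flag = flag)
}

#' Standardize descriptor columns to zero mean and unit variance
#'
#' Population (1/n) variance is used.  Constant columns cannot be
#' standardized and are dropped with a warning.
#'
#' @param m Numeric matrix, >= 2 rows.
#' @return List with `matrix`, `means`, `sds` (per kept column).
#' @export
standardize_descriptors <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 rows to standardize")
  mu <- colMeans(m)
  sdv <- sqrt(colMeans(sweep(m, 2L, mu)^2))
  const <- sdv <= 0
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(m)[const], collapse = ", "))
    m <- m[, !const, drop = FALSE]
    mu <- mu[!const]; sdv <- sdv[!const]
  }
  if (!ncol(m)) stop("no non-constant columns to standardize")
  list(matrix = sweep(sweep(m, 2L, mu), 2L, sdv, "/"), means = mu, sds = sdv)
}

#' Run the full descriptor-processing pipeline
#'
#' Zero-column filter, conditional log rescale of the count-like columns
#' (volume, probe totals, burial bins; the geometric block is left on its
#' natural scale unless `log_geometric` is set), then standardization.
#' The returned state carries everything needed to project new pockets
#' into the same space with [project_descriptors()].
#'
#' @param m Numeric matrix (pockets x descriptors) with column names.
#' @param max_zero_fraction Zero-filter threshold (default 0.95, strict).
#' @param log_geometric Also consider geometric columns for the log
#'   rescale (default `FALSE`; they can be negative-free but are not
#'   counts).
#' @return List of class `descriptor_pipeline` with `matrix` (processed)
#'   and `state` (`kept_columns`, `zero_fractions`, `log_flags`, `means`,
#'   `sds`).
#' @export
descriptor_pipeline <- function(m, max_zero_fraction = 0.95,
                                log_geometric = FALSE) {
  m <- as.matrix(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("D", seq_len(ncol(m)))
  zf <- filter_zero_columns(m, max_zero_fraction)
  mk <- zf$matrix
  geo <- descriptor_names()[100:109]
  log_flags <- setNames(logical(ncol(mk)), colnames(mk))
  for (j in seq_len(ncol(mk))) {
    nm <- colnames(mk)[j]
    if (!log_geometric && nm %in% geo) next
    x <- mk[, j]
    if (any(is.na(x)) || any(x < 0) || max(x) <= 0) next
    lr <- conditional_log_rescale(x)
    mk[, j] <- lr$values
    log_flags[j] <- lr$flag
  }
  st <- standardize_descriptors(mk)
  out <- list(matrix = st$matrix,
              state = list(kept_columns = colnames(st$matrix),
                           zero_fractions = zf$zero_fractions,
                           log_flags = log_flags[colnames(st$matrix)],
                           means = st$means, sds = st$sds))
  class(out) <- "descriptor_pipeline"
  out
}

#' Project pockets through a fitted descriptor pipeline
#'
#' @param state The `state` element of a [descriptor_pipeline()] result.
#' @param m Numeric matrix with (at least) the state's kept columns.
#' @return Standardized matrix over the kept columns.
#' @export
project_descriptors <- function(state, m) {
  m <- as.matrix(m)
  missing_cols <- setdiff(state$kept_columns, colnames(m))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  mk <- m[, state$kept_columns, drop = FALSE]
  for (nm in names(state$log_flags)[state$log_flags])
    mk[, nm] <- log1p(mk[, nm])
  sweep(sweep(mk, 2L, state$means), 2L, state$sds, "/")
}
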