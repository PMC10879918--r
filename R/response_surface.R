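# Thin-plate smoothing spline on scattered 2-D sites.
#
# Minimises  rho * sum (y_i - s(x_i))^2 + (1 - rho) * J(s),  where J is the
# thin-plate bending energy; rho = 1 interpolates.  With the radial kernel
# phi(r) = r^2 log(r^2) the minimiser is s(x) = sum a_i phi(|x - x_i|) +
# b0 + b1 u + b2 v with coefficients solving
#   [ K + lambda I   P ] [a]   [y]          lambda = (1 - rho) / rho
#   [ P'             0 ] [b] = [0]
# Affine functions have zero bending energy, so planes are reproduced
# exactly for any rho.

tps_kernel <- function(r2) ifelse(r2 > 0, r2 * log(r2), 0)

tps_basis <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
    2 * tcrossprod(x, centers)
  d2[d2 < 0] <- 0  # round-off guard
  tps_kernel(d2)
}

# One reusable factorisation for many response vectors on shared sites.
tps_system <- function(x, rho) {
  n <- nrow(x)
  P <- cbind(1, x)
  if (qr(P)$rank < 3L)
    stop("degenerate geometry: all ", n, " nodes are collinear")
  lambda <- (1 - rho) / rho
  K <- tps_basis(x, x)
  M <- rbind(cbind(K + diag(lambda, n), P),
             cbind(t(P), matrix(0, 3L, 3L)))
  list(qr = qr(M), n = n, centers = x, rho = rho)
}

tps_solve <- function(sys, y) {
  y <- as.matrix(y)
  rhs <- rbind(y, matrix(0, 3L, ncol(y)))
  coef <- qr.coef(sys$qr, rhs)
  list(a = coef[seq_len(sys$n), , drop = FALSE],
       b = coef[sys$n + 1:3, , drop = FALSE])
}

tps_predict <- function(centers, a, b, xnew) {
  drop(tps_basis(xnew, centers) %*% a + cbind(1, xnew) %*% b)
}

#' Default smoothing parameter for a node set
#'
#' The inverse mean-spacing heuristic `rho = 1/(1 + h^3/6)` with `h` the
#' average nearest-neighbour distance between node sites (in the
#' transformed log10 coordinates used for fitting).
#'
#' @param x numeric matrix of node sites (n x 2).
#' @return smoothing parameter in (0, 1).
#' @export
auto_rho <- function(x) {
  d2 <- outer(rowSums(x^2), rowSums(x^2), "+") - 2 * tcrossprod(x)
  diag(d2) <- Inf
  h <- mean(sqrt(pmax(apply(d2, 1L, min), 0)))
  1 / (1 + h^3 / 6)
}

#' Smooth one concentration-time response with a thin-plate spline
#'
#' Fits the thin-plate smoothing spline to a gene's response matrix on the
#' design grid.  Fitting is done in transformed coordinates
#' `u = log10(concentration)`, `v = log10(time)`, where the geometric
#' dilution series and near-geometric time series become roughly uniform.
#' Cells that are `NA` in `y` (missing design cells) are omitted from the
#' node set, never imputed.
#'
#' @param y numeric concentration x time response matrix (rows follow
#'   `conc_grid`, columns `time_grid`); `NA` marks missing cells.
#' @param conc_grid ascending positive concentrations (uM).
#' @param time_grid ascending positive times (h).
#' @param rho smoothing parameter in (0, 1], or `"auto"` for the
#'   [auto_rho()] heuristic; `rho = 1` interpolates the nodes.
#' @return an object of class `"smooth_surface"` with a deterministic
#'   continuous evaluator over the design rectangle (see
#'   [evaluate_surface()]).
#' @export
smooth_surface <- function(y, conc_grid, time_grid, rho = "auto") {
  stopifnot(is.matrix(y), nrow(y) == length(conc_grid),
            ncol(y) == length(time_grid),
            all(diff(conc_grid) > 0), all(conc_grid > 0),
            all(diff(time_grid) > 0), all(time_grid > 0))
  u <- log10(conc_grid)
  v <- log10(time_grid)
  sites <- cbind(u = rep(u, times = length(v)),
                 v = rep(v, each = length(u)))
  yy <- as.vector(y)
  keep <- is.finite(yy)
  if (sum(keep) < 3L) stop("need >= 3 non-missing nodes")
  sites <- sites[keep, , drop = FALSE]
  yy <- yy[keep]
  if (identical(rho, "auto")) rho <- auto_rho(sites)
  if (!is.numeric(rho) || rho <= 0 || rho > 1)
    stop("rho must be in (0, 1] or \"auto\"")
  sys <- tps_system(sites, rho)
  coef <- tps_solve(sys, yy)
  structure(list(centers = sys$centers, a = coef$a, b = coef$b, rho = rho,
                 conc_grid = conc_grid, time_grid = time_grid),
            class = "smooth_surface")
}

#' Evaluate a smoothed surface
#'
#' @param s a `"smooth_surface"` (or a factor-surface evaluator from
#'   [fit_factor_model()]).
#' @param points two-column matrix or data.frame of
#'   (concentration uM, time h) points.
#' @param extrapolate allow points outside the design rectangle (default
#'   `FALSE`: out-of-rectangle points are an error).
#' @return numeric vector of responses, one per point.
#' @export
evaluate_surface <- function(s, points, extrapolate = FALSE) {
  stopifnot(inherits(s, "smooth_surface"))
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must be (concentration, time) pairs")
  conc <- points[, 1L]
  time <- points[, 2L]
  if (any(conc <= 0) || any(time <= 0))
    stop("concentrations and times must be positive")
  if (!extrapolate) {
    out <- conc < min(s$conc_grid) - 1e-12 | conc > max(s$conc_grid) + 1e-12 |
      time < min(s$time_grid) - 1e-12 | time > max(s$time_grid) + 1e-12
    if (any(out))
      stop("point (", conc[which(out)[1L]], " uM, ", time[which(out)[1L]],
           " h) lies outside the design rectangle; set extrapolate = TRUE ",
           "to evaluate anyway")
  }
  tps_predict(s$centers, s$a, s$b, cbind(log10(conc), log10(time)))
}

#' @export
print.smooth_surface <- function(x, ...) {
  cat("thin-plate smoothed surface: ", nrow(x$centers), " nodes, rho = ",
      format(x$rho, digits = 4), "\n", sep = "")
  cat("  design rectangle: [", min(x$conc_grid), ", ", max(x$conc_grid),
      "] uM x [", min(x$time_grid), ", ", max(x$time_grid), "] h\n",
      sep = "")
  invisible(x)
}

#' Smooth every gene surface in a response set
#'
#' Fits the thin-plate smoothing spline (shared node geometry, one matrix
#' factorisation) to each gene's response and resamples the fits on the
#' design grid, producing the complete smoothed matrix the factor model
#' decomposes.
#'
#' @param rs a [response_set()].
#' @param rho smoothing parameter or `"auto"` (see [smooth_surface()]).
#' @return a list with `smoothed` (a `response_set` of fitted values on
#'   the full grid) and `rho` (the value used).
#' @export
smooth_response_set <- function(rs, rho = "auto") {
  stopifnot(inherits(rs, "response_set"))
  u <- log10(rs$conc_grid)
  v <- log10(rs$time_grid)
  all_sites <- cbind(u = rep(u, times = length(v)),
                     v = rep(v, each = length(u)))
  keep <- !as.vector(rs$missing)
  sites <- all_sites[keep, , drop = FALSE]
  if (identical(rho, "auto")) rho <- auto_rho(sites)
  sys <- tps_system(sites, rho)
  nc <- length(rs$conc_grid)
  nt <- length(rs$time_grid)
  Y <- t(apply(rs$values, 1L, as.vector))[, keep, drop = FALSE]
  coef <- tps_solve(sys, t(Y))
  fitted <- tps_basis(all_sites, sites) %*% coef$a +
    cbind(1, all_sites) %*% coef$b
  vals <- array(t(fitted), c(length(rs$gene_ids), nc, nt),
                dimnames = list(rs$gene_ids, NULL, NULL))
  list(smoothed = response_set(rs$gene_ids, rs$conc_grid, rs$time_grid,
                               vals),
       rho = rho)
}
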