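#' Fit the one-factor (principal component) model of collective response
#'
#' Stacks the (smoothed) gene surfaces as a genes x (conc*time) matrix `Y`
#' and decomposes it by uncentred singular value decomposition,
#' `Y = sum_r sigma_r u_r v_r'`.  Factor `r` is `v_r` reshaped to the
#' concentration x time grid; the loading of gene `g` on factor `r` is
#' `sigma_r * u_{g,r}`; the eigenvalue of factor `r` is `sigma_r^2`.
#' Factors are orthonormal over grid cells, so the common part of gene `g`
#' truncated at `p` factors is `sum_{r<=p} w_{g,r} f_r(c,t)`.
#'
#' No centring is applied by default: the responses are already
#' control-subtracted deviations and the model has no intercept.  Set
#' `center = TRUE` for the classical-covariance variant (grid-cell means
#' removed before decomposition and stored on the model).
#'
#' The sign of each factor/loading pair is fixed jointly so the factor's
#' grid sum is non-negative (ties broken by the sign of the
#' largest-magnitude grid cell), making the common factor surface
#' predominantly non-negative: positive loadings then read as
#' up-regulation, negative as down-regulation.
#'
#' @param surfaces a [response_set()] of smoothed responses on the
#'   complete grid (see [smooth_response_set()]).
#' @param p number of factors to keep (default 1; truncated with a warning
#'   if it exceeds the rank).
#' @param center remove grid-cell means before decomposition.
#' @return an object of class `"factor_model"`: grids, `factors`
#'   (conc x time x r array), `loadings` (genes x r matrix), `eigenvalues`
#'   (all, descending), `relative_eigenvalues`, `n_factors_kept`,
#'   `smoothed` (the input values, for residuals), `center_offset`.
#' @export
fit_factor_model <- function(surfaces, p = 1L, center = FALSE) {
  stopifnot(inherits(surfaces, "response_set"))
  if (any(surfaces$missing))
    stop("factor model needs complete grid values; smooth the responses ",
         "first (smooth_response_set)")
  gene_ids <- surfaces$gene_ids
  if (length(gene_ids) < 2L) stop("need >= 2 genes to fit a factor model")
  nc <- length(surfaces$conc_grid)
  nt <- length(surfaces$time_grid)
  Y <- matrix(aperm(surfaces$values, c(2L, 3L, 1L)),
              nrow = length(gene_ids), ncol = nc * nt, byrow = TRUE)
  rownames(Y) <- gene_ids
  offset <- rep(0, nc * nt)
  if (center) {
    offset <- colMeans(Y)
    Y <- sweep(Y, 2L, offset)
  }
  sv <- svd(Y)
  rank <- sum(sv$d > max(sv$d[1L], 1) * 1e-12)
  rank <- max(rank, 1L)
  if (p > rank) {
    warning("requested ", p, " factors but rank is ", rank,
            "; keeping ", rank)
    p <- rank
  }
  r_all <- length(sv$d)
  factors <- sv$v
  loadings <- sweep(sv$u, 2L, sv$d, "*")
  for (r in seq_len(r_all)) {     # joint sign fix per factor
    s <- sum(factors[, r])
    if (s == 0) s <- factors[which.max(abs(factors[, r])), r]
    if (s < 0) {
      factors[, r] <- -factors[, r]
      loadings[, r] <- -loadings[, r]
    }
  }
  rownames(loadings) <- gene_ids
  eig <- sv$d^2
  structure(list(conc_grid = surfaces$conc_grid,
                 time_grid = surfaces$time_grid,
                 factors = array(factors, c(nc, nt, r_all)),
                 loadings = loadings,
                 eigenvalues = eig,
                 relative_eigenvalues = eig / sum(eig),
                 n_factors_kept = as.integer(p),
                 gene_ids = gene_ids,
                 smoothed = Y,
                 center = center,
                 center_offset = offset),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  rel <- 100 * x$relative_eigenvalues
  cat("factor model: ", length(x$gene_ids), " genes, ",
      length(x$conc_grid), " x ", length(x$time_grid), " grid, ",
      x$n_factors_kept, " factor(s) kept\n", sep = "")
  cat("  relative eigenvalues (%): ",
      paste(format(rel[seq_len(min(4L, length(rel)))], digits = 3),
            collapse = ", "),
      if (length(rel) > 4L) ", ...", "\n", sep = "")
  invisible(x)
}

#' @export
coef.factor_model <- function(object, ...) object$loadings

#' Relative eigenvalue spectrum
#'
#' Per-factor eigenvalue shares as percentages.  With a list of models
#' (e.g. one per biological replicate) the shares are averaged across
#' models, matching the usual replicate-averaged spectrum display.
#'
#' @param model a `"factor_model"` or a list of them.
#' @param n_factors how many leading factors to tabulate (default all).
#' @return data.frame with columns `factor`, `eigenvalue` (NA for averaged
#'   spectra), `relative_pct`, `cumulative_pct`.
#' @export
eigen_spectrum <- function(model, n_factors = NULL) {
  if (inherits(model, "factor_model")) {
    rel <- model$relative_eigenvalues
    eig <- model$eigenvalues
  } else {
    stopifnot(is.list(model),
              all(vapply(model, inherits, TRUE, "factor_model")))
    len <- max(vapply(model, function(m) length(m$relative_eigenvalues), 1L))
    mat <- vapply(model, function(m) {
      r <- m$relative_eigenvalues
      c(r, rep(0, len - length(r)))
    }, numeric(len))
    rel <- rowMeans(matrix(mat, nrow = len))
    eig <- rep(NA_real_, len)
  }
  if (is.null(n_factors)) n_factors <- length(rel)
  n_factors <- min(n_factors, length(rel))
  idx <- seq_len(n_factors)
  data.frame(factor = idx, eigenvalue = eig[idx],
             relative_pct = 100 * rel[idx],
             cumulative_pct = 100 * cumsum(rel)[idx])
}

#' Histogram summary of first-factor gene loadings
#'
#' With the common factor surface oriented non-negative, a positive
#' loading marks an up-regulated gene and a negative loading a
#' down-regulated one.
#'
#' @param model a `"factor_model"`.
#' @param breaks passed to [graphics::hist()] (default `"Sturges"`).
#' @return list with `breaks`, `counts`, `mids`, `n_up`, `n_down`.
#' @export
loading_distribution <- function(model, breaks = "Sturges") {
  stopifnot(inherits(model, "factor_model"))
  w <- model$loadings[, 1L]
  h <- graphics::hist(w, breaks = breaks, plot = FALSE)
  list(breaks = h$breaks, counts = h$counts, mids = h$mids,
       n_up = sum(w > 0), n_down = sum(w < 0))
}

#' Reconstruct one gene's fitted response
#'
#' The common part truncated at `p` factors,
#' `sum_{r<=p} w_{g,r} f_r(c,t)`, on the design grid.
#'
#' @param model a `"factor_model"`.
#' @param gene gene id.
#' @param p number of factors (default: the model's `n_factors_kept`;
#'   `p = 0` gives the zero matrix, full rank reproduces the smoothed
#'   input).
#' @return concentration x time matrix of fitted responses.
#' @export
reconstruct_gene <- function(model, gene, p = model$n_factors_kept) {
  stopifnot(inherits(model, "factor_model"))
  g <- match(gene, model$gene_ids)
  if (is.na(g)) stop("unknown gene: '", gene, "'")
  nfac <- dim(model$factors)[3L]
  if (p > nfac) stop("p = ", p, " exceeds the ", nfac, " stored factors")
  nc <- length(model$conc_grid)
  nt <- length(model$time_grid)
  out <- matrix(model$center_offset, nc, nt)
  if (!model$center) out[] <- 0
  for (r in seq_len(p))
    out <- out + model$loadings[g, r] * model$factors[, , r]
  out
}

#' @export
residuals.factor_model <- function(object, p = object$n_factors_kept, ...) {
  nc <- length(object$conc_grid)
  nt <- length(object$time_grid)
  Fm <- matrix(object$factors, nc * nt, dim(object$factors)[3L])
  common <- object$loadings[, seq_len(p), drop = FALSE] %*%
    t(Fm[, seq_len(p), drop = FALSE])
  res <- object$smoothed - common
  rownames(res) <- object$gene_ids
  res
}

#' Continuous evaluator for a factor surface
#'
#' The factor exists only on the design grid after the decomposition; a
#' rho = 1 thin-plate interpolant of its grid values (in log10
#' coordinates) extends it to a smooth surface so level sets can be
#' solved continuously.
#'
#' @param model a `"factor_model"`.
#' @param r factor index (default 1, the common factor).
#' @return a `"smooth_surface"` interpolating the factor's grid values.
#' @export
factor_surface <- function(model, r = 1L) {
  stopifnot(inherits(model, "factor_model"))
  smooth_surface(model$factors[, , r], model$conc_grid, model$time_grid,
                 rho = 1)
}
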