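#' Per-gene benchmark levels on the common-factor surface
#'
#' For each gene, `bmr_factor * sigma_g / |w_g|`: the height the common
#' factor surface must reach for that gene's fitted response to move
#' `bmr_factor` noise standard deviations away from control.  The default
#' BMR factor 1.349 corresponds to the conventional benchmark response of
#' 1.349 control SDs.  Genes with `|w_g|` below `w_tol` are excluded
#' (division guard) and counted in the `"n_excluded"` attribute.
#'
#' @param model a `"factor_model"`.
#' @param sigma named per-gene noise SDs from [estimate_sigma()].
#' @param bmr_factor benchmark-response factor (default 1.349).
#' @param w_tol loading magnitude below which a gene is excluded.
#' @return named numeric vector of per-gene levels, attribute
#'   `n_excluded`.
#' @export
gene_levels <- function(model, sigma, bmr_factor = 1.349, w_tol = 1e-8) {
  stopifnot(inherits(model, "factor_model"))
  w <- model$loadings[, 1L]
  s <- sigma[model$gene_ids]
  if (anyNA(s)) stop("sigma is missing for ",
                     sum(is.na(s)), " model gene(s)")
  if (any(s <= 0)) stop("sigma must be strictly positive")
  keep <- abs(w) > w_tol
  if (!any(keep)) stop("no genes with |loading| > ", w_tol)
  lev <- bmr_factor * s[keep] / abs(w[keep])
  attr(lev, "n_excluded") <- sum(!keep)
  lev
}

#' Median benchmark level (the median isoBMR level)
#'
#' `v_med = median_g( bmr_factor * sigma_g / |w_g| )` over the genes in
#' the model.
#'
#' @inheritParams gene_levels
#' @return the level, a positive scalar in common-factor response units.
#' @export
compute_level_median <- function(model, sigma, bmr_factor = 1.349,
                                 w_tol = 1e-8) {
  stats::median(gene_levels(model, sigma, bmr_factor, w_tol))
}

#' Percentile benchmark level
#'
#' The `q`-th percentile of the per-gene levels, using the default R
#' quantile definition (type 7, linear interpolation of order statistics);
#' `q = 50` reproduces [compute_level_median()].
#'
#' @inheritParams gene_levels
#' @param q percentile in (0, 100).
#' @return the level, a positive scalar.
#' @export
compute_level_percentile <- function(model, sigma, q, bmr_factor = 1.349,
                                     w_tol = 1e-8) {
  if (q <= 0 || q >= 100) stop("q must lie strictly between 0 and 100")
  unname(stats::quantile(gene_levels(model, sigma, bmr_factor, w_tol),
                         q / 100, type = 7))
}

#' Extract an isoBMR curve (level set of the factor surface)
#'
#' For each time on a dense log-spaced grid, finds the smallest
#' concentration in `[c_min, c_max]` at which the continuous factor
#' surface crosses the level `v`, by bracketing on a scan grid followed by
#' bisection in log10 concentration (tolerance `tol`).  Times with no
#' crossing are omitted; times where the surface crosses the level more
#' than once are flagged (`multi` column) and the lowest crossing — the
#' most conservative BMC — is kept.
#'
#' @param model a `"factor_model"` (its first factor is used) or a
#'   `"smooth_surface"` evaluator.
#' @param level positive level `v` on the surface.
#' @param n_times dense time-grid resolution (default 200).
#' @param n_scan bracketing scan points along log10 concentration.
#' @param tol bisection tolerance in log10 concentration units.
#' @return an object of class `"isobmr_curve"`: a data.frame with columns
#'   `time_h`, `conc_uM`, `log10_time`, `log10_conc`, `multi`, ordered by
#'   strictly increasing time, plus attributes `level`, `kind`, `q_or_gene`.
#' @export
extract_iso_curve <- function(model, level, n_times = 200L, n_scan = 64L,
                              tol = 1e-6) {
  surf <- if (inherits(model, "factor_model")) factor_surface(model)
          else model
  stopifnot(inherits(surf, "smooth_surface"))
  if (!is.finite(level) || level <= 0) stop("level must be positive")
  tg <- surf$time_grid
  cg <- surf$conc_grid
  times <- 10^seq(log10(min(tg)), log10(max(tg)), length.out = n_times)
  lc_scan <- seq(log10(min(cg)), log10(max(cg)), length.out = n_scan)
  nt <- length(times)
  # bracketing scan: one vectorised surface evaluation over the whole
  # time x concentration lattice
  fv <- matrix(evaluate_surface(
    surf, cbind(10^rep(lc_scan, nt), rep(times, each = n_scan))),
    n_scan, nt) - level
  lo <- hi <- flo <- rep(NA_real_, nt)
  multi <- logical(nt)
  for (i in seq_len(nt)) {
    sgn <- sign(fv[, i])
    cross <- which(sgn[-n_scan] * sgn[-1L] < 0 | fv[-n_scan, i] == 0)
    if (!length(cross)) next
    multi[i] <- length(cross) > 1L  # lowest crossing kept (conservative)
    lo[i] <- lc_scan[cross[1L]]
    hi[i] <- lc_scan[cross[1L] + 1L]
    flo[i] <- fv[cross[1L], i]
  }
  keep <- which(is.finite(lo))
  if (length(keep)) {
    # simultaneous bisection in log10 concentration for all bracketed times
    n_iter <- ceiling(log2((lc_scan[2L] - lc_scan[1L]) / tol)) + 1L
    for (it in seq_len(n_iter)) {
      mid <- (lo[keep] + hi[keep]) / 2
      fm <- evaluate_surface(surf, cbind(10^mid, times[keep])) - level
      same <- sign(fm) == sign(flo[keep]) & fm != 0
      lo[keep][same] <- mid[same]
      flo[keep][same] <- fm[same]
      hi[keep][!same] <- mid[!same]
    }
  }
  lc <- (lo[keep] + hi[keep]) / 2
  out <- data.frame(time_h = times[keep], conc_uM = 10^lc,
                    log10_time = log10(times[keep]), log10_conc = lc,
                    multi = multi[keep])
  structure(out, level = level, kind = "level", q_or_gene = NA,
            class = c("isobmr_curve", "data.frame"))
}

#' @export
print.isobmr_curve <- function(x, ...) {
  cat("isoBMR curve (", attr(x, "kind"), "): level ",
      format(attr(x, "level"), digits = 4), ", ", nrow(x),
      " (time, concentration) points\n", sep = "")
  if (nrow(x)) {
    cat("  time span ", format(min(x$time_h), digits = 3), "-",
        format(max(x$time_h), digits = 3), " h; concentration ",
        format(min(x$conc_uM), digits = 3), "-",
        format(max(x$conc_uM), digits = 3), " uM\n", sep = "")
  } else cat("  empty: level above the surface everywhere\n")
  invisible(x)
}

#' Gene-specific isoBMR curve
#'
#' The level set of the common factor surface at
#' `bmr_factor * sigma_g / |w_g|`.  The absolute value of the loading is
#' used: down-regulated genes cross their benchmark at the same magnitude
#' of common-factor response as up-regulated genes of equal |loading|.
#'
#' @inheritParams gene_levels
#' @param gene_id gene whose curve to extract.
#' @param ... passed to [extract_iso_curve()].
#' @return an `"isobmr_curve"`.
#' @export
gene_iso_curve <- function(model, sigma, gene_id, bmr_factor = 1.349,
                           ...) {
  lev <- gene_levels(model, sigma, bmr_factor, w_tol = 0)
  if (!gene_id %in% names(lev))
    stop("gene '", gene_id, "' not in the model (or zero loading)")
  cur <- extract_iso_curve(model, lev[[gene_id]], ...)
  attr(cur, "kind") <- "gene"
  attr(cur, "q_or_gene") <- gene_id
  cur
}

#' Benchmark concentration at an exposure time
#'
#' Projects an isoBMR curve onto a chosen exposure time by log-linear
#' interpolation of the polyline in (log10 time, log10 concentration).
#' Times outside the curve's span are an error by default; with
#' `extrapolate = TRUE` a power law `log10 c = a + b log10 t` is fitted to
#' the curve tail (last `tail_n` points) and used beyond the span.
#'
#' @param curve an `"isobmr_curve"`.
#' @param t exposure time(s), hours.
#' @param extrapolate allow power-law extrapolation beyond the span.
#' @param tail_n points in the tail fit (default 10).
#' @return concentration(s) in uM.
#' @export
bmc_at_time <- function(curve, t, extrapolate = FALSE, tail_n = 10L) {
  stopifnot(inherits(curve, "isobmr_curve"))
  if (!nrow(curve)) stop("empty isoBMR curve has no BMC")
  lt <- log10(t)
  inside <- lt >= min(curve$log10_time) - 1e-12 &
    lt <= max(curve$log10_time) + 1e-12
  if (!extrapolate && any(!inside))
    stop("time ", t[which(!inside)[1L]], " h is outside the curve span [",
         format(min(curve$time_h), digits = 3), ", ",
         format(max(curve$time_h), digits = 3),
         "] h; set extrapolate = TRUE for a power-law tail fit")
  out <- numeric(length(lt))
  if (any(inside))
    out[inside] <- stats::approx(curve$log10_time, curve$log10_conc,
                                 xout = pmin(pmax(lt[inside],
                                                  min(curve$log10_time)),
                                             max(curve$log10_time)),
                                 ties = "ordered")$y
  if (any(!inside)) {
    n <- nrow(curve)
    idx <- if (any(lt[!inside] > max(curve$log10_time)))
      seq(max(1L, n - tail_n + 1L), n) else seq_len(min(tail_n, n))
    fit <- stats::lm.fit(cbind(1, curve$log10_time[idx]),
                         curve$log10_conc[idx])
    out[!inside] <- fit$coefficients[1L] + fit$coefficients[2L] * lt[!inside]
  }
  10^out
}

#' Slope of an isoBMR curve in log-log coordinates
#'
#' Least-squares slope of log10 concentration against log10 time over an
#' optional time window (hours); slope -1 is Haber-rule behaviour
#' (constant concentration x time product), slope 0 a purely
#' concentration-driven effect.
#'
#' @param curve an `"isobmr_curve"`.
#' @param time_window optional `c(min_h, max_h)` restriction, e.g. to drop
#'   early transient response.
#' @return the slope (dimensionless).
#' @export
curve_slope <- function(curve, time_window = NULL) {
  stopifnot(inherits(curve, "isobmr_curve"))
  d <- curve
  if (!is.null(time_window))
    d <- d[d$time_h >= time_window[1L] & d$time_h <= time_window[2L], ,
           drop = FALSE]
  if (nrow(d) < 2L) stop("fewer than 2 curve points in the window")
  stats::cov(d$log10_time, d$log10_conc) / stats::var(d$log10_time)
}

#' Percentile, median and per-replicate isoBMR curve report
#'
#' Tabulates, for one chemical: the percentile curves (default 10th-90th)
#' and median curve of the averaged model, and the median curves of any
#' per-replicate models.  All curves are level sets of each model's common
#' factor surface; tables carry raw and log10 coordinates.
#'
#' @param model the averaged-replicate `"factor_model"`.
#' @param sigma per-gene noise SDs.
#' @param replicate_models optional named list of per-replicate models.
#' @param percentiles percentiles to extract (default `seq(10, 90, 10)`).
#' @param bmr_factor benchmark-response factor (default 1.349).
#' @param chemical label written into the table.
#' @param ... passed to [extract_iso_curve()].
#' @return data.frame with columns `chemical`, `curve_kind`
#'   (`median|percentile|replicate`), `q_or_gene`, `level`, `time_h`,
#'   `conc_uM`, `log10_time`, `log10_conc`.
#' @export
curve_set_report <- function(model, sigma, replicate_models = NULL,
                             percentiles = seq(10, 90, 10),
                             bmr_factor = 1.349, chemical = NA_character_,
                             ...) {
  row_of <- function(cur, kind, qog, level) {
    if (!nrow(cur)) return(NULL)
    data.frame(chemical = chemical, curve_kind = kind, q_or_gene = qog,
               level = level, time_h = cur$time_h, conc_uM = cur$conc_uM,
               log10_time = cur$log10_time, log10_conc = cur$log10_conc,
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (q in percentiles) {
    lev <- compute_level_percentile(model, sigma, q, bmr_factor)
    out[[length(out) + 1L]] <-
      row_of(extract_iso_curve(model, lev, ...), "percentile",
             as.character(q), lev)
  }
  lev <- compute_level_median(model, sigma, bmr_factor)
  out[[length(out) + 1L]] <-
    row_of(extract_iso_curve(model, lev, ...), "median", "50", lev)
  if (!is.null(replicate_models)) {
    if (is.null(names(replicate_models)))
      names(replicate_models) <- seq_along(replicate_models)
    for (nm in names(replicate_models)) {
      m <- replicate_models[[nm]]
      lev <- compute_level_median(m, sigma, bmr_factor)
      out[[length(out) + 1L]] <-
        row_of(extract_iso_curve(m, lev, ...), "replicate", nm, lev)
    }
  }
  do.call(rbind, out)
}

#' Plot isoBMR curves in log-log coordinates
#'
#' @param report a curve table from [curve_set_report()].
#' @param main plot title.
#' @export
plot_curve_report <- function(report, main = "isoBMR curves") {
  stopifnot(nrow(report) > 0)
  graphics::plot(NA, xlim = range(report$log10_time),
                 ylim = range(report$log10_conc),
                 xlab = "log10 time (h)",
                 ylab = "log10 concentration (uM)", main = main)
  keys <- unique(report[, c("curve_kind", "q_or_gene")])
  for (i in seq_len(nrow(keys))) {
    d <- report[report$curve_kind == keys$curve_kind[i] &
                  report$q_or_gene == keys$q_or_gene[i], ]
    med <- keys$curve_kind[i] == "median"
    graphics::lines(d$log10_time, d$log10_conc,
                    col = if (med) "red" else "grey40",
                    lwd = if (med) 2 else 1)
  }
  invisible(report)
}
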