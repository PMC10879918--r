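#' Build control-subtracted response surfaces for one chemical
#'
#' Convenience wrapper around [condition_means()], [control_means()] and
#' [subtract_vehicle()].  Vehicle controls are matched by time point only
#' by default; `control_matching = "plate"` restricts each design cell's
#' control mean to the plates its treated samples sit on.
#'
#' @param expr log2 CPM matrix.
#' @param ann sample annotation.
#' @param chemical chemical name.
#' @param bio_rep `NULL` to pool biological replicates, or one id.
#' @param control_matching `"time"` (default) or `"plate"`.
#' @return a [response_set()].
#' @export
response_surfaces <- function(expr, ann, chemical, bio_rep = NULL,
                              control_matching = c("time", "plate")) {
  control_matching <- match.arg(control_matching)
  ann <- validate_annotation(as.data.frame(ann))
  cm <- condition_means(expr, ann, chemical, bio_rep)
  if (control_matching == "time")
    return(subtract_vehicle(cm, control_means(expr, ann, bio_rep)))
  sub <- ann
  if (!is.null(bio_rep)) sub <- sub[sub$bio_rep %in% bio_rep, , drop = FALSE]
  trt <- sub[!sub$is_control & sub$chemical %in% chemical, , drop = FALSE]
  ctl <- sub[sub$is_control, , drop = FALSE]
  vals <- cm$values
  for (ci in seq_along(cm$conc_grid)) {
    for (ti in seq_along(cm$time_grid)) {
      if (cm$n[ci, ti] == 0L) next
      plates <- unique(trt$plate[trt$concentration_uM == cm$conc_grid[ci] &
                                   trt$time_h == cm$time_grid[ti]])
      ids <- ctl$sample_id[ctl$plate %in% plates &
                             ctl$time_h == cm$time_grid[ti]]
      if (!length(ids))
        stop("no vehicle controls on plate(s) ",
             paste(plates, collapse = ", "), " at ", cm$time_grid[ti], " h")
      vals[, ci, ti] <- vals[, ci, ti] -
        rowMeans(expr[, ids, drop = FALSE])
    }
  }
  response_set(cm$gene_ids, cm$conc_grid, cm$time_grid, vals,
               missing = cm$n == 0L)
}

#' Fit the concentration-time benchmark-response model
#'
#' The full analysis for one chemical, from a raw count matrix to isoBMR
#' curves: (1) drop genes with mean raw count below `min_mean_reads`;
#' (2) normalise to log2 counts per million; (3) estimate per-gene noise
#' SDs from vehicle-control replicates; (4) select differentially
#' expressed genes with the two-sided permutation Williams' trend test
#' (`p < alpha` and `|log2FC| > lfc` at >= 1 time point); (5) form
#' control-subtracted concentration x time responses per biological
#' replicate and smooth each with a thin-plate spline; (6) fit the
#' one-factor principal-component model to the per-replicate surfaces and
#' to their average; (7) compute the median and percentile benchmark
#' levels `bmr_factor * sigma_g / |w_g|` and extract the corresponding
#' isoBMR curves from the common factor surface.
#'
#' `mode` picks which model drives the reported median curve:
#' `"averaged"` (default) uses the factor model of the
#' replicate-averaged smoothed surfaces; `"per-replicate"` reports each
#' replicate's own median curve and uses their first replicate's model
#' for percentile curves.  Both sets of models are kept on the object.
#'
#' Randomness (permutation p-values) uses R's RNG: call `set.seed()`
#' before fitting for reproducible p-values.
#'
#' @param counts integer count matrix, genes in rows.
#' @param ann sample annotation (see [read_annotation()]).
#' @param chemical chemical to model.
#' @param min_mean_reads mean-read filter threshold (default 10).
#' @param pseudocount CPM offset in the log transform (default 1).
#' @param alpha Williams-test p-value threshold (default 0.05).
#' @param lfc absolute log2-fold-change threshold (default 1).
#' @param n_perm permutations per Williams test (default 999).
#' @param rho thin-plate smoothing parameter or `"auto"`.
#' @param bmr_factor benchmark-response factor (default 1.349).
#' @param percentiles percentile curves to extract.
#' @param mode `"averaged"` or `"per-replicate"`.
#' @param sigma_method `"control"` or `"residual"` (see
#'   [estimate_sigma()]).
#' @param control_matching `"time"` or `"plate"`.
#' @param center mean-centre surfaces before the decomposition.
#' @param n_times dense time-grid resolution for curve extraction.
#' @return an object of class `"isobmr_fit"`; see Details for the main
#'   components (`degs`, `model`, `replicate_models`, `sigma`, `levels`,
#'   `median_curve`, `curves`).
#' @examples
#' set.seed(1)
#' des <- experiment_design(chemicals = "chemA", top_conc_uM = 50,
#'                          n_bio_reps = 2, n_tech_reps = 2,
#'                          time_points_h = c(2, 6, 24))
#' truth <- synthetic_truth(n_genes = 120, noise_sd = 0.05)
#' sim <- simulate_counts(truth, generate_design(des))
#' fit <- isobmr_fit(sim$counts, sim$ann, "chemA", n_perm = 199)
#' print(fit)
#' predict(fit, time_h = c(6, 24))
#' @export
isobmr_fit <- function(counts, ann, chemical,
                       min_mean_reads = 10, pseudocount = 1,
                       alpha = 0.05, lfc = 1.0, n_perm = 999L,
                       rho = "auto", bmr_factor = 1.349,
                       percentiles = seq(10, 90, 10),
                       mode = c("averaged", "per-replicate"),
                       sigma_method = c("control", "residual"),
                       control_matching = c("time", "plate"),
                       center = FALSE, n_times = 200L) {
  mode <- match.arg(mode)
  sigma_method <- match.arg(sigma_method)
  control_matching <- match.arg(control_matching)
  cl <- match.call()
  counts <- validate_counts(counts)
  ann <- validate_annotation(as.data.frame(ann))
  filtered <- filter_low_expression(counts, min_mean_reads)
  expr <- cpm_log2(filtered, pseudocount)
  sigma <- estimate_sigma(expr, ann, sigma_method)
  degs <- select_degs(expr, ann, chemical, alpha = alpha, lfc = lfc,
                      n_perm = n_perm)
  if (length(degs$gene_ids) < 2L)
    stop("fewer than 2 differentially expressed genes for '", chemical,
         "'; nothing to model (", length(degs$gene_ids), " retained)")
  dexpr <- expr[degs$gene_ids, , drop = FALSE]
  bios <- sort(unique(ann$bio_rep[!ann$is_control &
                                    ann$chemical %in% chemical]))
  rho_used <- rho
  smoothed <- list()
  for (b in bios) {
    rs <- response_surfaces(dexpr, ann, chemical, bio_rep = b,
                            control_matching = control_matching)
    sm <- smooth_response_set(rs, rho)
    rho_used <- sm$rho
    smoothed[[as.character(b)]] <- sm$smoothed
  }
  avg_vals <- Reduce(`+`, lapply(smoothed, `[[`, "values")) /
    length(smoothed)
  g1 <- smoothed[[1L]]
  avg_set <- response_set(g1$gene_ids, g1$conc_grid, g1$time_grid,
                          avg_vals)
  model <- fit_factor_model(avg_set, p = 1L, center = center)
  replicate_models <- lapply(smoothed, fit_factor_model, p = 1L,
                             center = center)
  sigma_deg <- sigma[degs$gene_ids]
  main_model <- if (mode == "averaged") model else replicate_models[[1L]]
  v_med <- compute_level_median(main_model, sigma_deg, bmr_factor)
  v_q <- vapply(percentiles, function(q)
    compute_level_percentile(main_model, sigma_deg, q, bmr_factor),
    numeric(1L))
  names(v_q) <- percentiles
  median_curve <- extract_iso_curve(main_model, v_med, n_times = n_times)
  attr(median_curve, "kind") <- "median"
  attr(median_curve, "q_or_gene") <- "50"
  curves <- curve_set_report(main_model, sigma_deg,
                             replicate_models = replicate_models,
                             percentiles = percentiles,
                             bmr_factor = bmr_factor,
                             chemical = chemical, n_times = n_times)
  structure(list(chemical = chemical, call = cl,
                 config = list(min_mean_reads = min_mean_reads,
                               pseudocount = pseudocount, alpha = alpha,
                               lfc = lfc, n_perm = as.integer(n_perm),
                               rho = rho_used, bmr_factor = bmr_factor,
                               percentiles = percentiles, mode = mode,
                               sigma_method = sigma_method,
                               control_matching = control_matching,
                               center = center, n_times = n_times),
                 n_genes_raw = nrow(counts),
                 n_genes_filtered = nrow(filtered),
                 degs = degs, sigma = sigma,
                 responses = avg_set,
                 model = model, replicate_models = replicate_models,
                 levels = list(median = v_med, percentiles = v_q,
                               gene = gene_levels(main_model, sigma_deg,
                                                  bmr_factor)),
                 median_curve = median_curve, curves = curves),
            class = "isobmr_fit")
}

#' @export
print.isobmr_fit <- function(x, ...) {
  cat("isoBMR fit for ", x$chemical, "\n", sep = "")
  cat("  genes: ", x$n_genes_raw, " read, ", x$n_genes_filtered,
      " pass the ", x$config$min_mean_reads, "-mean-read filter, ",
      length(x$degs$gene_ids), " differentially expressed\n", sep = "")
  cat("  first factor explains ",
      format(100 * x$model$relative_eigenvalues[1L], digits = 3),
      "% of response variation (averaged replicates)\n", sep = "")
  cat("  median benchmark level v = ",
      format(x$levels$median, digits = 4), " (BMR factor ",
      x$config$bmr_factor, ")\n", sep = "")
  if (nrow(x$median_curve)) {
    bmc24 <- tryCatch(bmc_at_time(x$median_curve, 24), error = function(e) NA)
    if (is.finite(bmc24))
      cat("  median BMC at 24 h: ", format(bmc24, digits = 3), " uM\n",
          sep = "")
  } else cat("  median level is above the factor surface everywhere\n")
  invisible(x)
}

#' @export
summary.isobmr_fit <- function(object, ...) {
  structure(list(fit = object,
                 spectrum = eigen_spectrum(object$model, n_factors = 5L),
                 deg_counts = object$degs$counts_per_time,
                 slope = if (nrow(object$median_curve) >= 2L)
                   curve_slope(object$median_curve) else NA_real_),
            class = "summary.isobmr_fit")
}

#' @export
print.summary.isobmr_fit <- function(x, ...) {
  print(x$fit)
  cat("\nDEG counts per time point (h):\n")
  print(x$deg_counts)
  cat("\nEigenvalue spectrum (averaged model):\n")
  print(x$spectrum, row.names = FALSE)
  if (is.finite(x$slope))
    cat("\nmedian-curve log-log slope: ", format(x$slope, digits = 3),
        "  (-1 = Haber's rule, 0 = concentration-only)\n", sep = "")
  invisible(x)
}

#' @export
coef.isobmr_fit <- function(object, ...) coef(object$model)

#' @export
residuals.isobmr_fit <- function(object, ...) residuals(object$model, ...)

#' Benchmark concentration at chosen exposure times
#'
#' Projects a fitted isoBMR curve onto exposure times.  `q = 50` (default)
#' uses the median curve; other percentiles must be among the fitted
#' `percentiles`; a `gene` id uses that gene's own curve.
#'
#' @param object an `"isobmr_fit"`.
#' @param time_h exposure times, hours.
#' @param q percentile of the reported curve (default 50).
#' @param gene optional gene id overriding `q`.
#' @param extrapolate allow power-law extrapolation beyond the curve span.
#' @param ... unused.
#' @return named numeric vector of BMCs (uM) at `time_h`.
#' @export
predict.isobmr_fit <- function(object, time_h = c(2, 6, 12, 24, 48),
                               q = 50, gene = NULL, extrapolate = FALSE,
                               ...) {
  if (!is.null(gene)) {
    main <- if (object$config$mode == "averaged") object$model
            else object$replicate_models[[1L]]
    curve <- gene_iso_curve(main, object$sigma[object$degs$gene_ids],
                            gene, object$config$bmr_factor,
                            n_times = object$config$n_times)
  } else if (q == 50) {
    curve <- object$median_curve
  } else {
    d <- object$curves[object$curves$curve_kind == "percentile" &
                         object$curves$q_or_gene == as.character(q), ]
    if (!nrow(d)) stop("percentile ", q, " was not fitted; refit with it ",
                       "in `percentiles`")
    curve <- structure(d[, c("time_h", "conc_uM", "log10_time",
                             "log10_conc")],
                       level = d$level[1L], kind = "percentile",
                       q_or_gene = as.character(q),
                       class = c("isobmr_curve", "data.frame"))
  }
  out <- bmc_at_time(curve, time_h, extrapolate = extrapolate)
  stats::setNames(out, paste0(time_h, "h"))
}

#' Plot the fitted isoBMR curves
#'
#' Percentile fan (grey), median curve (red), per-replicate medians
#' (dashed blue), in log10-log10 coordinates.
#'
#' @param x an `"isobmr_fit"`.
#' @param ... unused.
#' @export
plot.isobmr_fit <- function(x, ...) {
  rep_cur <- x$curves[x$curves$curve_kind == "replicate", ]
  plot_curve_report(x$curves[x$curves$curve_kind != "replicate", ],
                    main = paste("isoBMR curves:", x$chemical))
  for (nm in unique(rep_cur$q_or_gene)) {
    d <- rep_cur[rep_cur$q_or_gene == nm, ]
    graphics::lines(d$log10_time, d$log10_conc, col = "blue", lty = 2)
  }
  invisible(x)
}
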