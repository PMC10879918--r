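#' Filter genes with low mean read count
#'
#' Retains exactly the genes whose mean raw count across all samples is at
#' least `min_mean_reads` (inclusive); row order is preserved.
#'
#' @param counts integer count matrix, genes in rows.
#' @param min_mean_reads mean-read threshold (default 10).
#' @return the filtered count matrix.
#' @export
filter_low_expression <- function(counts, min_mean_reads = 10) {
  keep <- rowMeans(counts) >= min_mean_reads
  if (!any(keep))
    stop("all ", nrow(counts), " genes fall below mean-read threshold ",
         min_mean_reads, "; review the threshold or the input counts")
  counts[keep, , drop = FALSE]
}

#' Log2 counts-per-million normalisation
#'
#' `log2(count / sample_total * 1e6 + pseudocount)`.  The pseudocount (in
#' CPM units, default 1) keeps zero counts finite.
#'
#' @param counts integer count matrix, genes in rows.
#' @param pseudocount CPM offset added inside the log.
#' @return a numeric matrix of log2 CPM values, same dimnames as `counts`.
#' @export
cpm_log2 <- function(counts, pseudocount = 1) {
  totals <- colSums(counts)
  if (any(totals <= 0))
    stop("sample '", colnames(counts)[which(totals <= 0)[1L]],
         "' has zero total count")
  cpm <- sweep(counts, 2L, totals, "/") * 1e6
  log2(cpm + pseudocount)
}

#' Per-condition mean expression for one chemical
#'
#' Averages replicate log2 expression values within each
#' (concentration, time) cell of one chemical's design grid.  Technical
#' replicates are always pooled; biological replicates are pooled when
#' `bio_rep = NULL` (the default) or restricted to a single biological
#' replicate otherwise.
#'
#' @param expr log2 CPM matrix from [cpm_log2()].
#' @param ann sample annotation.
#' @param chemical chemical name to extract.
#' @param bio_rep `NULL` to pool biological replicates, or one bio_rep id.
#' @return a list with `gene_ids`, ascending `conc_grid` and `time_grid`,
#'   a gene x concentration x time array `values` of cell means, and an
#'   integer array `n` of replicate counts (0 marks a missing cell).
#' @export
condition_means <- function(expr, ann, chemical, bio_rep = NULL) {
  ann <- validate_annotation(as.data.frame(ann))
  if (!all(colnames(expr) %in% ann$sample_id))
    stop("annotation does not cover all expression samples")
  sel <- !ann$is_control & ann$chemical %in% chemical
  if (!is.null(bio_rep)) sel <- sel & ann$bio_rep %in% bio_rep
  trt <- ann[sel, , drop = FALSE]
  if (!nrow(trt)) stop("no treated samples found for chemical '",
                       chemical, "'")
  conc_grid <- sort(unique(trt$concentration_uM))
  time_grid <- sort(unique(trt$time_h))
  vals <- array(NA_real_,
                c(nrow(expr), length(conc_grid), length(time_grid)),
                dimnames = list(rownames(expr), NULL, NULL))
  n <- array(0L, c(length(conc_grid), length(time_grid)))
  for (ci in seq_along(conc_grid)) {
    for (ti in seq_along(time_grid)) {
      ids <- trt$sample_id[trt$concentration_uM == conc_grid[ci] &
                             trt$time_h == time_grid[ti]]
      n[ci, ti] <- length(ids)
      if (length(ids))
        vals[, ci, ti] <- rowMeans(expr[, ids, drop = FALSE])
    }
  }
  list(gene_ids = rownames(expr), conc_grid = conc_grid,
       time_grid = time_grid, values = vals, n = n)
}

#' Mean vehicle-control expression per time point
#'
#' @param expr log2 CPM matrix.
#' @param ann sample annotation.
#' @param bio_rep `NULL` to pool biological replicates, or one bio_rep id.
#' @return a gene x time matrix of control means; columns named by time.
#' @export
control_means <- function(expr, ann, bio_rep = NULL) {
  ann <- validate_annotation(as.data.frame(ann))
  ctl <- ann[ann$is_control, , drop = FALSE]
  if (!is.null(bio_rep)) ctl <- ctl[ctl$bio_rep %in% bio_rep, , drop = FALSE]
  if (!nrow(ctl)) stop("no vehicle-control samples in annotation")
  times <- sort(unique(ctl$time_h))
  out <- sapply(times, function(t) {
    ids <- ctl$sample_id[ctl$time_h == t]
    rowMeans(expr[, ids, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(expr),
                dimnames = list(rownames(expr), times))
  out
}

#' Control-subtracted concentration-time responses
#'
#' Subtracts the time-matched vehicle-control mean from each condition
#' mean, yielding the per-gene response surface values on the design grid
#' (a `response_set`).
#'
#' @param cm output of [condition_means()].
#' @param ctrl gene x time control-mean matrix from [control_means()]
#'   (columns named by time point).
#' @return an object of class `"response_set"`: `gene_ids`, `conc_grid`,
#'   `time_grid`, gene x conc x time `values`, logical conc x time
#'   `missing` mask.
#' @export
subtract_vehicle <- function(cm, ctrl) {
  have <- as.numeric(colnames(ctrl))
  miss <- setdiff(cm$time_grid, have)
  if (length(miss))
    stop("no vehicle controls for time point(s): ",
         paste(miss, collapse = ", "), " h")
  vals <- cm$values
  for (ti in seq_along(cm$time_grid)) {
    j <- match(cm$time_grid[ti], have)
    vals[, , ti] <- vals[, , ti] - ctrl[, j]
  }
  response_set(cm$gene_ids, cm$conc_grid, cm$time_grid, vals,
               missing = cm$n == 0L)
}

#' Construct a response-surface set
#'
#' Container for per-gene control-subtracted log2 responses on the
#' concentration x time design grid.
#'
#' @param gene_ids character vector.
#' @param conc_grid strictly increasing positive concentrations (uM).
#' @param time_grid strictly increasing positive times (h).
#' @param values gene x conc x time numeric array.
#' @param missing logical conc x time mask of absent design cells.
#' @return an object of class `"response_set"`.
#' @export
response_set <- function(gene_ids, conc_grid, time_grid, values,
                         missing = NULL) {
  stopifnot(all(diff(conc_grid) > 0), all(conc_grid > 0),
            all(diff(time_grid) > 0), all(time_grid > 0),
            length(dim(values)) == 3L,
            dim(values)[1L] == length(gene_ids),
            dim(values)[2L] == length(conc_grid),
            dim(values)[3L] == length(time_grid))
  if (is.null(missing))
    missing <- matrix(FALSE, length(conc_grid), length(time_grid))
  ok <- !missing
  for (g in seq_len(dim(values)[1L])) {
    if (any(!is.finite(values[g, , ][ok])))
      stop("non-finite response for gene '", gene_ids[g],
           "' on a non-missing design cell")
  }
  structure(list(gene_ids = as.character(gene_ids), conc_grid = conc_grid,
                 time_grid = time_grid, values = values, missing = missing),
            class = "response_set")
}

#' @export
print.response_set <- function(x, ...) {
  cat("response_set: ", length(x$gene_ids), " genes on a ",
      length(x$conc_grid), " concentration x ", length(x$time_grid),
      " time grid\n", sep = "")
  if (any(x$missing))
    cat("  missing design cells: ", sum(x$missing), "\n", sep = "")
  invisible(x)
}

#' Per-gene noise standard deviation
#'
#' For each gene, the sample standard deviation of log2 expression across
#' vehicle-control replicates is computed at each time point and averaged
#' over time points (`sigma_method = "control"`, the default).  The
#' `"residual"` alternative averages, over all treated conditions and time
#' points, the replicate SD within each condition cell.  A floor (default
#' 1e-6) keeps downstream benchmark levels finite for degenerate
#' zero-variance genes.
#'
#' @param expr log2 CPM matrix.
#' @param ann sample annotation.
#' @param sigma_method `"control"` or `"residual"`.
#' @param floor lower bound applied to each sigma.
#' @return named numeric vector of per-gene sigmas (log2 scale).
#' @export
estimate_sigma <- function(expr, ann,
                           sigma_method = c("control", "residual"),
                           floor = 1e-6) {
  sigma_method <- match.arg(sigma_method)
  ann <- validate_annotation(as.data.frame(ann))
  if (sigma_method == "control") {
    ctl <- ann[ann$is_control, , drop = FALSE]
    groups <- split(ctl$sample_id, ctl$time_h)
  } else {
    trt <- ann[!ann$is_control, , drop = FALSE]
    groups <- split(trt$sample_id,
                    interaction(trt$chemical, trt$concentration_uM,
                                trt$time_h, drop = TRUE))
  }
  small <- vapply(groups, function(ids) length(ids) < 2L, logical(1L))
  if (any(small))
    stop("fewer than 2 replicates for group(s): ",
         paste(names(groups)[small], collapse = ", "))
  sds <- sapply(groups, function(ids)
    apply(expr[, ids, drop = FALSE], 1L, stats::sd))
  sigma <- rowMeans(matrix(sds, nrow = nrow(expr)))
  names(sigma) <- rownames(expr)
  pmax(sigma, floor)
}
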