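#' Weighted isotonic regression of group means (PAVA)
#'
#' Pool-adjacent-violators: the weighted least-squares projection of the
#' ordered group means onto the monotone-nondecreasing cone, with group
#' sizes as weights.  This is the amalgamation step of Williams' trend
#' test.
#'
#' @param group_means ordered numeric vector of group means.
#' @param group_sizes positive weights (replicate counts), same length.
#' @return numeric vector of monotone-nondecreasing fitted means.
#' @export
pava_isotonic_means <- function(group_means, group_sizes) {
  k <- length(group_means)
  if (k == 0L) stop("empty input")
  if (length(group_sizes) != k) stop("means and sizes differ in length")
  if (any(group_sizes <= 0)) stop("group sizes must be positive")
  mean_blk <- numeric(k)
  w_blk <- numeric(k)
  len_blk <- integer(k)
  nb <- 0L
  for (j in seq_len(k)) {
    nb <- nb + 1L
    mean_blk[nb] <- group_means[j]
    w_blk[nb] <- group_sizes[j]
    len_blk[nb] <- 1L
    while (nb > 1L && mean_blk[nb - 1L] > mean_blk[nb]) {
      w <- w_blk[nb - 1L] + w_blk[nb]
      mean_blk[nb - 1L] <- (mean_blk[nb - 1L] * w_blk[nb - 1L] +
                              mean_blk[nb] * w_blk[nb]) / w
      w_blk[nb - 1L] <- w
      len_blk[nb - 1L] <- len_blk[nb - 1L] + len_blk[nb]
      nb <- nb - 1L
    }
  }
  rep(mean_blk[seq_len(nb)], len_blk[seq_len(nb)])
}

#' One-sided Williams' trend test by permutation
#'
#' Tests for a monotone concentration trend: the statistic is
#' `(mu*_K - ybar_0) / (s * sqrt(1/n_K + 1/n_0))` where `mu*_K` is the
#' isotonic (PAVA-amalgamated) mean of the highest dose group, `ybar_0`
#' the control mean and `s^2` the pooled within-group variance.  For
#' `direction = "down"` the data are negated first.  The p-value is a
#' Monte-Carlo permutation p-value over `n_perm` relabellings
#' (`(1 + #{T_perm >= T_obs}) / (n_perm + 1)`), driven by R's RNG so
#' `set.seed()` makes it reproducible.
#'
#' @param control numeric vector of control replicate values (length >= 2).
#' @param dose_groups list of numeric vectors, ascending dose order.
#' @param direction `"up"` or `"down"`.
#' @param n_perm number of permutations (default 999).
#' @return list with `statistic`, `p_value`, `direction`, `n_perm`.
#' @export
williams_test <- function(control, dose_groups, direction = c("up", "down"),
                          n_perm = 999L) {
  direction <- match.arg(direction)
  if (length(control) < 2L) stop("need >= 2 control replicates")
  if (!length(dose_groups)) stop("need >= 1 dose group")
  if (any(vapply(dose_groups, length, 1L) < 1L))
    stop("every dose group needs >= 1 replicate")
  y <- matrix(c(control, unlist(dose_groups)), nrow = 1L)
  sizes <- c(length(control), vapply(dose_groups, length, 1L))
  res <- .williams_perm_cpp(y, as.integer(sizes), as.integer(n_perm))
  if (direction == "up")
    list(statistic = res$stat_up[1L], p_value = res$p_up[1L],
         direction = "up", n_perm = as.integer(n_perm))
  else
    list(statistic = res$stat_down[1L], p_value = res$p_down[1L],
         direction = "down", n_perm = as.integer(n_perm))
}

#' Two-sided Williams' trend test
#'
#' Runs both one-sided tests on the same permutations and combines them by
#' Bonferroni doubling: `p_two = min(1, 2 * min(p_up, p_down))`; the
#' reported direction is the smaller one-sided p (ties go to the larger
#' statistic).
#'
#' @inheritParams williams_test
#' @return list with `statistic` (of the winning direction), `p_value`,
#'   `direction`, `p_up`, `p_down`, `n_perm`.
#' @export
two_sided_williams <- function(control, dose_groups, n_perm = 999L) {
  if (length(control) < 2L) stop("need >= 2 control replicates")
  if (!length(dose_groups)) stop("need >= 1 dose group")
  y <- matrix(c(control, unlist(dose_groups)), nrow = 1L)
  sizes <- c(length(control), vapply(dose_groups, length, 1L))
  res <- .williams_perm_cpp(y, as.integer(sizes), as.integer(n_perm))
  up_wins <- res$p_up[1L] < res$p_down[1L] ||
    (res$p_up[1L] == res$p_down[1L] && res$stat_up[1L] >= res$stat_down[1L])
  list(statistic = if (up_wins) res$stat_up[1L] else res$stat_down[1L],
       p_value = min(1, 2 * min(res$p_up[1L], res$p_down[1L])),
       direction = if (up_wins) "up" else "down",
       p_up = res$p_up[1L], p_down = res$p_down[1L],
       n_perm = as.integer(n_perm))
}

#' Select differentially expressed genes for one chemical
#'
#' Per gene and time point, runs the two-sided permutation Williams' trend
#' test across the ascending concentration groups against the time-matched
#' vehicle controls, and computes the per-concentration log2 fold change
#' versus the control mean.  A gene is retained when, at at least one time
#' point, `p_value < alpha` and `max |log2 fold change| > lfc` (strict).
#' No multiple-testing correction is applied across genes by default
#' (`adjust = "none"`); set `adjust` to a [stats::p.adjust()] method to
#' gate on adjusted p-values instead.
#'
#' Technical and biological replicates are pooled into one test unless
#' `bio_rep` restricts to a single biological replicate.
#'
#' @param expr log2 CPM matrix from [cpm_log2()].
#' @param ann sample annotation.
#' @param chemical chemical to test.
#' @param alpha p-value threshold (default 0.05).
#' @param lfc absolute log2-fold-change threshold (default 1).
#' @param n_perm permutations per test (default 999).
#' @param bio_rep `NULL` to pool biological replicates, or one bio_rep id.
#' @param adjust p-value adjustment method across genes within each time
#'   point (default `"none"`).
#' @return an object of class `"deg_set"`: `chemical`, `gene_ids`
#'   (retained genes), `table` (gene x time test results with columns
#'   gene_id, time_h, statistic, p_value, direction, max_abs_lfc,
#'   retained), `counts_per_time` (Table-1-style per-time DEG counts),
#'   `n_genes_tested`, thresholds.
#' @export
select_degs <- function(expr, ann, chemical, alpha = 0.05, lfc = 1.0,
                        n_perm = 999L, bio_rep = NULL, adjust = "none") {
  ann <- validate_annotation(as.data.frame(ann))
  sub <- ann
  if (!is.null(bio_rep)) sub <- sub[sub$bio_rep %in% bio_rep, , drop = FALSE]
  trt <- sub[!sub$is_control & sub$chemical %in% chemical, , drop = FALSE]
  ctl <- sub[sub$is_control, , drop = FALSE]
  if (!nrow(trt)) stop("no treated samples for chemical '", chemical, "'")
  times <- sort(unique(trt$time_h))
  miss <- setdiff(times, unique(ctl$time_h))
  if (length(miss))
    stop("no vehicle controls at time point(s): ",
         paste(miss, collapse = ", "), " h")
  tabs <- vector("list", length(times))
  for (ti in seq_along(times)) {
    t <- times[ti]
    ctl_ids <- ctl$sample_id[ctl$time_h == t]
    if (length(ctl_ids) < 2L)
      stop("fewer than 2 control replicates at ", t, " h")
    concs <- sort(unique(trt$concentration_uM[trt$time_h == t]))
    grp_ids <- lapply(concs, function(co)
      trt$sample_id[trt$time_h == t & trt$concentration_uM == co])
    sizes <- c(length(ctl_ids), lengths(grp_ids))
    y <- expr[, c(ctl_ids, unlist(grp_ids)), drop = FALSE]
    res <- .williams_perm_cpp(y, as.integer(sizes), as.integer(n_perm))
    up_wins <- res$p_up < res$p_down |
      (res$p_up == res$p_down & res$stat_up >= res$stat_down)
    p <- pmin(1, 2 * pmin(res$p_up, res$p_down))
    p <- stats::p.adjust(p, method = adjust)
    ctl_mean <- rowMeans(expr[, ctl_ids, drop = FALSE])
    lfc_mat <- vapply(grp_ids, function(ids)
      rowMeans(expr[, ids, drop = FALSE]) - ctl_mean,
      numeric(nrow(expr)))
    lfc_mat <- matrix(lfc_mat, nrow = nrow(expr))
    tabs[[ti]] <- data.frame(
      gene_id = rownames(expr), time_h = t,
      statistic = ifelse(up_wins, res$stat_up, res$stat_down),
      p_value = p,
      direction = ifelse(up_wins, "up", "down"),
      max_abs_lfc = apply(abs(lfc_mat), 1L, max),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, tabs)
  tab$retained <- tab$p_value < alpha & tab$max_abs_lfc > lfc
  counts <- tapply(tab$retained, tab$time_h, sum)
  gene_ids <- sort(unique(tab$gene_id[tab$retained]))
  structure(list(chemical = chemical, gene_ids = gene_ids, table = tab,
                 counts_per_time = counts,
                 n_genes_tested = nrow(expr),
                 alpha = alpha, lfc = lfc, n_perm = as.integer(n_perm)),
            class = "deg_set")
}

#' @export
print.deg_set <- function(x, ...) {
  cat("DEG selection for ", x$chemical, ": ", length(x$gene_ids), " of ",
      x$n_genes_tested, " genes retained\n", sep = "")
  cat("  rule: Williams p < ", x$alpha, " and |log2FC| > ", x$lfc,
      " at >= 1 time point\n", sep = "")
  cat("  per-time counts:\n")
  print(x$counts_per_time)
  invisible(x)
}

#' Write a DEG table
#'
#' @param degs a `deg_set` from [select_degs()].
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(degs, path) {
  utils::write.table(degs$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
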