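#' Enumerate the full plate layout of a concentration-time design
#'
#' Expands an [experiment_design()] into one annotation row per sample:
#' for every biological replicate, time point and plate, each chemical at
#' the plate's share of the dilution series (the series is split across
#' `n_plates_per_timepoint` plates, highest concentrations on the first
#' plate) with `n_tech_reps` technical replicates, plus the plate's
#' vehicle controls.  Well positions are permuted independently for each
#' biological replicate (draws from R's RNG; call `set.seed()` first for
#' reproducibility), emulating a layout change between replicates.
#'
#' @param design an [experiment_design()].
#' @return annotation data.frame (see [read_annotation()] for columns)
#'   with `is_control` appended.
#' @export
generate_design <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  conc_per_plate <- design$n_conc / design$n_plates_per_timepoint
  wells_needed <- length(design$chemicals) * conc_per_plate *
    design$n_tech_reps + design$n_controls_per_plate
  all_wells <- paste0(rep(LETTERS[1:8], each = 12L),
                      sprintf("%02d", 1:12))
  if (wells_needed > length(all_wells))
    stop("design needs ", wells_needed, " wells per plate; a 96-well ",
         "plate has 96")
  rows <- vector("list", 0L)
  sid <- 0L
  for (bio in seq_len(design$n_bio_reps)) {
    wells <- sample(all_wells)  # layout changes per biological replicate
    for (t in design$time_points_h) {
      for (pl in seq_len(design$n_plates_per_timepoint)) {
        plate_id <- sprintf("bio%d_t%g_plate%d", bio, t, pl)
        wi <- 0L
        plate_rows <- vector("list", 0L)
        ranks <- (pl - 1L) * conc_per_plate + seq_len(conc_per_plate)
        for (ch in design$chemicals) {
          concs <- design$concentrations_per_chemical[[ch]][ranks]
          for (co in concs) {
            for (tr in seq_len(design$n_tech_reps)) {
              sid <- sid + 1L
              wi <- wi + 1L
              plate_rows[[length(plate_rows) + 1L]] <- data.frame(
                sample_id = sprintf("s%05d", sid), chemical = ch,
                concentration_uM = co, time_h = t, bio_rep = bio,
                tech_rep = tr, plate = plate_id, well = wells[wi],
                stringsAsFactors = FALSE)
            }
          }
        }
        for (ctl in seq_len(design$n_controls_per_plate)) {
          sid <- sid + 1L
          wi <- wi + 1L
          plate_rows[[length(plate_rows) + 1L]] <- data.frame(
            sample_id = sprintf("s%05d", sid), chemical = NA_character_,
            concentration_uM = 0, time_h = t, bio_rep = bio,
            tech_rep = ctl, plate = plate_id, well = wells[wi],
            stringsAsFactors = FALSE)
        }
        rows <- c(rows, plate_rows)
      }
    }
  }
  validate_annotation(do.call(rbind, rows))
}

#' Define a one-factor generative truth
#'
#' Ground truth for end-to-end validation: a parametric common-factor
#' surface, per-gene loadings from an up/down/null mixture, per-gene
#' baseline log2 CPM (rescaled so expected CPMs sum to 1e6), Gaussian
#' log2-scale biological noise, and negative-binomial count noise.
#' Loadings and baselines are drawn from R's RNG; `set.seed()` first.
#'
#' Factor surface forms (`c` in uM, `t` in hours):
#' \describe{
#'   \item{haber}{`f = s * max(0, log10(c * t / k))` — constant
#'     concentration-time product contours, slope -1 in log-log.}
#'   \item{separable}{`f = s * max(0, log10(c / c0)) * (t / t_ref)^b` —
#'     time-independent contours when `b = 0`.}
#'   \item{hill_time}{`f = E * c^n / (c^n + K(t)^n)` with
#'     `K(t) = K0 * (t / t_ref)^(-kt)` decreasing in time.}
#' }
#'
#' @param n_genes number of genes (default 2000).
#' @param factor_form `"haber"`, `"separable"` or `"hill_time"`.
#' @param factor_params named list of surface parameters (defaults:
#'   haber `s = 1, k = 10`; separable `s = 1, c0 = 1, b = 0, t_ref = 48`;
#'   hill_time `E = 2, n = 2, K0 = 5, kt = 0.5, t_ref = 48`).
#' @param fraction_up,fraction_down mixture fractions of up- and
#'   down-regulated genes (the rest are null, loading 0).
#' @param loading_range `c(min, max)` of |loading| for non-null genes.
#' @param baseline_log2cpm_range range of raw baseline draws before the
#'   CPM rescaling.
#' @param noise_sd log2-scale Gaussian noise SD (default 0.1).
#' @param nb_dispersion negative-binomial dispersion (0 gives Poisson).
#' @param library_size expected reads per sample (default 3e6).
#' @return an object of class `"synthetic_truth"`.
#' @export
synthetic_truth <- function(n_genes = 2000L,
                            factor_form = c("haber", "separable",
                                            "hill_time"),
                            factor_params = list(),
                            fraction_up = 0.125, fraction_down = 0.125,
                            loading_range = c(0.3, 1),
                            baseline_log2cpm_range = c(5, 10),
                            noise_sd = 0.1, nb_dispersion = 0.005,
                            library_size = 3e6) {
  factor_form <- match.arg(factor_form)
  defaults <- switch(factor_form,
    haber = list(s = 1, k = 10),
    separable = list(s = 1, c0 = 1, b = 0, t_ref = 48),
    hill_time = list(E = 2, n = 2, K0 = 5, kt = 0.5, t_ref = 48))
  factor_params <- utils::modifyList(defaults, factor_params)
  stopifnot(fraction_up + fraction_down <= 1, noise_sd >= 0,
            nb_dispersion >= 0, library_size > 0,
            loading_range[1L] > 0)
  n_up <- round(n_genes * fraction_up)
  n_down <- round(n_genes * fraction_down)
  w <- c(stats::runif(n_up, loading_range[1L], loading_range[2L]),
         -stats::runif(n_down, loading_range[1L], loading_range[2L]),
         rep(0, n_genes - n_up - n_down))
  w <- w[sample.int(n_genes)]
  b <- stats::runif(n_genes, baseline_log2cpm_range[1L],
                    baseline_log2cpm_range[2L])
  b <- b + log2(1e6 / sum(2^b))  # true CPMs sum to one million
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  structure(list(gene_ids = gene_ids, factor_form = factor_form,
                 factor_params = factor_params, loadings = stats::setNames(w, gene_ids),
                 baseline_log2cpm = stats::setNames(b, gene_ids),
                 noise_sd = noise_sd, nb_dispersion = nb_dispersion,
                 library_size = library_size,
                 fraction_up = fraction_up, fraction_down = fraction_down),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  w <- x$loadings
  cat("synthetic one-factor truth: ", length(w), " genes (",
      sum(w > 0), " up, ", sum(w < 0), " down, ", sum(w == 0),
      " null)\n", sep = "")
  cat("  surface: ", x$factor_form, " (",
      paste(names(x$factor_params), unlist(x$factor_params), sep = "=",
            collapse = ", "), ")\n", sep = "")
  cat("  noise_sd ", x$noise_sd, ", NB dispersion ", x$nb_dispersion,
      ", library size ", format(x$library_size, big.mark = ","), "\n",
      sep = "")
  invisible(x)
}

#' Evaluate the true factor surface
#'
#' @param truth a [synthetic_truth()].
#' @param conc,time vectors of concentrations (uM) and times (h),
#'   recycled against each other.
#' @return numeric vector of true common-factor responses.
#' @export
truth_factor <- function(truth, conc, time) {
  p <- truth$factor_params
  switch(truth$factor_form,
    haber = p$s * pmax(0, log10(conc * time / p$k)),
    separable = p$s * pmax(0, log10(conc / p$c0)) * (time / p$t_ref)^p$b,
    hill_time = {
      K <- p$K0 * (time / p$t_ref)^(-p$kt)
      p$E * conc^p$n / (conc^p$n + K^p$n)
    })
}

#' Simulate a count matrix from a one-factor truth
#'
#' Per gene and sample: mean log2 CPM = baseline + w_g * f(c, t)
#' (controls: baseline) plus Gaussian log2-scale noise of SD `noise_sd`;
#' the implied CPM is converted to an expected read count via the library
#' size, and the observed count is drawn negative-binomial with the
#' configured dispersion (Poisson when dispersion is 0).  Uses R's RNG:
#' `set.seed()` makes runs identical.
#'
#' @param truth a [synthetic_truth()].
#' @param ann design annotation from [generate_design()].
#' @return list with `counts` (genes x samples integer matrix), `ann`,
#'   and `truth`.
#' @export
simulate_counts <- function(truth, ann) {
  stopifnot(inherits(truth, "synthetic_truth"))
  ann <- validate_annotation(as.data.frame(ann))
  f <- numeric(nrow(ann))
  trt <- !ann$is_control
  f[trt] <- truth_factor(truth, ann$concentration_uM[trt], ann$time_h[trt])
  ng <- length(truth$gene_ids)
  ns <- nrow(ann)
  m <- truth$baseline_log2cpm + outer(truth$loadings, f)
  if (truth$noise_sd > 0)
    m <- m + matrix(stats::rnorm(ng * ns, 0, truth$noise_sd), ng, ns)
  mu <- 2^m * truth$library_size / 1e6
  counts <- if (truth$nb_dispersion > 0)
    stats::rnbinom(ng * ns, mu = mu, size = 1 / truth$nb_dispersion)
  else stats::rpois(ng * ns, mu)
  counts <- matrix(as.integer(counts), ng, ns,
                   dimnames = list(truth$gene_ids, ann$sample_id))
  list(counts = counts, ann = ann, truth = truth)
}

#' Expected total log2-scale noise SD per gene
#'
#' The generative per-gene SD of a control sample's log2 CPM, combining
#' the Gaussian log2-scale noise with the delta-method count-noise
#' contribution: `sqrt(noise_sd^2 + (1/mu + dispersion) / ln(2)^2)` with
#' `mu` the gene's expected control count.  This is the quantity the
#' control-based [estimate_sigma()] estimates, and the honest sigma to
#' use when matching an analytic contour to pipeline output.
#'
#' @param truth a [synthetic_truth()].
#' @return named per-gene numeric vector.
#' @export
effective_sigma <- function(truth) {
  mu <- 2^truth$baseline_log2cpm * truth$library_size / 1e6
  sqrt(truth$noise_sd^2 + (1 / mu + truth$nb_dispersion) / log(2)^2)
}

#' Analytic isoBMR contour of the true surface
#'
#' Exact level set of the generative factor surface, the oracle against
#' which pipeline-extracted curves are compared.
#'
#' @param truth a [synthetic_truth()].
#' @param level positive level on the true surface.
#' @param times time points (h) at which to evaluate the contour.
#' @param conc_range concentrations (uM) bracketing the numeric root
#'   search for the `hill_time` form.
#' @return an `"isobmr_curve"` (times with no crossing are omitted).
#' @export
analytic_iso_curve <- function(truth, level,
                               times = 10^seq(log10(2), log10(48),
                                              length.out = 200L),
                               conc_range = c(1e-6, 1e6)) {
  stopifnot(inherits(truth, "synthetic_truth"), level > 0)
  p <- truth$factor_params
  lc <- switch(truth$factor_form,
    haber = level / p$s + log10(p$k) - log10(times),
    separable = {
      h <- (times / p$t_ref)^p$b
      out <- level / (p$s * h) + log10(p$c0)
      out
    },
    hill_time = {
      vapply(times, function(t) {
        g <- function(c) truth_factor(truth, c, t) - level
        if (g(conc_range[1L]) > 0 || g(conc_range[2L]) < 0)
          return(NA_real_)
        log10(stats::uniroot(g, conc_range, tol = 1e-10)$root)
      }, numeric(1L))
    })
  keep <- is.finite(lc)
  out <- data.frame(time_h = times[keep], conc_uM = 10^lc[keep],
                    log10_time = log10(times[keep]), log10_conc = lc[keep],
                    multi = FALSE)
  structure(out, level = level, kind = "analytic", q_or_gene = NA,
            class = c("isobmr_curve", "data.frame"))
}
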