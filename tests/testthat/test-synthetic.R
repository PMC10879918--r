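test_that("small designs enumerate exactly (4 conc x 3 tech + 6 controls)", {
  des <- experiment_design(chemicals = "c1", top_conc_uM = 50, n_conc = 4,
                           time_points_h = 24, n_bio_reps = 1,
                           n_tech_reps = 3, n_controls_per_plate = 6,
                           n_plates_per_timepoint = 1)
  set.seed(1)
  ann <- generate_design(des)
  expect_identical(nrow(ann), 18L)
  expect_identical(sum(ann$is_control), 6L)
  expect_identical(length(unique(ann$well)), 18L)
})

test_that("designs that overflow a 96-well plate are refused", {
  des <- experiment_design(chemicals = paste0("c", 1:9), top_conc_uM = 50,
                           n_conc = 8, n_plates_per_timepoint = 2)
  expect_error(generate_design(des), "96")
})

test_that("simulation is reproducible from the seed", {
  des <- tiny_design(n_bio_reps = 1, time_points_h = c(2, 24))
  set.seed(5); ann1 <- generate_design(des)
  set.seed(5); ann2 <- generate_design(des)
  expect_identical(ann1, ann2)
  set.seed(6); truth1 <- synthetic_truth(n_genes = 50)
  set.seed(6); truth2 <- synthetic_truth(n_genes = 50)
  expect_identical(truth1, truth2)
  set.seed(7); s1 <- simulate_counts(truth1, ann1)
  set.seed(7); s2 <- simulate_counts(truth2, ann2)
  expect_identical(s1$counts, s2$counts)
})

test_that("noise-free Poisson counts have the configured expectations", {
  des <- tiny_design(n_bio_reps = 1, n_tech_reps = 3,
                     time_points_h = c(2, 24))
  set.seed(8)
  ann <- generate_design(des)
  truth <- synthetic_truth(n_genes = 400, noise_sd = 0,
                           nb_dispersion = 0, library_size = 1e6)
  sim <- simulate_counts(truth, ann)
  # a null gene's control-sample counts are Poisson around its baseline
  null_g <- names(truth$loadings)[truth$loadings == 0][1]
  mu <- 2^truth$baseline_log2cpm[null_g]
  obs <- sim$counts[null_g, ann$sample_id[ann$is_control]]
  expect_lt(abs(mean(obs) - mu), 4 * sqrt(mu / length(obs)))
})

test_that("per-sample totals match the configured library size on controls", {
  des <- tiny_design(n_bio_reps = 1, n_tech_reps = 1,
                     time_points_h = c(2, 24))
  set.seed(9)
  ann <- generate_design(des)
  truth <- synthetic_truth(n_genes = 500, noise_sd = 0.05,
                           nb_dispersion = 0.005, library_size = 1e6)
  sim <- simulate_counts(truth, ann)
  ctl <- ann$sample_id[ann$is_control]
  totals <- colSums(sim$counts[, ctl])
  # variance of a total: sum over genes of mu + disp * mu^2, inflated by
  # the log-normal noise factor
  mu <- 2^truth$baseline_log2cpm
  infl <- exp((0.05 * log(2))^2)
  v <- sum(mu * infl + (truth$nb_dispersion + infl - 1) * mu^2 * infl)
  expect_true(all(abs(totals - 1e6) < 5 * sqrt(v) + 0.01 * 1e6))
})

test_that("realised top-dose fold changes recover the injected effect", {
  des <- tiny_design(n_bio_reps = 3, n_tech_reps = 3, time_points_h = 48)
  set.seed(10)
  ann <- generate_design(des)
  truth <- synthetic_truth(n_genes = 300, fraction_up = 0.05,
                           fraction_down = 0.05)
  sim <- simulate_counts(truth, ann)
  expr <- cpm_log2(sim$counts)
  g <- names(which(truth$loadings > 0.8))[1]
  top <- ann$sample_id[!ann$is_control &
                         ann$concentration_uM == max(ann$concentration_uM)]
  ctl <- ann$sample_id[ann$is_control]
  lfc <- mean(expr[g, top]) - mean(expr[g, ctl])
  want <- truth$loadings[[g]] * truth_factor(truth, 50, 48)
  se <- effective_sigma(truth)[[g]] * sqrt(1 / 9 + 1 / length(ctl))
  expect_lt(abs(lfc - want), 3 * se + 0.05)
})

test_that("null genes reach the Williams p-gate at close to the nominal
           rate on all-null data", {
  des <- tiny_design(n_bio_reps = 2, n_tech_reps = 2,
                     time_points_h = c(6, 24))
  set.seed(12)
  ann <- generate_design(des)
  truth <- synthetic_truth(n_genes = 1000, fraction_up = 0,
                           fraction_down = 0)
  sim <- simulate_counts(truth, ann)
  expr <- cpm_log2(filter_low_expression(sim$counts, 10))
  set.seed(13)
  degs <- select_degs(expr, sim$ann, "chemA", n_perm = 199, lfc = 0)
  rate <- mean(degs$table$p_value < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("analytic contours obey their closed forms", {
  truth <- synthetic_truth(n_genes = 10, factor_form = "haber",
                           factor_params = list(s = 2, k = 5))
  cur <- analytic_iso_curve(truth, level = 1, times = c(2, 4, 8, 16))
  expect_equal(cur$log10_conc, 1 / 2 + log10(5) - log10(cur$time_h),
               tolerance = 1e-12)
  # doubling time halves concentration
  expect_equal(cur$conc_uM[2], cur$conc_uM[1] / 2, tolerance = 1e-9)
  sep <- synthetic_truth(n_genes = 10, factor_form = "separable",
                         factor_params = list(s = 1, c0 = 2, b = 0))
  cs <- analytic_iso_curve(sep, level = 0.7, times = c(2, 24, 48))
  expect_equal(cs$conc_uM, rep(2 * 10^0.7, 3), tolerance = 1e-9)
})

test_that("hill_time analytic contour matches a dense root scan", {
  truth <- synthetic_truth(n_genes = 10, factor_form = "hill_time",
                           factor_params = list(E = 2, n = 2, K0 = 5,
                                                kt = 0.5, t_ref = 48))
  times <- c(2, 6, 12, 24, 48)
  cur <- analytic_iso_curve(truth, level = 0.8, times = times)
  for (i in seq_len(nrow(cur))) {
    cgrid <- 10^seq(-4, 4, length.out = 2e5)
    fv <- truth_factor(truth, cgrid, cur$time_h[i])
    j <- which(fv >= 0.8)[1]
    expect_equal(cur$log10_conc[i], log10(cgrid[j]), tolerance = 1e-3)
  }
})

test_that("effective sigma matches the empirical control SD", {
  des <- tiny_design(n_bio_reps = 3, n_tech_reps = 3,
                     n_controls_per_plate = 6)
  set.seed(14)
  ann <- generate_design(des)
  truth <- synthetic_truth(n_genes = 300)
  sim <- simulate_counts(truth, ann)
  expr <- cpm_log2(sim$counts)
  sig_hat <- estimate_sigma(expr, ann)
  sig_true <- effective_sigma(truth)
  expect_equal(mean(sig_hat), mean(sig_true), tolerance = 0.05)
  expect_equal(stats::median(sig_hat), stats::median(sig_true),
               tolerance = 0.05)
})
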