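conc8 <- 50 / 2.5^(7:0)
time5 <- c(2, 6, 12, 24, 48)

# rank-1 model with loadings exactly w: surfaces w_g * f, ||f|| = 1
model_with_loadings <- function(w, kink = TRUE) {
  f <- outer(log10(conc8), log10(time5), "+") - log10(10)
  if (kink) f <- pmax(f, 0)
  f <- f / sqrt(sum(f^2))
  fit_factor_model(rank1_set(w, f, conc8, time5))
}

test_that("the median level reproduces the forced arithmetic example", {
  m <- model_with_loadings(c(1, 2, 4))
  sigma <- c(g001 = 1, g002 = 1, g003 = 1)
  lev <- gene_levels(m, sigma, bmr_factor = 1.349)
  expect_equal(sort(unname(lev)), c(0.337250, 0.674500, 1.349000),
               tolerance = 1e-9)
  expect_equal(compute_level_median(m, sigma), 0.6745, tolerance = 1e-12)
  # identical genes: v = 1.349 * s
  m2 <- model_with_loadings(c(2, 2, 2))
  s2 <- c(g001 = 0.4, g002 = 0.4, g003 = 0.4)
  expect_equal(compute_level_median(m2, s2), 1.349 * 0.4 / 2,
               tolerance = 1e-12)
})

test_that("percentile levels follow the documented quantile rule and are
           monotone", {
  set.seed(401)
  w <- runif(1001, 0.2, 3)
  m <- model_with_loadings(w)
  sigma <- stats::setNames(runif(1001, 0.05, 0.5), m$gene_ids)
  lev <- gene_levels(m, sigma)
  # sort-based median oracle
  srt <- sort(unname(lev))
  expect_equal(compute_level_median(m, sigma), srt[501], tolerance = 1e-12)
  expect_equal(compute_level_percentile(m, sigma, 50),
               compute_level_median(m, sigma), tolerance = 1e-12)
  # type-7 rule on a known ladder
  m10 <- model_with_loadings(rep(1, 10))
  s10 <- stats::setNames((1:10) / 1.349, m10$gene_ids)
  expect_equal(compute_level_percentile(m10, s10, 10), 1.9,
               tolerance = 1e-9)
  qs <- sapply(c(10, 25, 50, 75, 90), function(q)
    compute_level_percentile(m, sigma, q))
  expect_true(all(diff(qs) >= 0))
  expect_error(compute_level_percentile(m, sigma, 0), "strictly between")
})

test_that("level sets of separable and Haber planes match closed forms", {
  # concentration-only surface: f = log10(c / c0), c0 = 1
  fsep <- matrix(log10(conc8), 8, 5)
  ssep <- smooth_surface(fsep, conc8, time5, rho = 1)
  cur <- extract_iso_curve(ssep, level = 0.5, n_times = 50)
  expect_equal(cur$conc_uM, rep(10^0.5, nrow(cur)), tolerance = 1e-4)
  # Haber plane: f = log10(c t / k), contour slope -1 in log-log
  k <- 10
  fhab <- outer(log10(conc8), log10(time5), "+") - log10(k)
  shab <- smooth_surface(fhab, conc8, time5, rho = 1)
  cur2 <- extract_iso_curve(shab, level = 0.5, n_times = 80)
  want <- 0.5 + log10(k) - cur2$log10_time
  expect_equal(cur2$log10_conc, want, tolerance = 1e-4)
  expect_equal(curve_slope(cur2), -1, tolerance = 1e-3)
})

test_that("bisection matches a dense scan on a curved monotone surface", {
  f <- outer(log10(conc8)^2 + log10(conc8), log10(time5) / 2, "+")
  s <- smooth_surface(f, conc8, time5, rho = 1)
  lev <- 2.0
  cur <- extract_iso_curve(s, lev, n_times = 12)
  for (i in seq_len(nrow(cur))) {
    lc_dense <- seq(log10(min(conc8)), log10(max(conc8)),
                    length.out = 1e5)
    fv <- evaluate_surface(s, cbind(10^lc_dense,
                                    rep(cur$time_h[i], 1e5)))
    j <- which(fv >= lev)[1]
    expect_equal(cur$log10_conc[i], lc_dense[j], tolerance = 1e-4)
    # emitted point satisfies the level equation (independent re-check)
    expect_lt(abs(evaluate_surface(
      s, cbind(cur$conc_uM[i], cur$time_h[i])) - lev), 1e-4)
  }
})

test_that("a level above the surface yields an empty, reported curve", {
  m <- model_with_loadings(c(1, 1.5))
  cur <- extract_iso_curve(m, level = 100)
  expect_identical(nrow(cur), 0L)
  expect_error(bmc_at_time(cur, 24), "empty")
})

test_that("gene curves reproduce the median curve and order by sensitivity", {
  set.seed(402)
  w <- c(0.5, 1, 2)
  m <- model_with_loadings(w, kink = FALSE)
  sigma <- stats::setNames(rep(0.1, 3), m$gene_ids)
  lev <- gene_levels(m, sigma)
  med_gene <- names(sort(lev))[2]
  cur_med <- extract_iso_curve(m, compute_level_median(m, sigma))
  cur_gene <- gene_iso_curve(m, sigma, med_gene)
  expect_equal(cur_gene$log10_conc, cur_med$log10_conc, tolerance = 1e-9)
  # the large-|w| gene is most sensitive: lowest level, lowest curve
  cur_lo <- gene_iso_curve(m, sigma, m$gene_ids[which.max(abs(w))])
  cur_hi <- gene_iso_curve(m, sigma, m$gene_ids[which.min(abs(w))])
  shared <- intersect(cur_lo$time_h, cur_hi$time_h)
  expect_true(all(cur_lo$conc_uM[match(shared, cur_lo$time_h)] <
                    cur_hi$conc_uM[match(shared, cur_hi$time_h)]))
})

test_that("gene-specific curves on one model never cross", {
  set.seed(403)
  w <- runif(12, 0.5, 3) * sample(c(-1, 1), 12, replace = TRUE)
  m <- model_with_loadings(w)
  sigma <- stats::setNames(runif(12, 0.05, 0.15), m$gene_ids)
  curves <- lapply(m$gene_ids, function(g)
    gene_iso_curve(m, sigma, g, n_times = 60))
  for (i in seq_along(curves)) {
    for (j in seq_len(i - 1L)) {
      a <- curves[[i]]; b <- curves[[j]]
      shared <- intersect(a$time_h, b$time_h)
      if (length(shared) < 2) next
      d <- a$log10_conc[match(shared, a$time_h)] -
        b$log10_conc[match(shared, b$time_h)]
      expect_true(all(d >= -1e-7) || all(d <= 1e-7))
    }
  }
})

test_that("BMC projection interpolates log-linearly and halves along a
           Haber line", {
  k <- 10
  fhab <- outer(log10(conc8), log10(time5), "+") - log10(k)
  s <- smooth_surface(fhab, conc8, time5, rho = 1)
  cur <- extract_iso_curve(s, 0.5)
  # node time returns the node concentration
  i <- 57
  expect_equal(bmc_at_time(cur, cur$time_h[i]), cur$conc_uM[i],
               tolerance = 1e-9)
  expect_equal(bmc_at_time(cur, 24), bmc_at_time(cur, 12) / 2,
               tolerance = 1e-3)
  expect_error(bmc_at_time(cur, 96), "outside the curve span")
  # power-law tail extrapolation continues slope -1
  expect_equal(bmc_at_time(cur, 96, extrapolate = TRUE),
               bmc_at_time(cur, 48) / 2, tolerance = 1e-3)
})

test_that("percentile curves are nested and replicate curves reproducible", {
  set.seed(404)
  w <- runif(40, 0.3, 2)
  m <- model_with_loadings(w)
  sigma <- stats::setNames(runif(40, 0.1, 0.3), m$gene_ids)
  rep_models <- list(r1 = m, r2 = m)
  tab <- curve_set_report(m, sigma, replicate_models = rep_models,
                          percentiles = c(10, 50, 90), n_times = 40)
  q10 <- tab[tab$curve_kind == "percentile" & tab$q_or_gene == "10", ]
  q90 <- tab[tab$curve_kind == "percentile" & tab$q_or_gene == "90", ]
  shared <- intersect(q10$time_h, q90$time_h)
  expect_true(all(q10$conc_uM[match(shared, q10$time_h)] <=
                    q90$conc_uM[match(shared, q90$time_h)] + 1e-9))
  r1 <- tab[tab$curve_kind == "replicate" & tab$q_or_gene == "r1", ]
  r2 <- tab[tab$curve_kind == "replicate" & tab$q_or_gene == "r2", ]
  expect_equal(r1$conc_uM, r2$conc_uM, tolerance = 1e-12)
})

test_that("replicate median curves from one truth stay tightly grouped", {
  sim <- tiny_sim(seed = 44, n_genes = 200, noise_sd = 0.05)
  set.seed(45)
  fit <- isobmr_fit(sim$counts, sim$ann, "chemA", n_perm = 99,
                    n_times = 60)
  reps <- fit$curves[fit$curves$curve_kind == "replicate", ]
  spread <- tapply(reps$log10_conc, reps$time_h,
                   function(x) max(x) - min(x))
  expect_lt(stats::median(spread), 3 * 0.05)
})
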