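test_that("PAVA leaves monotone input unchanged and pools violators", {
  expect_equal(pava_isotonic_means(c(1, 2, 3), c(1, 1, 1)), c(1, 2, 3))
  expect_equal(pava_isotonic_means(c(3, 1), c(1, 1)), c(2, 2))
  expect_equal(pava_isotonic_means(c(3, 1), c(3, 1)), c(2.5, 2.5))
  expect_error(pava_isotonic_means(numeric(0), numeric(0)), "empty")
})

test_that("PAVA equals the exhaustive block-partition oracle", {
  set.seed(91)
  for (i in 1:25) {
    k <- 6
    means <- rnorm(k)
    sizes <- sample(1:4, k, replace = TRUE)
    fit <- pava_isotonic_means(means, sizes)
    expect_equal(fit, pava_oracle(means, sizes), tolerance = 1e-10)
    # output monotone, weighted mean preserved
    expect_true(all(diff(fit) >= -1e-12))
    expect_equal(sum(fit * sizes), sum(means * sizes), tolerance = 1e-10)
  }
})

test_that("PAVA matches stats::isoreg for equal weights", {
  set.seed(92)
  y <- rnorm(8)
  expect_equal(pava_isotonic_means(y, rep(1, 8)), stats::isoreg(y)$yf,
               tolerance = 1e-12)
})

test_that("flat zero-variance data give p = 1; strong trends reach the
           permutation floor", {
  set.seed(101)
  flat <- williams_test(c(0, 0, 0), rep(list(c(0, 0, 0)), 7), n_perm = 99)
  expect_equal(flat$p_value, 1)
  set.seed(102)
  doses <- lapply(1:8, function(d) d + rnorm(3, 0, 1e-3))
  strong <- williams_test(rnorm(3, 0, 1e-3), doses, n_perm = 999)
  expect_equal(strong$p_value, 1 / 1000)   # 1/(n_perm + 1) floor
  # zero pooled variance with unequal means maps to the floor
  set.seed(103)
  sep <- williams_test(c(0, 0, 0), list(c(1, 1, 1)), n_perm = 99)
  expect_equal(sep$p_value, 1 / 100)
  expect_true(is.infinite(sep$statistic))
})

test_that("the statistic is shift-invariant and direction-symmetric,
           with seed-reproducible permutation p-values", {
  set.seed(111)
  ctrl <- rnorm(3)
  doses <- lapply(1:5, function(d) rnorm(3, 0.3 * d))
  set.seed(1); a <- williams_test(ctrl, doses, n_perm = 199)
  set.seed(1); b <- williams_test(ctrl + 7, lapply(doses, `+`, 7),
                                  n_perm = 199)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_identical(a$p_value, b$p_value)
  set.seed(2); dn <- williams_test(-ctrl, lapply(doses, `-`),
                                   direction = "down", n_perm = 199)
  set.seed(2); up <- williams_test(ctrl, doses, "up", n_perm = 199)
  expect_equal(dn$statistic, up$statistic, tolerance = 1e-12)
  expect_identical(dn$p_value, up$p_value)
  expect_true(a$p_value >= 1 / 200 && a$p_value <= 1)
})

test_that("the two-sided test doubles the smaller one-sided p, capped at 1", {
  set.seed(121)
  r <- two_sided_williams(rnorm(3), lapply(1:4, function(i) rnorm(3)),
                          n_perm = 199)
  expect_equal(r$p_value, min(1, 2 * min(r$p_up, r$p_down)))
  expect_true(r$direction %in% c("up", "down"))
  # decreasing trend is detected with direction = down
  set.seed(122)
  dec <- two_sided_williams(rnorm(3, 0, 0.05),
                            lapply(1:6, function(d) rnorm(3, -0.8 * d, 0.05)),
                            n_perm = 499)
  expect_identical(dec$direction, "down")
  expect_lt(dec$p_value, 0.01)
})

test_that("two-sided type-I error is calibrated under a Gaussian null", {
  # 8 dose groups + control, n = 3 each; quick 600-replicate check
  set.seed(131)
  nrep <- 600
  y <- matrix(rnorm(nrep * 27), nrep, 27)
  res <- isobmr:::.williams_perm_cpp(y, rep(3L, 9), 399L)
  p <- pmin(1, 2 * pmin(res$p_up, res$p_down))
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("DEG selection applies the conjunctive p/fold-change rule", {
  # strong but small-amplitude monotone trend: significant p, |lfc| 0.5
  des <- tiny_design(n_bio_reps = 1, n_tech_reps = 3,
                     time_points_h = c(2, 24))
  set.seed(141)
  ann <- generate_design(des)
  ng <- 6
  expr <- matrix(rnorm(ng * nrow(ann), 8, 0.02), ng, nrow(ann),
                 dimnames = list(sprintf("g%d", 1:ng), ann$sample_id))
  trt <- !ann$is_control
  shift <- 0.5 * (log10(ann$concentration_uM[trt]) -
                    log10(min(ann$concentration_uM[trt]))) /
    (log10(max(ann$concentration_uM[trt])) -
       log10(min(ann$concentration_uM[trt])))
  expr["g1", ann$sample_id[trt]] <- expr["g1", ann$sample_id[trt]] + shift
  expr["g2", ann$sample_id[trt]] <- expr["g2", ann$sample_id[trt]] +
    4 * shift
  set.seed(142)
  degs <- select_degs(expr, ann, "chemA", n_perm = 199)
  tab1 <- degs$table[degs$table$gene_id == "g1", ]
  expect_true(any(tab1$p_value < 0.05))        # significant trend
  expect_true(all(tab1$max_abs_lfc < 1))       # but small amplitude
  expect_false("g1" %in% degs$gene_ids)        # hence excluded
  expect_true("g2" %in% degs$gene_ids)         # large amplitude retained
  expect_identical(unname(degs$counts_per_time[length(degs$counts_per_time)]),
                   sum(degs$table$retained & degs$table$time_h == 24))
})

test_that("DEG selection recovers injected effects with controlled false
           positives", {
  # 50 true monotone genes (|lfc| ~ 2 at top dose) among 450 nulls
  des <- tiny_design(n_bio_reps = 3, n_tech_reps = 3,
                     time_points_h = c(6, 24))
  set.seed(151)
  ann <- generate_design(des)
  truth <- synthetic_truth(n_genes = 500, fraction_up = 0.05,
                           fraction_down = 0.05,
                           loading_range = c(0.82, 0.86),
                           noise_sd = 0.1)
  sim <- simulate_counts(truth, ann)
  expr <- cpm_log2(filter_low_expression(sim$counts, 10))
  set.seed(152)
  degs <- select_degs(expr, sim$ann, "chemA", n_perm = 199)
  true_de <- names(truth$loadings)[truth$loadings != 0]
  true_de <- intersect(true_de, rownames(expr))
  found <- intersect(degs$gene_ids, true_de)
  expect_gte(length(found), 0.9 * length(true_de))
  false_pos <- setdiff(degs$gene_ids, true_de)
  # conjunctive rule keeps the false-positive count far below alpha * nulls
  expect_lte(length(false_pos), 0.05 * (nrow(expr) - length(true_de)) + 10)
})
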