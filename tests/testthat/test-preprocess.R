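make_counts <- function(vals, ng, ns) {
  m <- matrix(vals, ng, ns,
              dimnames = list(sprintf("g%03d", seq_len(ng)),
                              sprintf("s%03d", seq_len(ns))))
  storage.mode(m) <- "integer"
  m
}

test_that("mean-read filter is inclusive at the threshold and idempotent", {
  # gene means 9.99 (below), 10 (at), 250 (above) across 100 samples
  m <- make_counts(0L, 3, 100)
  m[1, ] <- c(rep(10L, 99), 9L)      # mean 9.99
  m[2, ] <- 10L                      # mean 10
  m[3, ] <- 250L                     # mean 250
  kept <- filter_low_expression(m, 10)
  expect_identical(rownames(kept), c("g002", "g003"))
  expect_identical(filter_low_expression(m, 0), m)
  expect_identical(filter_low_expression(kept, 10), kept)
  expect_error(filter_low_expression(m, 1e9), "threshold")
})

test_that("filter agrees with an independent per-gene mean loop", {
  set.seed(21)
  lambda <- runif(500, 5, 20)     # gene means straddle the threshold
  m <- make_counts(rpois(500 * 60, rep(lambda, 60)), 500, 60)
  kept <- rownames(filter_low_expression(m, 10))
  brute <- character(0)
  for (g in rownames(m)) {
    s <- 0
    for (j in seq_len(ncol(m))) s <- s + m[g, j]
    if (s / ncol(m) >= 10) brute <- c(brute, g)
  }
  expect_identical(kept, brute)
})

test_that("log2 CPM matches forced arithmetic and a naive reimplementation", {
  m <- make_counts(c(1L, 1L), 2, 1)
  e <- cpm_log2(m)
  expect_equal(unname(e[, 1]), rep(log2(5e5 + 1), 2), tolerance = 1e-12)
  m2 <- make_counts(c(0L, 4L), 2, 1)
  expect_equal(cpm_log2(m2)["g001", 1], 0.0)   # log2(0 + 1)
  set.seed(5)
  m3 <- make_counts(rpois(200, 20), 20, 10)
  e3 <- cpm_log2(m3, pseudocount = 1)
  brute <- e3
  for (g in seq_len(20)) for (s in seq_len(10))
    brute[g, s] <- log2(m3[g, s] / sum(m3[, s]) * 1e6 + 1)
  expect_equal(e3, brute, tolerance = 1e-12)
  m0 <- make_counts(0L, 2, 2)
  expect_error(cpm_log2(m0), "s001")
})

test_that("log2 CPM is invariant to integer scaling of a sample when
           pseudocount is 0", {
  set.seed(6)
  m <- make_counts(rpois(50, 30) + 1L, 10, 5)
  m2 <- m
  m2[, 3] <- m2[, 3] * 7L
  expect_equal(cpm_log2(m, pseudocount = 0),
               cpm_log2(m2, pseudocount = 0), tolerance = 1e-12)
})

test_that("condition means average replicates and match brute-force group-by", {
  sim <- tiny_sim(seed = 31, n_genes = 40,
                  des = tiny_design(n_bio_reps = 2, n_tech_reps = 2,
                                    time_points_h = c(2, 24)))
  expr <- cpm_log2(sim$counts)
  cm <- condition_means(expr, sim$ann, "chemA")
  trt <- sim$ann[!sim$ann$is_control, ]
  for (ci in seq_along(cm$conc_grid)) {
    for (ti in seq_along(cm$time_grid)) {
      ids <- trt$sample_id[trt$concentration_uM == cm$conc_grid[ci] &
                             trt$time_h == cm$time_grid[ti]]
      expect_identical(cm$n[ci, ti], length(ids))
      expect_equal(cm$values[, ci, ti],
                   apply(expr[, ids, drop = FALSE], 1, mean),
                   tolerance = 1e-12)
    }
  }
  # two replicates 1.0 and 3.0 average to 2.0 (n recorded)
  e2 <- expr[, 1:2]
  e2[1, ] <- c(1, 3)
  a2 <- sim$ann[match(colnames(e2), sim$ann$sample_id), ]
  a2$chemical <- "x"; a2$concentration_uM <- 1; a2$time_h <- 2
  a2$bio_rep <- 1; a2$tech_rep <- 1:2; a2$is_control <- FALSE
  cm2 <- condition_means(e2, a2, "x")
  expect_equal(unname(cm2$values[1, 1, 1]), 2.0)
})

test_that("vehicle subtraction is exact and zero against itself", {
  sim <- tiny_sim(seed = 32, n_genes = 30,
                  des = tiny_design(n_bio_reps = 1, n_tech_reps = 2,
                                    time_points_h = c(2, 24)))
  expr <- cpm_log2(sim$counts)
  cm <- condition_means(expr, sim$ann, "chemA")
  ctrl <- control_means(expr, sim$ann)
  rs <- subtract_vehicle(cm, ctrl)
  expect_s3_class(rs, "response_set")
  expect_equal(rs$values[, 3, 2],
               cm$values[, 3, 2] - ctrl[, "24"], tolerance = 1e-12)
  # treated == control implies response identically zero
  cm0 <- cm
  for (ti in seq_along(cm$time_grid))
    cm0$values[, , ti] <- matrix(ctrl[, as.character(cm$time_grid[ti])],
                                 nrow(expr), length(cm$conc_grid))
  rs0 <- subtract_vehicle(cm0, ctrl)
  expect_equal(max(abs(rs0$values)), 0)
  # missing control time point errors
  ctrl2 <- ctrl[, 1, drop = FALSE]
  expect_error(subtract_vehicle(cm, ctrl2), "24")
})

test_that("sigma is the time-averaged control-replicate SD with a floor", {
  ann <- generate_design(tiny_design(n_bio_reps = 1, n_tech_reps = 1,
                                     time_points_h = c(2, 24)))
  ctl_ids <- ann$sample_id[ann$is_control]
  expr <- matrix(5, 2, nrow(ann),
                 dimnames = list(c("g1", "g2"), ann$sample_id))
  # identical controls -> floored sigma
  s <- estimate_sigma(expr, ann, floor = 1e-6)
  expect_equal(unname(s), c(1e-6, 1e-6))
  # per-time SD exactly 1 at both times -> sigma 1
  for (t in c(2, 24)) {
    ids <- ann$sample_id[ann$is_control & ann$time_h == t]
    expr["g1", ids] <- 5 + scale(seq_along(ids))[, 1] # sd 1 by construction
  }
  s2 <- estimate_sigma(expr, ann)
  expect_equal(unname(s2["g1"]), 1.0, tolerance = 1e-12)
})

test_that("sigma estimate is consistent with the c4-corrected truth", {
  # 6 controls x 5 times x 200 genes, true SD 0.5: the mean per-time
  # sample SD estimates 0.5 * c4(6)
  set.seed(77)
  des <- tiny_design(n_bio_reps = 1, n_tech_reps = 1,
                     n_controls_per_plate = 3)  # 3 x 2 plates = 6 per time
  ann <- generate_design(des)
  ng <- 200
  expr <- matrix(rnorm(ng * nrow(ann), 0, 0.5), ng, nrow(ann),
                 dimnames = list(sprintf("g%03d", 1:ng), ann$sample_id))
  s <- estimate_sigma(expr, ann)
  n <- 6
  c4 <- sqrt(2 / (n - 1)) * gamma(n / 2) / gamma((n - 1) / 2)
  expect_equal(mean(s), 0.5 * c4, tolerance = 0.05 * 0.5 * c4)
})

test_that("sigma estimation demands replicated controls", {
  ann <- generate_design(tiny_design(n_bio_reps = 1, n_tech_reps = 1,
                                     n_controls_per_plate = 6,
                                     n_plates_per_timepoint = 1))
  ann <- ann[!(ann$is_control & ann$time_h == 2 & ann$tech_rep > 1), ]
  expr <- matrix(5, 1, nrow(ann),
                 dimnames = list("g1", ann$sample_id))
  expect_error(estimate_sigma(expr, ann), "fewer than 2")
})
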