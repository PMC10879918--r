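# Shared in-code fixtures: small synthetic experiments and hand-built
# rank-1 response sets.  Everything is generated at test time.

tiny_design <- function(chemicals = "chemA", top_conc_uM = 50,
                        n_bio_reps = 3, n_tech_reps = 3,
                        time_points_h = c(2, 6, 12, 24, 48), ...) {
  experiment_design(chemicals = chemicals, top_conc_uM = top_conc_uM,
                    n_bio_reps = n_bio_reps, n_tech_reps = n_tech_reps,
                    time_points_h = time_points_h, ...)
}

tiny_sim <- function(seed = 11, n_genes = 150, des = tiny_design(), ...) {
  set.seed(seed)
  ann <- generate_design(des)
  truth <- synthetic_truth(n_genes = n_genes, ...)
  sim <- simulate_counts(truth, ann)
  sim$design <- des
  sim
}

# response_set whose gene surfaces are exactly w_g * f on the grid
rank1_set <- function(w, f, conc_grid = 50 / 2.5^(7:0),
                      time_grid = c(2, 6, 12, 24, 48)) {
  f <- matrix(f, length(conc_grid), length(time_grid))
  vals <- array(NA_real_, c(length(w), nrow(f), ncol(f)))
  for (g in seq_along(w)) vals[g, , ] <- w[g] * f
  response_set(sprintf("g%03d", seq_along(w)), conc_grid, time_grid, vals)
}

# a smooth positive surface grid, affine in log10 coordinates
plane_grid <- function(a = 1, b = 1, c0 = 0,
                       conc_grid = 50 / 2.5^(7:0),
                       time_grid = c(2, 6, 12, 24, 48)) {
  outer(a * log10(conc_grid), b * log10(time_grid), "+") + c0
}

# exhaustive isotonic-regression oracle: minimise weighted SSE over all
# contiguous block partitions whose block means are nondecreasing
pava_oracle <- function(means, sizes) {
  k <- length(means)
  best <- NULL
  best_sse <- Inf
  for (mask in 0:(2^(k - 1) - 1)) {          # cut positions between groups
    cuts <- which(bitwAnd(mask, 2^(0:(k - 2))) > 0)
    bounds <- c(0, cuts, k)
    bm <- numeric(k)
    sse <- 0
    ok <- TRUE
    prev <- -Inf
    for (bi in seq_len(length(bounds) - 1L)) {
      idx <- (bounds[bi] + 1L):bounds[bi + 1L]
      m <- sum(means[idx] * sizes[idx]) / sum(sizes[idx])
      if (m < prev) { ok <- FALSE; break }
      prev <- m
      bm[idx] <- m
      sse <- sse + sum(sizes[idx] * (means[idx] - m)^2)
    }
    if (ok && sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- bm
    }
  }
  best
}

# thin-plate bending energy of a fitted surface (a' K a)
tps_bending_energy <- function(s) {
  d2 <- outer(rowSums(s$centers^2), rowSums(s$centers^2), "+") -
    2 * tcrossprod(s$centers)
  d2[d2 < 0] <- 0
  K <- ifelse(d2 > 0, d2 * log(d2), 0)
  drop(t(s$a) %*% K %*% s$a)
}
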