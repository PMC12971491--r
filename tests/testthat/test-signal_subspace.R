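make_grid_trace <- function(n_per_bin = 30, bin = 10, extent = 40) {
  # deterministic uniform occupancy on a coarse grid, one unit of counts
  centers <- seq(bin / 2, extent - bin / 2, by = bin)
  g <- expand.grid(x = centers, y = centers)
  idx <- rep(seq_len(nrow(g)), each = n_per_bin)
  latents <- cbind(x = g$x[idx], y = g$y[idx],
                   vx = rep(0.1, length(idx)), vy = rep(-0.1, length(idx)))
  behavior_trace(latents, matrix(1L, length(idx), 1))
}

test_that("basis centers tile occupied bins and peak at their own center", {
  trace <- make_grid_trace()
  cfg <- basis_config(position_bin_size = 10, velocity_bin_size = 5,
                      min_occupancy = 20)
  feat <- build_basis(trace, cfg)
  centers <- attr(feat, "centers")
  expect_equal(nrow(centers$position), 16)  # 4 x 4 occupied grid
  # evaluate the first position feature at its own center: exactly 1
  at_center <- which(trace$latents[, "x"] == centers$position$cx[1] &
                     trace$latents[, "y"] == centers$position$cy[1])
  expect_equal(max(feat[at_center, 1]), 1)
  # decays with squared distance
  far <- which.max((trace$latents[, "x"] - centers$position$cx[1])^2 +
                   (trace$latents[, "y"] - centers$position$cy[1])^2)
  expect_lt(feat[far, 1], 0.01)
  # occupancy threshold: raising it above the per-bin count removes all centers
  expect_error(build_basis(trace, basis_config(min_occupancy = 1e5)), "occupancy")
})

test_that("trajectory types duplicate the feature set", {
  trace <- make_grid_trace()
  tt <- rep(c("inbound", "outbound"), length.out = nrow(trace$counts))
  trace2 <- behavior_trace(trace$latents, trace$counts, trajectory_type = tt)
  f1 <- build_basis(trace, basis_config(min_occupancy = 10))
  f2 <- build_basis(trace2, basis_config(min_occupancy = 10))
  expect_equal(ncol(f2), 2 * ncol(f1))
  # each row is active in exactly one duplicate block
  expect_equal(rowSums(f2[, 1:ncol(f1)] != 0) > 0,
               tt == "inbound", ignore_attr = TRUE)
})

test_that("constant-rate units are null-flagged with constant predictions", {
  set.seed(30)
  sim <- simulate_tuned_population(n_units = 4, n_bins = 1500, amplitude = 0,
                                   velocity_gain = 0, seed = 31)
  feat <- build_basis(sim$trace, basis_config())
  fit <- fit_population_glm(feat, sim$trace$counts, seed = 32)
  expect_true(all(fit$null_flag))
  rates <- conditional_mean_rates(fit, feat)
  expect_true(all(rates > 0))
  expect_equal(apply(rates, 2, stats::sd), rep(0, 4))
  expect_error(task_subspace_dimension(rates), "constant")
})

test_that("the GLM recovers rates it generated (self-consistency)", {
  set.seed(33)
  sim <- simulate_tuned_population(n_units = 6, n_bins = 4000,
                                   amplitude = 1.2, seed = 34)
  res <- signal_subspace_dimension(sim$trace, basis_config(), seed = 35)
  expect_true(all(!res$fit$null_flag))
  expect_true(all(res$fit$d2 > 0 & res$fit$d2 <= 1))
  # fitted conditional means track the true rates
  for (u in 1:6) {
    expect_gt(stats::cor(res$rates[, u], sim$true_rates[, u]), 0.9)
  }
})

test_that("higher firing rates give higher deviance explained at fixed tuning", {
  set.seed(36)
  lo <- simulate_tuned_population(n_units = 5, n_bins = 3000,
                                  baseline_rate = 0.5, seed = 37)
  hi <- simulate_tuned_population(n_units = 5, n_bins = 3000,
                                  baseline_rate = 5, seed = 37)
  f_lo <- build_basis(lo$trace); f_hi <- build_basis(hi$trace)
  d2_lo <- fit_population_glm(f_lo, lo$trace$counts, seed = 38)$d2
  d2_hi <- fit_population_glm(f_hi, hi$trace$counts, seed = 38)$d2
  expect_gt(mean(d2_hi), mean(d2_lo))
})

test_that("task-subspace dimension reflects the rank of the tuning", {
  set.seed(39)
  t_grid <- seq(0, 2 * pi, length.out = 600)
  # rank-1: every unit tuned to the same latent function
  base <- sin(t_grid)
  v1 <- outer(base, runif(8, 0.5, 2)) + matrix(rnorm(600 * 8, sd = 1e-4), 600)
  expect_equal(task_subspace_dimension(v1), 1, tolerance = 0.01)
  # k orthogonal functions, equal strength, one per unit group
  funs <- cbind(sin(t_grid), cos(t_grid), sin(2 * t_grid), cos(2 * t_grid))
  v4 <- funs[, rep(1:4, each = 3)]
  expect_equal(task_subspace_dimension(v4), 4, tolerance = 0.05)
})

test_that("behavior traces round-trip through delimited text", {
  sim <- simulate_tuned_population(n_units = 3, n_bins = 200, seed = 40)
  dir <- withr::local_tempdir()
  write_behavior_trace(sim$trace, file.path(dir, "trace"))
  back <- read_behavior_trace(file.path(dir, "trace"))
  expect_equal(back$latents, sim$trace$latents, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(back$counts, sim$trace$counts)
  expect_equal(back$bin_width, sim$trace$bin_width)
})

test_that("simulated populations match their specification", {
  sim <- simulate_tuned_population(n_units = 4, n_bins = 3000, amplitude = 0,
                                   velocity_gain = 0, baseline_rate = 2,
                                   seed = 41)
  # homogeneous Poisson at the baseline rate
  expect_equal(unname(colMeans(sim$trace$counts)), rep(2, 4), tolerance = 0.1)
  expect_true(all(sim$trace$counts >= 0))
  sim2 <- simulate_tuned_population(n_units = 10, n_bins = 500,
                                    frac_noise = 0.3, seed = 42)
  expect_equal(sum(!sim2$tuned), 3)
  expect_true(is.finite(sim2$true_pr))
})
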