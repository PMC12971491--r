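test_that("power-law latent covariance has the stated eigenvalues", {
  expect_equal(power_law_omega(5, 0, scale = 2), diag(2, 5))
  om <- power_law_omega(40, 1)
  ev <- sort(diag(om), decreasing = TRUE)
  expect_equal(ev[1] / ev[40], 40)
  expect_equal(ev[1], 5)
  # rotation preserves the spectrum
  omr <- power_law_omega(6, 0.5, rotate = TRUE, seed = 2)
  expect_equal(eigen(omr, symmetric = TRUE, only.values = TRUE)$values,
               5 * seq_len(6)^-0.5, tolerance = 1e-10)
})

test_that("Gaussian latent sampling is seeded and has the right moments", {
  om <- power_law_omega(5, 0.5)
  z1 <- sample_gaussian_latents(om, 100, seed = 6)
  z2 <- sample_gaussian_latents(om, 100, seed = 6)
  expect_identical(z1, z2)
  z <- sample_gaussian_latents(om, 2e4, seed = 7)
  emp <- crossprod(scale(z, scale = FALSE)) / (nrow(z) - 1)
  expect_lt(norm(emp - om, "F") / norm(om, "F"), 0.05)
  expect_lt(max(abs(colMeans(z))), 4 * sqrt(max(diag(om)) / 2e4))
})

test_that("linear code specs apply mixing, whitening and noise correctly", {
  z <- matrix(rnorm(300 * 4), ncol = 4)
  expect_identical(apply_code(z, linear_code_spec(a_matrix = diag(4))), z)
  om <- diag(c(4, 3, 2, 1))
  zw <- sample_gaussian_latents(om, 2e4, seed = 8)
  xw <- apply_code(zw, linear_code_spec(whiten = TRUE, omega = om))
  emp <- crossprod(scale(xw, scale = FALSE)) / (nrow(xw) - 1)
  expect_lt(norm(emp - diag(4), "F"), 0.1)
  expect_error(linear_code_spec(a_matrix = diag(2), whiten = TRUE), "exclusive")
  expect_error(linear_code_spec(), "provide")
})

test_that("random MLP codes expand widths and rectify responses", {
  z <- matrix(rnorm(100 * 6), ncol = 6)
  layers <- apply_code(z, mlp_spec(seed = 3))
  expect_named(layers, c("lin1", "act1", "lin2", "act2", "lin3", "act3"))
  expect_equal(vapply(layers[c("act1", "act2", "act3")], ncol, 1),
               c(act1 = 12, act2 = 24, act3 = 48))
  expect_true(all(layers$act2 >= 0))
  expect_true(any(layers$lin2 < 0))
  # tanh variant is bounded
  lt <- apply_code(z, mlp_spec(nonlinearity = "tanh", seed = 3))
  expect_true(all(abs(lt$act1) <= 1))
  # same seed, same network
  expect_identical(apply_code(z, mlp_spec(seed = 3))$act3, layers$act3)
})

test_that("covariance estimation recovers known structure", {
  z <- matrix(rnorm(500 * 3), ncol = 3)
  code <- estimate_covariances(z, z)
  expect_equal(code$psi, code$omega, tolerance = 1e-12)
  expect_equal(code$phi, code$omega, tolerance = 1e-12)
  # constant response column gives zero covariance rows
  x <- cbind(z[, 1], 5)
  code2 <- estimate_covariances(x, z)
  expect_equal(code2$psi[2, ], c(0, 0))
  expect_equal(code2$phi[2, ], c(0, 0, 0))
  expect_error(estimate_covariances(x[1, , drop = FALSE], z[1, , drop = FALSE]),
               "at least 2")
})

test_that("metrics from estimated covariances converge to the generative truth", {
  set.seed(9)
  code <- random_valid_code(n = 12, d = 5)
  draws <- latentgeom:::sample_joint(code, 4e4)
  est <- estimate_covariances(draws$X, draws$Z)
  g_true <- geometry_summary(code); g_est <- geometry_summary(est)
  expect_equal(g_est$c, g_true$c, tolerance = 0.05)
  expect_equal(g_est$pr, g_true$pr, tolerance = 0.05)
  expect_equal(g_est$f, g_true$f, tolerance = 0.05)
  expect_equal(theoretical_error(g_est, 100)$e_g,
               theoretical_error(g_true, 100)$e_g, tolerance = 0.02)
})

test_that("random projections bound dimension and preserve it when orthonormal", {
  set.seed(10)
  x <- matrix(rnorm(400 * 20), ncol = 20) %*% diag(seq(2, 0.1, length.out = 20))
  projs <- random_projection(x, target_dim = 5, n_projections = 4, seed = 1)
  for (px in projs) {
    expect_lte(participation_ratio(stats::cov(px)), 5)
  }
  full <- random_projection(x, target_dim = 20, n_projections = 1,
                            orthogonalize = TRUE, seed = 2)[[1]]
  expect_equal(participation_ratio(stats::cov(full)),
               participation_ratio(stats::cov(x)), tolerance = 1e-8)
})

test_that("column z-scoring honors the standard-deviation floor", {
  set.seed(12)
  m <- scale(matrix(rnorm(600), ncol = 3))
  attr(m, "scaled:center") <- NULL; attr(m, "scaled:scale") <- NULL
  expect_equal(zscore_columns(m), m, tolerance = 1e-12, ignore_attr = TRUE)
  mc <- cbind(m[, 1], 7)
  zc <- zscore_columns(mc, sd_floor = 0.02)
  expect_equal(zc[, 2], rep(0, 200))
  expect_error(zscore_columns(mc), "constant column")
  # a column with sd equal to the floor is halved in scale
  v <- rnorm(200); v <- 0.02 * (v - mean(v)) / stats::sd(v)
  zv <- zscore_columns(matrix(v), sd_floor = 0.02)
  expect_equal(stats::sd(zv), 0.5, tolerance = 1e-12)
})

test_that("trained multitask MLPs learn and evaluate deterministically", {
  set.seed(13)
  d <- 5
  om <- power_law_omega(d, 0.2, scale = 1)
  z <- sample_gaussian_latents(om, 4000, seed = 14)
  battery <- sample_tasks(d, 25, seed = 15)
  y <- make_labels(z, battery)
  net <- train_multitask_mlp(z, y, widths = c(16, 16, 16), epochs = 2,
                             seed = 16)
  # training loss decreases
  k <- length(net$loss_trace)
  expect_lt(mean(net$loss_trace[(k - 9):k]), mean(net$loss_trace[1:10]))
  expect_false(net$diverged)
  # held-out accuracy of the network's own readouts beats chance
  z_new <- sample_gaussian_latents(om, 2000, seed = 17)
  acc <- mean(mlp_predict_tasks(net, z_new) == make_labels(z_new, battery))
  expect_gt(acc, 0.5 + 3 * sqrt(0.25 / (2000 * 25)))
  # frozen batchnorm: evaluation is a deterministic function of the input
  expect_identical(mlp_forward(net, z_new, layers = FALSE),
                   mlp_forward(net, z_new, layers = FALSE))
  stages <- mlp_forward(net, z_new)
  expect_named(stages, c("lin1", "act1", "lin2", "act2", "lin3", "act3"))
  expect_true(all(stages$act1 >= 0))
})

test_that("generated datasets round-trip through delimited text", {
  dir <- withr::local_tempdir()
  z <- matrix(rnorm(20), 5, 4)
  x <- matrix(rnorm(15), 5, 3)
  path <- write_dataset(X = x, Z = z, prefix = file.path(dir, "ds"),
                        manifest = list(seed = 1))
  expect_true(file.exists(path))
  back <- as.matrix(read.table(file.path(dir, "ds_Z.tsv"), sep = "\t"))
  expect_equal(unname(back), z, tolerance = 1e-12)
})
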