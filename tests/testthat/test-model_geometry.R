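test_that("participation ratio matches hand-computed spectra", {
  expect_equal(participation_ratio(diag(3)), 3)
  expect_equal(participation_ratio(diag(c(1, 0, 0))), 1)
  expect_equal(participation_ratio(diag(c(3, 1))), 1.6)
  expect_error(participation_ratio(matrix(0, 2, 2)), "positive")
})

test_that("neural-latent correlation handles degenerate and perfect codes", {
  d <- 3
  zero_phi <- gaussian_code(diag(d), matrix(0, d, d), diag(d))
  expect_equal(neural_latent_correlation(zero_phi), 0)
  # perfect scalar code x = z
  scalar <- gaussian_code(matrix(2), matrix(2), matrix(2))
  expect_equal(neural_latent_correlation(scalar), 1)
  # whitened code: c = 1/d
  for (d in 2:5) {
    omega <- diag(seq(d, 1))
    expect_equal(neural_latent_correlation(whitened_code(omega)), 1 / d,
                 tolerance = 1e-12)
  }
})

test_that("noise covariance isolates latent-unexplained variability", {
  # deterministic linear code x = A z: zero noise
  set.seed(1)
  a <- matrix(rnorm(12), 4, 3)
  omega <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  code <- gaussian_code(a %*% omega %*% t(a), a %*% omega, omega)
  expect_lt(max(abs(noise_covariance(code))), 1e-10)
  # x = z + isotropic noise: sigma^2 I
  code2 <- isotropic_noisy_code(3, 0.7)
  expect_equal(noise_covariance(code2), diag(0.7, 3), tolerance = 1e-12)
  # phi = 0: noise is psi itself
  code3 <- gaussian_code(diag(c(2, 1)), matrix(0, 2, 2), diag(2))
  expect_equal(noise_covariance(code3), diag(c(2, 1)))
})

test_that("SSF is maximal for whitened signal and matches hand algebra", {
  # single latent: Cauchy-Schwarz equality automatic
  one <- gaussian_code(diag(c(2, 1)), matrix(c(1, 0.5), 2, 1), matrix(3))
  expect_equal(ssf(one), 1, tolerance = 1e-12)
  # whitened: equality case
  expect_equal(ssf(whitened_code(diag(c(4, 2, 1)))), 1, tolerance = 1e-12)
  # x = z with omega = diag(3, 1): Tr(Omega^2)^2 / (Tr(Omega) Tr(Omega^3))
  code <- gaussian_code(diag(c(3, 1)), diag(c(3, 1)), diag(c(3, 1)))
  expect_equal(ssf(code), 100 / 112, tolerance = 1e-12)
  zero_phi <- gaussian_code(diag(2), matrix(0, 2, 2), diag(2))
  expect_error(ssf(zero_phi), "undefined")
})

test_that("SNF diverges for noiseless codes and tracks noise level", {
  expect_equal(snf(whitened_code(diag(c(3, 1)))), Inf)
  expect_equal(snf(isotropic_noisy_code(4, 1)), 1, tolerance = 1e-12)
  expect_equal(snf(isotropic_noisy_code(2, 4)), 0.25, tolerance = 1e-12)
  zero_phi <- gaussian_code(diag(2), matrix(0, 2, 2), diag(2))
  expect_error(snf(zero_phi), "undefined")
})

test_that("geometry_summary equals the individually computed metrics", {
  g <- geometry_summary(whitened_code(diag(c(4, 3, 2, 1))))
  expect_equal(g$c, 0.25, tolerance = 1e-12)
  expect_equal(g$pr, 4)
  expect_equal(g$f, 1, tolerance = 1e-12)
  expect_equal(g$s, Inf)
  code <- isotropic_noisy_code(3, 0.5)
  g2 <- geometry_summary(code)
  expect_identical(g2$c, neural_latent_correlation(code))
  expect_identical(g2$pr, participation_ratio(code$psi))
  expect_identical(g2$f, ssf(code))
  expect_identical(g2$s, snf(code))
})

test_that("theoretical error reproduces closed-form landmarks", {
  # fewshot + irreducible = 2 gives arctan(1)/pi = 1/4
  s <- manual_summary(c = 1, pr = pi / 2, f = 1, s = Inf)
  expect_equal(theoretical_error(s, 1)$e_g, 0.25, tolerance = 1e-12)
  # perfect factorization, infinite data: error vanishes
  s2 <- manual_summary(c = 0.5, pr = 10, f = 1, s = Inf)
  expect_lt(theoretical_error(s2, 10^7)$e_g, 1e-3)
  # c = 0: chance level, flagged
  s3 <- manual_summary(c = 0, pr = 5, f = 0.8, s = 2)
  pred <- theoretical_error(s3, 100)
  expect_equal(pred$e_g, 0.5)
  expect_true(pred$chance)
  # strictly decreasing in p
  s4 <- manual_summary(c = 0.3, pr = 8, f = 0.7, s = 3)
  eg <- theoretical_error(s4, c(10, 100, 1000))$e_g
  expect_true(all(diff(eg) < 0))
})

test_that("error is strictly decreasing in every geometric statistic", {
  set.seed(7)
  for (i in 1:200) {
    s <- manual_summary(c = runif(1, 0.05, 1), pr = runif(1, 1, 50),
                        f = runif(1, 0.1, 1), s = exp(runif(1, -2, 4)))
    p <- sample(c(10, 50, 200), 1)
    base <- theoretical_error(s, p)$e_g
    bump <- function(field, eps = 1e-4) {
      s2 <- s; s2[[field]] <- s2[[field]] * (1 + eps)
      theoretical_error(s2, p)$e_g
    }
    expect_lt(bump("c"), base)
    expect_lt(bump("pr"), base)
    expect_lt(bump("s"), base)
    s_f <- s; s_f$f <- min(s$f * (1 + 1e-4), 1)
    if (s_f$f > s$f) expect_lt(theoretical_error(s_f, p)$e_g, base)
    expect_lt(theoretical_error(s, p + 1)$e_g, base)
  }
})

test_that("metrics and error are invariant to the (a, b) rescaling gauge", {
  set.seed(11)
  for (i in 1:20) {
    code <- random_valid_code()
    a <- runif(1, 0.2, 5); b <- runif(1, 0.2, 5)
    scaled <- gaussian_code(a^2 * code$psi, a * b * code$phi, b^2 * code$omega)
    g1 <- geometry_summary(code); g2 <- geometry_summary(scaled)
    expect_equal(g1$c, g2$c, tolerance = 1e-9)
    expect_equal(g1$pr, g2$pr, tolerance = 1e-9)
    expect_equal(g1$f, g2$f, tolerance = 1e-9)
    if (is.finite(g1$s)) expect_equal(g1$s, g2$s, tolerance = 1e-8)
    expect_equal(theoretical_error(g1, 50)$e_g, theoretical_error(g2, 50)$e_g,
                 tolerance = 1e-9)
  }
})

test_that("invalid covariance triples are rejected", {
  expect_error(gaussian_code(diag(2), matrix(2, 2, 2) * 2, diag(2)), "PSD")
  asym <- matrix(c(1, 0.5, -0.5, 1), 2, 2)
  expect_error(gaussian_code(asym, diag(2) * 0, diag(2)), "symmetric")
  # phi too strong for psi: noise covariance indefinite
  expect_error(gaussian_code(diag(0.5, 2), diag(2), diag(2)), "PSD")
})

test_that("a covariance triple round-trips through delimited text", {
  set.seed(3)
  code <- random_valid_code(n = 5, d = 3)
  prefix <- file.path(withr::local_tempdir(), "code")
  write_gaussian_code(code, prefix, provenance = list(source = "unit test"))
  back <- read_gaussian_code(prefix)
  expect_equal(back$psi, code$psi, tolerance = 1e-12)
  expect_equal(back$phi, code$phi, tolerance = 1e-12)
  expect_equal(back$omega, code$omega, tolerance = 1e-12)
})
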