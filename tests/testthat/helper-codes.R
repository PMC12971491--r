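# Fixture builders used across test files.

# A random valid Gaussian code, PSD by construction: the joint covariance is
# assembled from a lower-triangular block factor, so every draw is realizable.
random_valid_code <- function(n = NULL, d = NULL) {
  n <- n %||% sample(3:10, 1)
  d <- d %||% sample(2:min(n, 6), 1)
  omega_factor <- matrix(rnorm(d * d), d, d)
  omega <- crossprod(omega_factor) + 0.1 * diag(d)
  omega_root <- latentgeom:::sqrt_sym(omega)
  x1 <- matrix(rnorm(n * d), n, d)
  x2 <- matrix(rnorm(n * n, sd = 0.5), n, n)
  gaussian_code(tcrossprod(x1) + tcrossprod(x2), x1 %*% omega_root, omega)
}

# Additive-noise code x = z + eps with isotropic noise, omega = I_d.
isotropic_noisy_code <- function(d, sigma2) {
  gaussian_code(diag(1 + sigma2, d), diag(d), diag(d))
}

# Whitened code: phi^T phi proportional to omega, psi = I (f = 1 by
# construction, zero noise).
whitened_code <- function(omega) {
  d <- nrow(omega)
  gaussian_code(diag(d), latentgeom:::sqrt_sym(omega), omega)
}

# A geometry summary object assembled directly from its four statistics.
manual_summary <- function(c, pr, f, s, n = 100) {
  structure(list(c = c, pr = pr, f = f, s = s, n = n),
            class = "geometry_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
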