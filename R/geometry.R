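#' Participation ratio of a covariance matrix
#'
#' The participation ratio \deqn{PR(\Psi) = [\mathrm{Tr}(\Psi)]^2 / \mathrm{Tr}(\Psi^2)}
#' is a standard spectral measure of the effective dimensionality of
#' population activity: it equals `n` for isotropic covariance and 1 for a
#' rank-one covariance.
#'
#' @param psi symmetric PSD matrix with positive trace.
#' @return A scalar in `[1, n]`.
#' @examples
#' participation_ratio(diag(3))       # 3
#' participation_ratio(diag(c(3, 1))) # 1.6
#' @export
participation_ratio <- function(psi) {
  psi <- as.matrix(psi)
  check_symmetric(psi, "psi", 1e-8)
  tr <- sum(diag(psi))
  if (tr <= 0) stop("participation ratio undefined: Tr(psi) must be positive")
  tr^2 / sum(psi * psi)
}

#' Total neural-latent correlation
#'
#' A normalized sum of squared covariances between every unit and every
#' latent variable,
#' \deqn{c = \mathrm{Tr}(\Phi\Phi^\top) / [\mathrm{Tr}(\Psi)\,\mathrm{Tr}(\Omega)],}
#' a multidimensional generalization of the squared Pearson correlation
#' between responses and latents. Zero iff `phi = 0`.
#'
#' @param code a [gaussian_code()].
#' @return A non-negative scalar.
#' @export
neural_latent_correlation <- function(code) {
  stopifnot(inherits(code, "gaussian_code"))
  tr_psi <- sum(diag(code$psi))
  tr_omega <- sum(diag(code$omega))
  if (tr_psi <= 0 || tr_omega <= 0) {
    stop("neural-latent correlation undefined: Tr(psi) and Tr(omega) must be positive")
  }
  sum(code$phi^2) / (tr_psi * tr_omega)
}

#' Noise covariance of a Gaussian code
#'
#' Trial-to-trial covariability unexplained by the latents:
#' \eqn{\mathrm{cov}(x \mid z) = \Psi - \Phi\Omega^{-1}\Phi^\top}. A
#' rank-deficient `omega` is inverted by pseudo-inverse with relative
#' eigenvalue cutoff `1e-10`.
#'
#' @param code a [gaussian_code()].
#' @param tol relative tolerance; an eigenvalue below `-tol * ||psi||` raises
#'   an inconsistent-code error, small negatives are clipped to zero.
#' @return A symmetric PSD `n x n` matrix.
#' @export
noise_covariance <- function(code, tol = 1e-8) {
  stopifnot(inherits(code, "gaussian_code"))
  noise <- sym_part(code$psi - code$phi %*% pinv_sym(code$omega) %*% t(code$phi))
  e <- eigen(noise, symmetric = TRUE)
  psi_scale <- max(abs(eigen(code$psi, symmetric = TRUE, only.values = TRUE)$values), 0)
  if (psi_scale > 0 && min(e$values) < -tol * psi_scale) {
    stop("inconsistent code: noise covariance has a negative eigenvalue beyond tolerance")
  }
  e$vectors %*% (t(e$vectors) * pmax(e$values, 0))
}

#' Signal-signal factorization (SSF)
#'
#' Measures the degree to which independent latent variables are represented
#' along uncorrelated, equal-variance neural directions:
#' \deqn{f = [\mathrm{Tr}(\Phi\Phi^\top)]^2 /
#'   [\mathrm{Tr}(\Omega)\,\mathrm{Tr}(\Phi^\top\Phi\,\Omega^{-1}\,\Phi^\top\Phi)].}
#' By the Cauchy-Schwarz inequality \eqn{f \le 1}, with equality iff
#' \eqn{\Phi^\top\Phi \propto \Omega} (a whitened signal).
#'
#' @param code a [gaussian_code()].
#' @return A scalar in `(0, 1]`.
#' @export
ssf <- function(code) {
  stopifnot(inherits(code, "gaussian_code"))
  num <- sum(code$phi^2)
  if (num == 0) stop("SSF undefined: phi is identically zero")
  g <- crossprod(code$phi)                      # Phi^T Phi, d x d
  den <- sum(diag(code$omega)) * sum(diag(g %*% pinv_sym(code$omega) %*% g))
  num^2 / den
}

#' Signal-noise factorization (SNF)
#'
#' Measures (inversely) how much trial-to-trial noise lies along the coding
#' directions:
#' \deqn{s = [\mathrm{Tr}(\Phi\Phi^\top)]^2 /
#'   [\mathrm{Tr}(\Omega)\,\mathrm{Tr}(\Phi^\top(\Psi - \Phi\Omega^{-1}\Phi^\top)\Phi)].}
#' For a noiseless code the denominator vanishes and the SNF diverges; this
#' is returned as `Inf` (and contributes `1/s = 0` to the error formula).
#'
#' @param code a [gaussian_code()].
#' @param tol relative tolerance for declaring the noise trace zero (or
#'   flagging a negative trace as inconsistent).
#' @return A positive scalar, possibly `Inf`.
#' @export
snf <- function(code, tol = 1e-8) {
  stopifnot(inherits(code, "gaussian_code"))
  num <- sum(code$phi^2)
  if (num == 0) stop("SNF undefined: phi is identically zero")
  noise <- code$psi - code$phi %*% pinv_sym(code$omega) %*% t(code$phi)
  noise_tr <- sum(crossprod(code$phi, noise) * t(code$phi))
  scale <- sum(diag(code$psi)) * num
  if (noise_tr < -tol * max(scale, 1e-300)) {
    stop("inconsistent code: negative noise projection beyond tolerance")
  }
  if (noise_tr <= tol * scale) return(Inf)
  num^2 / (sum(diag(code$omega)) * noise_tr)
}

#' Four-statistic geometric summary of a Gaussian code
#'
#' Bundles the total neural-latent correlation `c`, participation-ratio
#' dimension `pr`, signal-signal factorization `f` and signal-noise
#' factorization `s`. All four are functions of the covariance triple alone
#' and do not depend on any sample size.
#'
#' @param code a [gaussian_code()].
#' @return An object of class `geometry_summary`: list with `c`, `pr`, `f`,
#'   `s`, and the unit count `n`.
#' @examples
#' code <- gaussian_code(diag(3), diag(3), diag(3))
#' geometry_summary(code)
#' @export
geometry_summary <- function(code) {
  stopifnot(inherits(code, "gaussian_code"))
  structure(
    list(
      c = neural_latent_correlation(code),
      pr = participation_ratio(code$psi),
      f = ssf(code),
      s = snf(code),
      n = code$n
    ),
    class = "geometry_summary"
  )
}

#' @export
print.geometry_summary <- function(x, ...) {
  cat(sprintf("<geometry_summary> c = %.4g, PR = %.4g, f = %.4g, s = %s\n",
              x$c, x$pr, x$f,
              if (is.infinite(x$s)) "Inf" else sprintf("%.4g", x$s)))
  invisible(x)
}

#' Theoretical task-averaged generalization error of the Hebbian readout
#'
#' Closed-form prediction for the generalization error of a supervised
#' Hebbian readout, averaged over random linear shatterings of the latent
#' space, given `p` training samples:
#' \deqn{E_g = \frac{1}{\pi}\arctan\sqrt{\frac{\pi}{2 p c^2 PR} +
#'   \frac{1}{f} + \frac{1}{s} - 1}.}
#' The first term under the root decays as `1/p` (the "few-shot" term); the
#' remaining `1/f + 1/s - 1` is an irreducible floor set by the factorization
#' statistics. The radicand can dip slightly below zero in floating point for
#' near-perfect codes; it is clamped at zero with a warning, giving `e_g = 0`.
#'
#' @param summary a [geometry_summary()] or a [gaussian_code()] (summarized
#'   internally).
#' @param p training-set size, a positive integer (vectorized).
#' @return An object of class `error_prediction` (a data.frame with columns
#'   `p`, `e_g`, `fewshot_term`, `irreducible_term`, `chance`). When `c = 0`
#'   the code carries no task information and chance error 0.5 is returned
#'   with `chance = TRUE`.
#' @examples
#' code <- gaussian_code(diag(4), diag(4), diag(4))
#' theoretical_error(code, p = c(10, 100, 1000))
#' @export
theoretical_error <- function(summary, p) {
  if (inherits(summary, "gaussian_code")) summary <- geometry_summary(summary)
  stopifnot(inherits(summary, "geometry_summary"))
  if (any(p < 1) || any(p != round(p))) stop("p must be positive integers")
  if (summary$c == 0) {
    out <- data.frame(p = p, e_g = 0.5, fewshot_term = Inf,
                      irreducible_term = 1 / summary$f + inv_or_zero(summary$s),
                      chance = TRUE)
    class(out) <- c("error_prediction", "data.frame")
    return(out)
  }
  fewshot <- pi / (2 * p * summary$c^2 * summary$pr)
  irreducible <- 1 / summary$f + inv_or_zero(summary$s)
  radicand <- fewshot + irreducible - 1
  if (any(radicand < 0)) {
    if (any(radicand < -1e-6)) {
      warning("radicand substantially negative; geometry summary may be inconsistent")
    } else {
      warning("radicand slightly negative (near-perfect code); clamped to 0")
    }
    radicand <- pmax(radicand, 0)
  }
  out <- data.frame(p = p, e_g = atan(sqrt(radicand)) / pi,
                    fewshot_term = fewshot, irreducible_term = irreducible,
                    chance = FALSE)
  class(out) <- c("error_prediction", "data.frame")
  out
}

inv_or_zero <- function(s) if (is.infinite(s)) 0 else 1 / s
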