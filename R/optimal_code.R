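#' Closed-form spectrum of the error-minimizing code
#'
#' For a fixed latent covariance with eigenvalues `omega_values` and a
#' training budget `p`, the neural covariance of the code minimizing the
#' task-averaged Hebbian error has eigenvalues
#' \deqn{\psi_i = C\,\frac{\omega_i}{2 p \omega_i + \pi \sum_k \omega_k},}
#' with `C` an arbitrary positive constant (the error is scale invariant).
#' As `p` grows the spectrum flattens (expansion); as `p` shrinks it decays
#' faster than the latent spectrum (compression of less informative
#' directions).
#'
#' @param omega_values positive latent eigenvalues, sorted descending.
#' @param p sample budget (non-negative integer; `p = 0` gives
#'   `psi proportional to omega`).
#' @param scale_c the constant `C > 0`.
#' @return An `optimal_spectrum`: list with `psi_values`, `omega_values`,
#'   `p`, `scale_c`.
#' @examples
#' optimal_spectrum(c(3, 1), p = 1)
#' @export
optimal_spectrum <- function(omega_values, p, scale_c = 1) {
  if (any(omega_values <= 0)) stop("latent eigenvalues must be positive")
  if (p < 0) stop("p must be non-negative")
  if (scale_c <= 0) stop("scale_c must be positive")
  omega_values <- sort(omega_values, decreasing = TRUE)
  psi <- scale_c * omega_values / (2 * p * omega_values + pi * sum(omega_values))
  structure(list(psi_values = psi, omega_values = omega_values,
                 p = p, scale_c = scale_c),
            class = "optimal_spectrum")
}

#' Construct the optimal Gaussian code explicitly
#'
#' Builds a noiseless rank-`d` code whose neural covariance carries the
#' closed-form optimal spectrum and whose cross-covariance singular vectors
#' align with the eigenvectors of the neural covariance (left) and the
#' latent covariance (right). With zero noise the signal-noise factorization
#' diverges, and the joint covariance is PSD by construction: the code is
#' \eqn{\Psi = U \mathrm{diag}(\psi) U^\top},
#' \eqn{\Phi = U \mathrm{diag}(\sqrt{\psi_i \omega_i}) V^\top}
#' with `V` the eigenvectors of `omega` and `U` an orthonormal `n x d`
#' embedding (the first `d` coordinate axes by default; extra units carry
#' zero variance).
#'
#' @param omega positive-definite `d x d` latent covariance.
#' @param p sample budget.
#' @param n number of units, `n >= d`.
#' @param scale_c overall scale constant `C`.
#' @return A [gaussian_code()].
#' @export
build_optimal_code <- function(omega, p, n, scale_c = 1) {
  omega <- as.matrix(omega)
  d <- nrow(omega)
  if (n < d) stop("need at least as many units as latents (n >= d)")
  eo <- eigen(sym_part(omega), symmetric = TRUE)
  if (any(eo$values <= 0)) stop("omega must be positive definite")
  spec <- optimal_spectrum(eo$values, p, scale_c)
  psi_vals <- spec$psi_values
  u <- diag(n)[, seq_len(d), drop = FALSE]
  sigma <- sqrt(psi_vals * eo$values)
  phi <- u %*% (sigma * t(eo$vectors))
  psi <- u %*% (psi_vals * t(u))
  gaussian_code(psi, phi, omega, check = FALSE)
}

# Scale-invariant objective: the radicand argument w of the error formula,
# w = pi/(2 p c^2 PR) + 1/f + 1/s. E_g = arctan(sqrt(w - 1))/pi is strictly
# increasing in w, so minimizing w minimizes the error with better numerical
# conditioning near w = 1. Parameterization: phi = X1 omega^{1/2},
# psi = X1 X1^T + X2 X2^T, so the noise covariance is exactly X2 X2^T and the
# joint covariance is PSD for every (X1, X2).
optimal_objective <- function(x1, x2, omega, omega_root, p) {
  a <- sum((x1 %*% omega) * x1)                  # Tr(Phi Phi^T)
  if (a <= 0) return(list(w = Inf))
  k <- crossprod(x1)                             # X1^T X1
  t_omega <- sum(diag(omega))
  psi <- tcrossprod(x1) + tcrossprod(x2)
  t_psi2 <- sum(psi * psi)
  fden <- sum((k %*% k) * omega)                 # Tr((X1^T X1)^2 Omega)
  x2tx1 <- crossprod(x2, x1)
  sden <- sum((x2tx1 %*% omega) * x2tx1)         # Tr(X1^T X2 X2^T X1 Omega)
  num <- pi * t_omega^2 * t_psi2 / (2 * p) + t_omega * (fden + sden)
  list(w = num / a^2, a = a, k = k, psi = psi, t_omega = t_omega,
       t_psi2 = t_psi2, fden = fden, sden = sden, num = num)
}

optimal_gradient <- function(x1, x2, omega, p, obj) {
  t_omega <- obj$t_omega
  da_dx1 <- 2 * x1 %*% omega
  dpsi2_dx1 <- 4 * obj$psi %*% x1
  dpsi2_dx2 <- 4 * obj$psi %*% x2
  ko <- obj$k %*% omega
  dfden_dx1 <- 2 * x1 %*% (ko + t(ko))
  x2x2t <- tcrossprod(x2)
  dsden_dx1 <- 2 * x2x2t %*% x1 %*% omega
  dsden_dx2 <- 2 * x1 %*% omega %*% crossprod(x1, x2)
  dnum_dx1 <- pi * t_omega^2 / (2 * p) * dpsi2_dx1 +
    t_omega * (dfden_dx1 + dsden_dx1)
  dnum_dx2 <- pi * t_omega^2 / (2 * p) * dpsi2_dx2 + t_omega * dsden_dx2
  g1 <- dnum_dx1 / obj$a^2 - 2 * obj$w / obj$a * da_dx1
  g2 <- dnum_dx2 / obj$a^2
  c(as.vector(g1), as.vector(g2))
}

#' Numerically optimize the code under the PSD constraint
#'
#' Validates the closed-form optimum by direct minimization of the
#' task-averaged error over all realizable codes. The joint covariance is
#' parameterized through its block-Cholesky factor
#' `L = [[omega^{1/2}, 0], [X1, X2]]`, so that `L L^T` is PSD for any
#' unconstrained `(X1, X2)` and `phi = X1 omega^{1/2}`,
#' `psi = X1 X1^T + X2 X2^T`. Optimization is gradient-based (L-BFGS-B with
#' analytic gradients) with random restarts; the returned code is rescaled
#' to `Tr(psi) = 1` (the error is scale invariant, so the overall scale is a
#' gauge freedom).
#'
#' @param omega positive-definite latent covariance.
#' @param p sample budget.
#' @param n number of units, `n >= d`.
#' @param n_restarts random restarts (default 5).
#' @param maxit L-BFGS iterations per restart.
#' @param factr L-BFGS convergence tolerance (see [stats::optim()]).
#' @param seed optional integer seed for the restart initializations.
#' @return A [gaussian_code()] with attribute `diagnostics`: list with
#'   `objective` (best radicand argument `w`), `e_g`, `per_restart`
#'   objectives, `convergence` codes and `converged` flag. Non-convergence
#'   of every restart is flagged with a warning, never silently.
#' @export
numerical_optimal_code <- function(omega, p, n, n_restarts = 5,
                                   maxit = 1000, factr = 1e4, seed = NULL) {
  omega <- as.matrix(omega)
  d <- nrow(omega)
  if (n < d) stop("need n >= d")
  if (!is.null(seed)) set.seed(seed)
  omega_root <- sqrt_sym(omega)
  unpack <- function(par) {
    list(x1 = matrix(par[seq_len(n * d)], n, d),
         x2 = matrix(par[n * d + seq_len(n * n)], n, n))
  }
  fn <- function(par) {
    m <- unpack(par)
    optimal_objective(m$x1, m$x2, omega, omega_root, p)$w
  }
  gr <- function(par) {
    m <- unpack(par)
    obj <- optimal_objective(m$x1, m$x2, omega, omega_root, p)
    optimal_gradient(m$x1, m$x2, omega, p, obj)
  }
  best <- NULL
  per_restart <- numeric(n_restarts)
  convergence <- integer(n_restarts)
  for (r in seq_len(n_restarts)) {
    par0 <- c(stats::rnorm(n * d, sd = 1), stats::rnorm(n * n, sd = 0.1))
    fit <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = factr))
    per_restart[r] <- fit$value
    convergence[r] <- fit$convergence
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  converged <- any(convergence == 0)
  if (!converged) {
    warning("numerical code optimization did not converge in any restart")
  }
  m <- unpack(best$par)
  # gauge: Tr(psi) = 1
  scale <- sqrt(sum(m$x1^2) + sum(m$x2^2))
  x1 <- m$x1 / scale
  x2 <- m$x2 / scale
  phi <- x1 %*% omega_root
  psi <- tcrossprod(x1) + tcrossprod(x2)
  code <- gaussian_code(psi, phi, omega, check = FALSE)
  attr(code, "diagnostics") <- list(
    objective = best$value,
    e_g = atan(sqrt(max(best$value - 1, 0))) / pi,
    per_restart = per_restart,
    convergence = convergence,
    converged = converged
  )
  code
}

#' Geometry of the optimal code across sample budgets
#'
#' Tabulates the geometric statistics and theoretical error of the
#' closed-form optimal code over a grid of training budgets. For unequal
#' latent eigenvalues the optimal spectrum flattens with `p`: the dimension
#' `pr` and factorization `f` are non-decreasing in `p` while the
#' correlation `c` is non-increasing; the noiseless construction makes `s`
#' infinite throughout.
#'
#' @param omega positive-definite latent covariance.
#' @param p_grid non-empty vector of sample budgets.
#' @param n number of units.
#' @return A data.frame with columns `p`, `c`, `pr`, `f`, `s`, `e_g`.
#' @export
optimal_geometry_curve <- function(omega, p_grid, n) {
  if (length(p_grid) == 0) stop("p_grid must be non-empty")
  rows <- lapply(p_grid, function(p) {
    code <- build_optimal_code(omega, p, n)
    g <- geometry_summary(code)
    data.frame(p = p, c = g$c, pr = g$pr, f = g$f, s = g$s,
               e_g = theoretical_error(g, max(p, 1))$e_g)
  })
  do.call(rbind, rows)
}
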