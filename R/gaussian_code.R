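#' Gaussian population code
#'
#' A Gaussian code describes the joint second-order statistics of a neural
#' population response \eqn{x \in R^n} and the latent variables
#' \eqn{z \in R^d} that generated it, assuming both are jointly zero-mean
#' Gaussian. It is fully specified by the covariance triple
#' \deqn{\Psi = E[x x^\top], \quad \Phi = E[x z^\top], \quad \Omega = E[z z^\top].}
#' \eqn{\Psi} holds neuron-neuron covariances (rate units squared), \eqn{\Phi}
#' the unit-latent cross-covariances and \eqn{\Omega} the latent covariances.
#'
#' Validation enforces (within tolerance) symmetry of `psi` and `omega`,
#' positive semidefiniteness of the joint \eqn{(n+d)\times(n+d)} covariance
#' `rbind(cbind(omega, t(phi)), cbind(phi, psi))`, and positive
#' semidefiniteness of the noise covariance \eqn{\Psi - \Phi\Omega^{-1}\Phi^\top}.
#' Eigenvalues in `[-tol * lambda_max, 0)` are treated as numerical zeros, as
#' is routine for sample covariances.
#'
#' @param psi symmetric `n x n` neuron covariance matrix.
#' @param phi `n x d` neuron-latent cross-covariance matrix.
#' @param omega symmetric `d x d` latent covariance matrix.
#' @param tol relative tolerance for symmetry/PSD checks.
#' @param check validate invariants (set `FALSE` only for internal callers
#'   that construct guaranteed-valid triples).
#'
#' @return An object of class `gaussian_code`: a list with elements `psi`,
#'   `phi`, `omega`, `n`, `d`.
#' @examples
#' code <- gaussian_code(diag(2), diag(2), diag(2))
#' geometry_summary(code)
#' @export
gaussian_code <- function(psi, phi, omega, tol = 1e-8, check = TRUE) {
  psi <- as.matrix(psi)
  phi <- as.matrix(phi)
  omega <- as.matrix(omega)
  n <- nrow(psi)
  d <- nrow(omega)
  if (ncol(psi) != n) stop("psi must be square")
  if (ncol(omega) != d) stop("omega must be square")
  if (nrow(phi) != n || ncol(phi) != d) {
    stop(sprintf("phi must be %d x %d (units x latents)", n, d))
  }
  if (check) {
    check_symmetric(psi, "psi", tol)
    check_symmetric(omega, "omega", tol)
    joint <- rbind(cbind(omega, t(phi)), cbind(phi, psi))
    ev <- eigen(sym_part(joint), symmetric = TRUE, only.values = TRUE)$values
    lam_max <- max(abs(ev), 0)
    if (lam_max > 0 && min(ev) < -tol * lam_max) {
      stop("joint covariance [[omega, t(phi)], [phi, psi]] is not PSD within tolerance")
    }
    noise <- psi - phi %*% pinv_sym(omega) %*% t(phi)
    evn <- eigen(sym_part(noise), symmetric = TRUE, only.values = TRUE)$values
    psi_scale <- max(abs(eigen(sym_part(psi), symmetric = TRUE,
                               only.values = TRUE)$values), 0)
    if (psi_scale > 0 && min(evn) < -tol * psi_scale) {
      stop("noise covariance psi - phi omega^-1 t(phi) is not PSD within tolerance")
    }
  }
  structure(
    list(psi = sym_part(psi), phi = phi, omega = sym_part(omega), n = n, d = d),
    class = "gaussian_code"
  )
}

#' @export
print.gaussian_code <- function(x, ...) {
  cat(sprintf("<gaussian_code> n = %d units, d = %d latents\n", x$n, x$d))
  cat(sprintf("  Tr(psi) = %.4g, Tr(omega) = %.4g, Tr(phi phi^T) = %.4g\n",
              sum(diag(x$psi)), sum(diag(x$omega)), sum(x$phi^2)))
  invisible(x)
}

sym_part <- function(m) (m + t(m)) / 2

check_symmetric <- function(m, name, tol) {
  scale <- max(abs(m), 0)
  if (scale > 0 && max(abs(m - t(m))) > tol * scale) {
    stop(sprintf("%s is not symmetric within tolerance", name))
  }
  invisible(TRUE)
}

# Pseudo-inverse of a symmetric PSD matrix via eigendecomposition.
# Directions with eigenvalue < rel_cutoff * lambda_max are dropped, which
# matches centering/z-scoring pipelines that can produce degenerate latents.
pinv_sym <- function(m, rel_cutoff = 1e-10) {
  e <- eigen(sym_part(m), symmetric = TRUE)
  keep <- e$values > rel_cutoff * max(e$values, 0)
  if (!any(keep)) return(matrix(0, nrow(m), ncol(m)))
  v <- e$vectors[, keep, drop = FALSE]
  v %*% (t(v) / e$values[keep])
}

# Symmetric PSD square root (eigenvalues clipped at zero).
sqrt_sym <- function(m) {
  e <- eigen(sym_part(m), symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (t(e$vectors) * sqrt(v))
}

#' Write a Gaussian code to delimited text
#'
#' Serializes the covariance triple as three tab-separated matrices
#' (`<prefix>_psi.tsv`, `<prefix>_phi.tsv`, `<prefix>_omega.tsv`) plus a JSON
#' sidecar `<prefix>_manifest.json` recording `n`, `d` and free-form
#' provenance.
#'
#' @param code a [gaussian_code()].
#' @param prefix file path prefix (directory must exist).
#' @param provenance optional named list recorded verbatim in the manifest.
#' @return Invisibly, the manifest path.
#' @export
write_gaussian_code <- function(code, prefix, provenance = list()) {
  stopifnot(inherits(code, "gaussian_code"))
  paths <- paste0(prefix, c("_psi.tsv", "_phi.tsv", "_omega.tsv"))
  utils::write.table(code$psi, paths[1], sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(code$phi, paths[2], sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(code$omega, paths[3], sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  manifest <- list(n = code$n, d = code$d,
                   files = basename(paths), provenance = provenance)
  manifest_path <- paste0(prefix, "_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest_path)
}

#' Read a Gaussian code written by [write_gaussian_code()]
#'
#' @param prefix the file path prefix used when writing.
#' @param tol validation tolerance passed to [gaussian_code()].
#' @return A [gaussian_code()].
#' @export
read_gaussian_code <- function(prefix, tol = 1e-8) {
  rd <- function(suffix) {
    as.matrix(utils::read.table(paste0(prefix, suffix), sep = "\t"))
  }
  psi <- unname(rd("_psi.tsv"))
  phi <- unname(rd("_phi.tsv"))
  omega <- unname(rd("_omega.tsv"))
  manifest <- jsonlite::read_json(paste0(prefix, "_manifest.json"))
  if (!is.null(manifest$n) && manifest$n != nrow(psi)) {
    stop("manifest n does not match psi dimension")
  }
  if (!is.null(manifest$d) && manifest$d != nrow(omega)) {
    stop("manifest d does not match omega dimension")
  }
  gaussian_code(psi, phi, omega, tol = tol)
}
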