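#' Diffusion tensor model
#'
#' Wraps a 3x3 symmetric positive-semidefinite diffusion tensor `D`
#' (mm^2/s) together with its spectral decomposition: a rotation `U`
#' whose columns are eigenvectors ordered by descending eigenvalue, and
#' the eigenvalues `lambda` (mm^2/s).  Under Gaussian diffusion the net
#' spin displacement over the effective diffusion time `tau` is
#' N(0, 2*tau*D); this object is the covariance generator for that law.
#'
#' Eigenvector signs are fixed deterministically (largest-magnitude
#' component made positive, third column flipped if needed so that
#' det(U) = +1), giving reproducible frames across platforms even for
#' degenerate spectra.
#'
#' @param D 3x3 symmetric matrix, mm^2/s.
#' @return An object of class `diffusion_tensor` with elements `D`, `U`
#'   (rotation, det +1), `lambda` (descending, clipped at 0).
#' @examples
#' dt <- diffusion_tensor(diag(c(2, 1, 0.5)) * 1e-3)
#' dt$lambda
#' @export
diffusion_tensor <- function(D) {
  if (!is.matrix(D) || !all(dim(D) == c(3L, 3L)))
    stop("D must be a 3x3 matrix")
  if (!all(is.finite(D))) stop("D must be finite")
  scale <- max(abs(D), .Machine$double.xmin)
  if (max(abs(D - t(D))) > 1e-8 * scale)
    stop("D must be symmetric")
  D <- (D + t(D)) / 2
  e <- eigen(D, symmetric = TRUE)
  if (any(e$values < -1e-8 * scale))
    stop("invalid tensor: negative eigenvalue")
  lambda <- pmax(e$values, 0)
  U <- .fix_frame(e$vectors)
  structure(list(D = D, U = U, lambda = lambda),
            class = "diffusion_tensor")
}

# Deterministic sign convention for eigenvector columns; ensures det +1.
.fix_frame <- function(U) {
  for (k in 1:3) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) U[, k] <- -U[, k]
  }
  if (det(U) < 0) U[, 3] <- -U[, 3]
  U
}

#' @export
print.diffusion_tensor <- function(x, ...) {
  cat("Diffusion tensor (mm^2/s), eigenvalues:",
      paste(signif(x$lambda, 4), collapse = " "), "\n")
  invisible(x)
}

#' Gaussian EAP density
#'
#' Probability density of the net displacement `R` of a spin undergoing
#' free Gaussian diffusion with tensor `D` over effective diffusion time
#' `tau`:
#' `(4 pi tau)^(-3/2) |D|^(-1/2) exp(-R' D^{-1} R / (4 tau))` (mm^-3).
#'
#' @param R displacement(s), mm: a length-3 vector or an n x 3 matrix.
#' @param model a [diffusion_tensor()].
#' @param tau effective diffusion time, s.
#' @return density value(s), mm^-3.
#' @export
gaussian_eap_pdf <- function(R, model, tau) {
  stopifnot(inherits(model, "diffusion_tensor"), tau > 0)
  R <- .as_points(R)
  detD <- prod(model$lambda)
  if (detD <= 0) stop("singular diffusion tensor: density undefined")
  # quadratic form via the eigenframe
  Rp <- R %*% model$U
  qf <- Rp^2 %*% (1 / model$lambda)
  as.numeric((4 * pi * tau)^(-1.5) / sqrt(detD) * exp(-qf / (4 * tau)))
}

#' Tensor spectrum to MAP-MRI frame
#'
#' Converts a diffusion tensor and diffusion time into the rotation and
#' per-axis displacement scales used by the MAP-MRI frame:
#' `s_i = sqrt(2 tau lambda_i)` (mm), ordered `sx >= sy >= sz` to match
#' the descending eigenvalues.
#'
#' @inheritParams gaussian_eap_pdf
#' @return list with `U` (rotation) and `s` (length-3, mm).
#' @export
dt_spectrum_to_frame <- function(model, tau) {
  stopifnot(inherits(model, "diffusion_tensor"), tau > 0)
  list(U = model$U, s = sqrt(2 * tau * model$lambda))
}

#' Draw Gaussian displacement samples
#'
#' Direct (non-rejection) sampling of the Gaussian EAP:
#' `R = sqrt(2 tau) D^{1/2} S` with `S` three independent standard
#' normal deviates, so that `Var(R) = 2 tau D`.
#'
#' @inheritParams gaussian_eap_pdf
#' @param n number of samples.
#' @param seed optional integer seed (set before drawing).
#' @return a `sample_batch`: list with `displacements` (n x 3, mm),
#'   `acceptance_rate` (1 for direct sampling), `seed`.
#' @export
sample_gaussian <- function(model, tau, n, seed = NULL) {
  stopifnot(inherits(model, "diffusion_tensor"), tau > 0, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  A <- model$U %*% (sqrt(2 * tau * model$lambda) * t(model$U))
  S <- matrix(stats::rnorm(3 * n), n, 3)
  new_sample_batch(S %*% A, acceptance_rate = 1, seed = seed)
}

new_sample_batch <- function(displacements, acceptance_rate, seed = NULL,
                             wrapper = NULL) {
  colnames(displacements) <- c("x", "y", "z")
  structure(list(displacements = displacements,
                 acceptance_rate = acceptance_rate,
                 seed = seed, wrapper = wrapper),
            class = "sample_batch")
}

#' @export
print.sample_batch <- function(x, ...) {
  cat(sprintf("sample_batch: %d displacements, acceptance rate %.3f\n",
              nrow(x$displacements), x$acceptance_rate))
  invisible(x)
}

.as_points <- function(R) {
  if (is.null(dim(R))) R <- matrix(R, ncol = 3)
  if (ncol(R) != 3) stop("displacements must have 3 columns")
  R
}
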