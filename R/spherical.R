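#' Real symmetric spherical harmonic basis
#'
#' Real-valued basis restricted to even degrees, orthonormal under the
#' sphere measure `sin(theta) dtheta dphi`:
#' `Y_lm = sqrt((2l+1)/(2 pi) * (l-|m|)!/(l+|m|)!) P_l^|m|(cos theta)
#' T(m phi)` with `T` the sine for `m > 0`, the cosine for `m < 0` and
#' `2^(-1/2)` for `m = 0`.  Associated Legendre functions are evaluated
#' without the Condon-Shortley phase.
#'
#' @param l even non-negative degree.
#' @param m order, `-l <= m <= l`.
#' @param theta polar angle(s), rad, in `[0, pi)`.
#' @param phi azimuthal angle(s), rad, in `[0, 2 pi)`.
#' @return numeric vector of basis values.
#' @export
sh_basis <- function(l, m, theta, phi) {
  if (l %% 2 != 0 || l < 0) stop("degree l must be even and non-negative")
  if (abs(m) > l) stop("|m| must not exceed l")
  P <- .assoc_legendre(l, cos(theta))  # (l+1) x npts, m = 0..l rows
  am <- abs(m)
  norm <- sqrt((2 * l + 1) / (2 * pi) *
                 exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
  Tm <- if (m > 0) sin(m * phi) else if (m < 0) cos(m * phi)
        else rep(1 / sqrt(2), length(phi))
  norm * P[am + 1, ] * Tm
}

# Associated Legendre P_l^m(x) for m = 0..l, WITHOUT Condon-Shortley
# phase.  pracma::legendre follows the MATLAB convention (phase
# included), so strip it with (-1)^m.
.assoc_legendre <- function(l, x) {
  P <- pracma::legendre(l, x)
  if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
  P * (-1)^(0:l)
}

#' Even-degree spherical-harmonic coefficient set
#'
#' Flat coefficient vector in canonical order: degree `l = 0, 2, ..., L`
#' ascending, order `m = -l..l` within each degree.  For `L = 6` the set
#' has 28 entries.  The spherical mass of the represented function is
#' `phi_00 * sqrt(4 pi)`.
#'
#' @param phi numeric coefficient vector in canonical order.
#' @param L maximum (even) degree.
#' @return object of class `sh_coefficients`.
#' @export
sh_coefficients <- function(phi, L) {
  idx <- sh_index_set(L)
  if (length(phi) != nrow(idx))
    stop("expected ", nrow(idx), " coefficients for L = ", L,
         ", got ", length(phi))
  structure(list(phi = as.numeric(phi), index = idx, L = L),
            class = "sh_coefficients")
}

#' @rdname sh_coefficients
#' @export
sh_index_set <- function(L) {
  stopifnot(L >= 0, L %% 2 == 0)
  l <- unlist(lapply(seq(0, L, 2), function(li) rep(li, 2 * li + 1)))
  m <- unlist(lapply(seq(0, L, 2), function(li) -li:li))
  data.frame(l = l, m = m)
}

#' @export
print.sh_coefficients <- function(x, ...) {
  cat(sprintf("SH coefficients: L = %d (%d terms), mass = %.6g\n",
              x$L, length(x$phi), x$phi[1] * sqrt(4 * pi)))
  invisible(x)
}

#' Evaluate a spherical-harmonic expansion (e.g. an fODF)
#'
#' Linear combination of even-degree real spherical harmonics; the
#' result is antipodally symmetric by construction.
#'
#' @param coeffs a [sh_coefficients()].
#' @inheritParams sh_basis
#' @return function values at `(theta, phi)`.
#' @export
fodf_eval <- function(coeffs, theta, phi) {
  stopifnot(inherits(coeffs, "sh_coefficients"))
  stopifnot(length(theta) == length(phi))
  out <- numeric(length(theta))
  x <- cos(theta)
  for (l in seq(0, coeffs$L, 2)) {
    P <- .assoc_legendre(l, x)
    for (m in -l:l) {
      k <- which(coeffs$index$l == l & coeffs$index$m == m)
      if (coeffs$phi[k] == 0) next
      am <- abs(m)
      norm <- sqrt((2 * l + 1) / (2 * pi) *
                     exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      Tm <- if (m > 0) sin(m * phi) else if (m < 0) cos(m * phi)
            else rep(1 / sqrt(2), length(phi))
      out <- out + coeffs$phi[k] * norm * P[am + 1, ] * Tm
    }
  }
  out
}

#' Product quadrature rule on the unit sphere
#'
#' Gauss-Legendre nodes in `cos(theta)` crossed with a uniform
#' (trapezoidal, periodic) rule in `phi`.  Exact for spherical
#' polynomials of degree up to `2*n_theta - 1` in `cos(theta)` and
#' azimuthal frequency below `n_phi`, so `n_theta >= L+1` and
#' `n_phi >= 2L+1` integrate band-limited products exactly.
#'
#' @param n_theta number of Gauss-Legendre polar nodes.
#' @param n_phi number of equispaced azimuthal nodes.
#' @return data.frame with `theta`, `phi`, weight `w` (sums to 4 pi) and
#'   Cartesian unit-vector columns `vx`, `vy`, `vz`.
#' @export
sphere_quadrature <- function(n_theta = 16, n_phi = 32) {
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  theta <- acos(gl$x)
  phi <- 2 * pi * (0:(n_phi - 1)) / n_phi
  grid <- expand.grid(theta = theta, phi = phi)
  wt <- rep(gl$w, n_phi) * (2 * pi / n_phi)
  st <- sin(grid$theta)
  data.frame(theta = grid$theta, phi = grid$phi, w = wt,
             vx = st * cos(grid$phi), vy = st * sin(grid$phi),
             vz = cos(grid$theta))
}

#' Project a spherical function onto the even-degree SH basis
#'
#' Computes `phi_lm = \int f Y_lm dS` by product quadrature; exact for
#' band-limited `f` up to degree `L` when the rule is order-adequate.
#'
#' @param f vectorized function of `(theta, phi)`.
#' @param L maximum (even) degree.
#' @param n_theta,n_phi quadrature orders; must satisfy
#'   `n_theta >= L+1`, `n_phi >= 2L+1`.
#' @return a [sh_coefficients()].
#' @export
project_to_sh <- function(f, L, n_theta = 2 * L + 2, n_phi = 4 * L + 4) {
  if (n_theta < L + 1 || n_phi < 2 * L + 1)
    stop("quadrature order too low for degree ", L,
         ": need n_theta >= L+1 and n_phi >= 2L+1")
  q <- sphere_quadrature(n_theta, n_phi)
  fv <- f(q$theta, q$phi)
  idx <- sh_index_set(L)
  phi <- vapply(seq_len(nrow(idx)), function(k) {
    sum(q$w * fv * sh_basis(idx$l[k], idx$m[k], q$theta, q$phi))
  }, numeric(1))
  sh_coefficients(phi, L)
}
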