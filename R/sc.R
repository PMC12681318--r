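#' Spherical-convolution ensemble average propagator
#'
#' EAP defined as the spherical mixture of an axisymmetric Gaussian
#' kernel over fiber orientations: the displacement density is
#' `\int Phi(v) kappa(R; v) dv`, where `Phi` is the fODF (even-degree
#' spherical harmonics) and `kappa` is the Gaussian EAP of a tensor with
#' principal eigenvector `v`, principal eigenvalue `lambda_par` and two
#' transverse eigenvalues `lambda_perp`.
#'
#' @param fodf a [sh_coefficients()] fiber orientation distribution;
#'   unit spherical mass recommended (warns otherwise).
#' @param lambda_par,lambda_perp kernel eigenvalues, mm^2/s, with
#'   `lambda_par >= lambda_perp > 0`.
#' @param tau effective diffusion time, s.
#' @return object of class `sc_eap`.
#' @export
sc_eap <- function(fodf, lambda_par, lambda_perp, tau = 0.05) {
  stopifnot(inherits(fodf, "sh_coefficients"), tau > 0)
  if (lambda_perp <= 0 || lambda_par < lambda_perp)
    stop("invalid kernel: need lambda_par >= lambda_perp > 0")
  mass <- fodf$phi[1] * sqrt(4 * pi)
  if (abs(mass - 1) > 1e-6)
    warning(sprintf("fODF mass is %.6g, not 1; density will not be unit mass",
                    mass))
  structure(list(fodf = fodf, lambda_par = lambda_par,
                 lambda_perp = lambda_perp, tau = tau),
            class = "sc_eap")
}

#' @export
print.sc_eap <- function(x, ...) {
  cat(sprintf(
    "Spherical-convolution EAP: L = %d, lambda_par = %g, lambda_perp = %g mm^2/s, tau = %g s\n",
    x$fodf$L, x$lambda_par, x$lambda_perp, x$tau))
  invisible(x)
}

# Quadrature nodes + fODF values reused by the density/marginal/signal.
.sc_nodes <- function(eap, n_theta, n_phi) {
  q <- sphere_quadrature(n_theta, n_phi)
  f <- fodf_eval(eap$fodf, q$theta, q$phi)
  list(V = cbind(q$vx, q$vy, q$vz), wf = q$w * f)
}

#' Spherical-convolution EAP density
#'
#' Evaluates the orientation mixture by product quadrature on the
#' sphere.  For each node `v` the kernel is the Gaussian EAP with
#' eigenframe `(v, lambda_par; lambda_perp, lambda_perp)`; its quadratic
#' form reduces to `|R|^2/lambda_perp + (R.v)^2 (1/lambda_par -
#' 1/lambda_perp)`.  Serves as the density oracle for the SC sampler.
#'
#' @param R displacement(s), mm: length-3 vector or n x 3 matrix.
#' @param eap a [sc_eap()].
#' @param n_theta,n_phi quadrature orders (default adequate for L = 6
#'   fODFs mixed with a smooth kernel).
#' @return density values, mm^-3.
#' @export
sc_eap_pdf <- function(R, eap, n_theta = 24, n_phi = 48) {
  stopifnot(inherits(eap, "sc_eap"))
  R <- .as_points(R)
  nd <- .sc_nodes(eap, n_theta, n_phi)
  tau <- eap$tau
  lp <- eap$lambda_par
  lt <- eap$lambda_perp
  norm <- (4 * pi * tau)^(-1.5) / sqrt(lp * lt^2)
  r2 <- rowSums(R^2)
  RV <- R %*% t(nd$V)                   # n_pts x n_nodes
  expo <- exp(-(r2 / lt + RV^2 * (1 / lp - 1 / lt)) / (4 * tau))
  as.numeric(norm * (expo %*% nd$wf))
}

#' Marginal density of an SC EAP along a measurement axis
#'
#' The conditional law given orientation `v` is Gaussian, so the 1-D
#' marginal along axis `e` is a mixture of centered normals with
#' variances `2 tau (lambda_perp + (lambda_par - lambda_perp)(v.e)^2)`,
#' mixed over the fODF.  Used as the marginalization oracle in sampler
#' tests.  Negative fODF lobes (from truncation) are cropped and the
#' weights renormalized, matching what the rejection sampler actually
#' draws from.
#'
#' @param eap a [sc_eap()].
#' @param axis 1, 2 or 3.
#' @param n_theta,n_phi quadrature orders.
#' @return vectorized function of displacement (mm).
#' @export
sc_marginal_pdf <- function(eap, axis = 1, n_theta = 48, n_phi = 96) {
  stopifnot(axis %in% 1:3)
  nd <- .sc_nodes(eap, n_theta, n_phi)
  wf <- pmax(nd$wf, 0)
  wf <- wf / sum(wf)
  sd <- sqrt(2 * eap$tau *
               (eap$lambda_perp +
                  (eap$lambda_par - eap$lambda_perp) * nd$V[, axis]^2))
  function(x) {
    out <- numeric(length(x))
    for (k in seq_along(wf)) {
      if (wf[k] == 0) next
      out <- out + wf[k] * stats::dnorm(x, 0, sd[k])
    }
    out
  }
}
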