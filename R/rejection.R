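#' Generic N-dimensional rejection sampling
#'
#' Draws exact samples from `target_pdf` using proposals from a wrapper
#' density `wrapper_pdf` that satisfies `target <= c * wrapper`
#' everywhere.  A proposal `u` is accepted when a uniform height
#' `v ~ U(0, c * wrapper_pdf(u))` falls at or below `target_pdf(u)`.
#' Negative target values (possible for truncated basis expansions) are
#' cropped to zero by construction: a candidate height is never
#' negative, so no sample can land where the target dips below zero.
#'
#' @param target_pdf vectorized function: n x d matrix -> n densities.
#' @param wrapper_pdf vectorized wrapper density, same signature.
#' @param wrapper_sampler function(n) returning an n x d matrix of
#'   wrapper draws.
#' @param c bounding constant, `target <= c * wrapper`.
#' @param n number of accepted samples required.
#' @param rate_floor diagnostic floor: if after a probe of at least
#'   10^4 proposals the acceptance rate is below this, an error naming
#'   `c` is raised instead of looping indefinitely.
#' @return list with `samples` (n x d), `acceptance_rate` (accepted /
#'   proposed over the whole run).
#' @export
rejection_sample <- function(target_pdf, wrapper_pdf, wrapper_sampler,
                             c, n, rate_floor = 1e-3) {
  stopifnot(c >= 1, n >= 1)
  accepted <- NULL
  n_prop <- 0
  n_acc <- 0
  while (n_acc < n) {
    chunk <- max(2000L, ceiling((n - n_acc) * c * 1.2))
    u <- wrapper_sampler(chunk)
    fx <- pmax(target_pdf(u), 0)
    v <- stats::runif(chunk) * c * wrapper_pdf(u)
    keep <- v <= fx
    n_prop <- n_prop + chunk
    n_acc <- n_acc + sum(keep)
    accepted <- rbind(accepted, u[keep, , drop = FALSE])
    if (n_prop >= 1e4 && n_acc / n_prop < rate_floor)
      stop(sprintf(
        "rejection sampling acceptance rate %.2g below floor %.2g (c = %.4g); wrapper bound is too loose or target is ill-formed",
        n_acc / n_prop, rate_floor, c))
  }
  list(samples = accepted[seq_len(n), , drop = FALSE],
       acceptance_rate = n_acc / n_prop)
}

#' Wrapper construction for MAP-MRI sampling
#'
#' Sampling is done in normalized coordinates `t_i = x'_i / s_i`, in
#' which the target density is the Hermite expansion with unit scales
#' (the Jacobian `prod(s)` cancels the scale factors exactly).  The
#' wrapper is a product of three N(0, nu^2) densities: the Gaussian
#' envelope widened so it decays more slowly than any
#' Gaussian-times-polynomial target.  For each `nu` in `nu_grid` the
#' bounding constant `c(nu)` is the maximum of target/wrapper over the
#' lattice `[-extent, extent)` cubed with the given step; the returned
#' spec keeps the `nu` minimizing `c`, inflated by a safety factor
#' because a finite grid can under-bound the supremum.
#'
#' For a pure Gaussian target (`a000 = 1`) the ratio is
#' `nu^3 exp(-(1 - nu^-2) |t|^2 / 2)`, maximal at the origin, so
#' `c(nu) = nu^3` and the search returns `nu = 1.1`, `c = 1.331`
#' (before the safety factor).
#'
#' @param eap a [mapmri_eap()].
#' @param nu_grid candidate wrapper widths (dimensionless).
#' @param extent,step lattice extent and step in normalized units.
#' @param safety multiplicative inflation of the grid maximum.
#' @return object of class `wrapper_spec` with fields `family`, `nu`,
#'   `c` (bound in use, includes safety), `c_raw` (grid maximum),
#'   `c_by_nu`, `target_min` (most negative lattice value of the
#'   target), and the grid descriptor.
#' @export
build_mapmri_wrapper <- function(eap, nu_grid = seq(1.1, 1.5, by = 0.1),
                                 extent = 5, step = 0.1, safety = 1.05) {
  stopifnot(inherits(eap, "mapmri_eap"))
  g <- seq(-extent, extent - step, by = step)
  Ht <- .hermite_table(g, eap$Nmax, 1)
  ng <- length(g)
  target <- array(0, dim = c(ng, ng, ng))
  for (k in seq_along(eap$a)) {
    if (eap$a[k] == 0) next
    target <- target + eap$a[k] *
      (Ht[, eap$index$n1[k] + 1] %o% Ht[, eap$index$n2[k] + 1] %o%
         Ht[, eap$index$n3[k] + 1])
  }
  if (!all(is.finite(target)))
    stop("invalid coefficients: non-finite target density on the grid")
  target_min <- min(target)
  pos <- pmax(target, 0)
  c_by_nu <- vapply(nu_grid, function(nu) {
    d <- stats::dnorm(g, 0, nu)
    wrap <- d %o% d %o% d
    max(pos / wrap)
  }, numeric(1))
  best <- which.min(c_by_nu)
  structure(list(family = "gaussian_product", nu = nu_grid[best],
                 c = max(safety * c_by_nu[best], 1),
                 c_raw = c_by_nu[best], c_by_nu = c_by_nu,
                 nu_grid = nu_grid, safety = safety,
                 grid = list(extent = extent, step = step),
                 target_min = target_min),
            class = "wrapper_spec")
}

#' Wrapper construction for fODF orientation sampling
#'
#' The fODF lives on the compact sphere, so the wrapper is the uniform
#' density per unit solid angle, `1/(4 pi)`.  The bounding constant is
#' the lattice maximum of `4 pi * Phi(theta, phi)` over
#' `[0, pi) x [0, 2 pi)`, inflated by a safety factor.  Severely
#' negative fODF lobes trigger a warning; sampling crops them.
#'
#' @param fodf a [sh_coefficients()] with (near) unit mass.
#' @param n_theta,n_phi lattice resolution (default 1 degree).
#' @param safety multiplicative inflation of the grid maximum.
#' @return a `wrapper_spec` with `family = "uniform_sphere"`.
#' @export
build_fodf_wrapper <- function(fodf, n_theta = 180, n_phi = 360,
                               safety = 1.05) {
  stopifnot(inherits(fodf, "sh_coefficients"))
  theta <- pi * (0:(n_theta - 1)) / n_theta
  phi <- 2 * pi * (0:(n_phi - 1)) / n_phi
  grid <- expand.grid(theta = theta, phi = phi)
  f <- fodf_eval(fodf, grid$theta, grid$phi)
  fmax <- max(f)
  if (min(f) < -0.1 * fmax)
    warning("fODF has a strongly negative lobe (min < -0.1 * max); sampling will crop it")
  c_raw <- max(4 * pi * f)
  structure(list(family = "uniform_sphere", nu = NA_real_,
                 c = max(safety * c_raw, 1), c_raw = c_raw,
                 safety = safety,
                 grid = list(n_theta = n_theta, n_phi = n_phi),
                 target_min = min(f)),
            class = "wrapper_spec")
}

#' @export
print.wrapper_spec <- function(x, ...) {
  cat(sprintf("wrapper_spec [%s]: c = %.4g (grid max %.4g, safety %.3g)",
              x$family, x$c, x$c_raw, x$safety))
  if (is.finite(x$nu)) cat(sprintf(", nu = %.2g", x$nu))
  cat("\n")
  invisible(x)
}

#' Sample displacements from a MAP-MRI EAP
#'
#' Rejection sampling in normalized coordinates with the product-normal
#' wrapper from [build_mapmri_wrapper()].  Accepted normalized samples
#' are scaled per axis by `(sx, sy, sz)` and rotated back into the
#' measurement frame (`R = U R'`).
#'
#' @param eap a [mapmri_eap()].
#' @param n number of samples.
#' @param seed optional integer seed.
#' @param wrapper optional precomputed `wrapper_spec` (rebuilt if NULL).
#' @return a `sample_batch` (displacements in mm, measurement frame)
#'   whose `wrapper` field records `c`, `nu` and the acceptance rate.
#' @export
sample_mapmri <- function(eap, n, seed = NULL, wrapper = NULL) {
  stopifnot(inherits(eap, "mapmri_eap"))
  if (is.null(wrapper)) wrapper <- build_mapmri_wrapper(eap)
  if (!is.null(seed)) set.seed(seed)
  nu <- wrapper$nu
  # target in normalized coordinates: unit-scale Hermite expansion
  eap_t <- eap
  eap_t$scales <- c(1, 1, 1)
  res <- rejection_sample(
    target_pdf = function(u) mapmri_eap_pdf(u, eap_t),
    wrapper_pdf = function(u)
      stats::dnorm(u[, 1], 0, nu) * stats::dnorm(u[, 2], 0, nu) *
      stats::dnorm(u[, 3], 0, nu),
    wrapper_sampler = function(k) matrix(stats::rnorm(3 * k, 0, nu), k, 3),
    c = wrapper$c, n = n)
  Rp <- sweep(res$samples, 2, eap$scales, `*`)
  new_sample_batch(Rp %*% t(eap$U), res$acceptance_rate, seed,
                   wrapper = wrapper)
}

#' Sample displacements from a spherical-convolution EAP
#'
#' Two-stage exact sampling of the orientation mixture: an orientation
#' `(theta, phi)` is drawn from the fODF by rejection against the
#' uniform-sphere wrapper (proposals via `cos(theta) ~ U(-1, 1)`,
#' `phi ~ U(0, 2 pi)`; densities compared per unit solid angle), the
#' kernel tensor frame is assembled as `u1 = [sin t cos p, sin t sin p,
#' cos t]`, `u2 = [-sin p, cos p, 0]`, `u3 = u1 x u2`, and a Gaussian
#' displacement `R = sqrt(2 tau) D^{1/2} S` is drawn in that frame so
#' the conditional law is the Gaussian EAP of `D = U
#' diag(lambda_par, lambda_perp, lambda_perp) U'`.
#'
#' At the degenerate poles (`sin(theta)` numerically 0) the azimuth is
#' undefined; the frame convention `u2 = [0, 1, 0]` is applied.
#'
#' @param eap a [sc_eap()].
#' @inheritParams sample_mapmri
#' @return a `sample_batch` (displacements in mm).
#' @export
sample_sc <- function(eap, n, seed = NULL, wrapper = NULL) {
  stopifnot(inherits(eap, "sc_eap"))
  if (is.null(wrapper)) wrapper <- build_fodf_wrapper(eap$fodf)
  if (!is.null(seed)) set.seed(seed)
  res <- rejection_sample(
    target_pdf = function(u) fodf_eval(eap$fodf, u[, 1], u[, 2]),
    wrapper_pdf = function(u) rep(1 / (4 * pi), nrow(u)),
    wrapper_sampler = function(k)
      cbind(acos(stats::runif(k, -1, 1)), stats::runif(k, 0, 2 * pi)),
    c = wrapper$c, n = n)
  theta <- res$samples[, 1]
  phi <- res$samples[, 2]
  st <- sin(theta)
  degen <- st < 1e-12
  phi[degen] <- 0                      # u2 -> [0, 1, 0] at the poles
  u1 <- cbind(st * cos(phi), st * sin(phi), cos(theta))
  u2 <- cbind(-sin(phi), cos(phi), 0)
  u3 <- cbind(u1[, 2] * u2[, 3] - u1[, 3] * u2[, 2],
              u1[, 3] * u2[, 1] - u1[, 1] * u2[, 3],
              u1[, 1] * u2[, 2] - u1[, 2] * u2[, 1])
  s1 <- sqrt(2 * eap$tau * eap$lambda_par)
  s23 <- sqrt(2 * eap$tau * eap$lambda_perp)
  Z <- matrix(stats::rnorm(3 * n), n, 3)
  R <- (s1 * Z[, 1]) * u1 + (s23 * Z[, 2]) * u2 + (s23 * Z[, 3]) * u3
  new_sample_batch(R, res$acceptance_rate, seed, wrapper = wrapper)
}

#' Sample displacements from any supported EAP
#'
#' Dispatches to [sample_gaussian()], [sample_mapmri()] or
#' [sample_sc()] according to the EAP class.
#'
#' @param eap a `diffusion_tensor`, `mapmri_eap` or `sc_eap`.
#' @param n number of samples.
#' @param tau diffusion time, s (used by the tensor route only; MAP-MRI
#'   and SC objects carry their own).
#' @param seed optional integer seed.
#' @param wrapper optional precomputed wrapper spec.
#' @return a `sample_batch`.
#' @export
sample_eap <- function(eap, n, tau = NULL, seed = NULL, wrapper = NULL) {
  if (inherits(eap, "diffusion_tensor")) {
    if (is.null(tau)) stop("tau is required for tensor EAPs")
    sample_gaussian(eap, tau, n, seed)
  } else if (inherits(eap, "mapmri_eap")) {
    sample_mapmri(eap, n, seed, wrapper)
  } else if (inherits(eap, "sc_eap")) {
    sample_sc(eap, n, seed, wrapper)
  } else stop("unsupported EAP class: ", paste(class(eap), collapse = "/"))
}
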