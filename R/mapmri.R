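#' Normalized 1-D Hermite basis function
#'
#' Evaluates `H_n(t; s) = [2^(n+1) pi n!]^(-1/2) s^-1 exp(-t^2/(2 s^2))
#' H_n(t/s)` with `H_n` the physicists' Hermite polynomial.  With this
#' normalization the order-0 function is exactly the N(0, s^2) density,
#' so a MAP-MRI expansion with a single unit zeroth coefficient
#' reproduces the Gaussian EAP.
#'
#' Constants are computed in the log domain so large orders do not
#' overflow.
#'
#' @param n non-negative integer order.
#' @param t evaluation point(s).
#' @param s scale (same units as `t`), strictly positive.
#' @return numeric vector of values.
#' @export
hermite_basis_1d <- function(n, t, s = 1) {
  stopifnot(length(n) == 1, n >= 0, n == round(n), s > 0)
  u <- t / s
  lognorm <- -0.5 * ((n + 1) * log(2) + log(pi) + lgamma(n + 1))
  exp(lognorm) / s * exp(-u^2 / 2) * .hermite_poly(n, u)
}

# Physicists' Hermite polynomial H_n by upward recurrence, vectorized in u.
.hermite_poly <- function(n, u) {
  h0 <- rep(1, length(u))
  if (n == 0) return(h0)
  h1 <- 2 * u
  if (n == 1) return(h1)
  for (k in 2:n) {
    h2 <- 2 * u * h1 - 2 * (k - 1) * h0
    h0 <- h1
    h1 <- h2
  }
  h1
}

# Table of H_n(t; s) for n = 0..nmax: length(t) x (nmax+1).
.hermite_table <- function(t, nmax, s = 1) {
  out <- matrix(0, length(t), nmax + 1)
  for (n in 0:nmax) out[, n + 1] <- hermite_basis_1d(n, t, s)
  out
}

#' MAP-MRI index set
#'
#' All non-negative integer triplets (n1, n2, n3) with even total order
#' `n1+n2+n3 <= Nmax`, in deterministic order (total order ascending,
#' then n1 descending, then n2 descending).  For `Nmax = 6` there are
#' 50 triplets (1 + 6 + 15 + 28).
#'
#' @param Nmax even non-negative integer.
#' @return data.frame with integer columns `n1`, `n2`, `n3`.
#' @export
mapmri_index_set <- function(Nmax) {
  stopifnot(Nmax >= 0, Nmax %% 2 == 0)
  rows <- list()
  for (N in seq(0, Nmax, by = 2)) {
    for (n1 in N:0) {
      for (n2 in (N - n1):0) {
        rows[[length(rows) + 1L]] <- c(n1, n2, N - n1 - n2)
      }
    }
  }
  m <- do.call(rbind, rows)
  data.frame(n1 = m[, 1], n2 = m[, 2], n3 = m[, 3])
}

#' MAP-MRI ensemble average propagator
#'
#' Truncated expansion of a displacement density in products of 1-D
#' Hermite basis functions, evaluated in a tensor-adapted frame: the
#' displacement is rotated into the frame `U` and scaled per axis by
#' `(sx, sy, sz)` (typically from [dt_spectrum_to_frame()]).  Only even
#' total orders are allowed, so the density is antipodally symmetric.
#'
#' @param a numeric coefficients aligned with [mapmri_index_set()]
#'   order, or a data.frame with columns `n1`, `n2`, `n3`, `a` (missing
#'   triplets are zero).
#' @param Nmax maximum (even) total order of the expansion.
#' @param scales length-3 positive scales `(sx, sy, sz)`, mm.
#' @param U 3x3 rotation into the measurement frame (columns are the
#'   frame axes).
#' @param tau effective diffusion time, s (carried for provenance; the
#'   density itself is fully determined by `a`, `scales`, `U`).
#' @return object of class `mapmri_eap`.
#' @export
mapmri_eap <- function(a, Nmax, scales, U = diag(3), tau = 0.05) {
  idx <- mapmri_index_set(Nmax)
  if (is.data.frame(a)) {
    coef <- numeric(nrow(idx))
    for (i in seq_len(nrow(a))) {
      j <- which(idx$n1 == a$n1[i] & idx$n2 == a$n2[i] & idx$n3 == a$n3[i])
      if (length(j) != 1)
        stop("coefficient index (", a$n1[i], ",", a$n2[i], ",", a$n3[i],
             ") is not a valid even-order triplet for Nmax = ", Nmax)
      coef[j] <- a$a[i]
    }
  } else {
    if (length(a) != nrow(idx))
      stop("expected ", nrow(idx), " coefficients for Nmax = ", Nmax,
           ", got ", length(a))
    coef <- as.numeric(a)
  }
  stopifnot(length(scales) == 3, all(scales > 0), tau > 0)
  if (max(abs(crossprod(U) - diag(3))) > 1e-8) stop("U must be a rotation")
  structure(list(a = coef, index = idx, Nmax = Nmax,
                 scales = as.numeric(scales), U = U, tau = tau),
            class = "mapmri_eap")
}

#' @export
print.mapmri_eap <- function(x, ...) {
  cat(sprintf("MAP-MRI EAP: Nmax = %d (%d coefficients), scales = %s mm\n",
              x$Nmax, length(x$a),
              paste(signif(x$scales, 4), collapse = " ")))
  invisible(x)
}

#' Evaluate a MAP-MRI EAP density
#'
#' Computes the Hermite-product expansion at points given in the rotated
#' frame (`Rprime = U' R`).  Truncated expansions may dip slightly below
#' zero; callers that need a bona-fide density must crop at zero (the
#' rejection sampler does so by construction).
#'
#' @param Rprime length-3 vector or n x 3 matrix of rotated-frame
#'   displacements, mm.
#' @param eap a [mapmri_eap()].
#' @return density values, mm^-3 (possibly slightly negative).
#' @export
mapmri_eap_pdf <- function(Rprime, eap) {
  stopifnot(inherits(eap, "mapmri_eap"))
  Rprime <- .as_points(Rprime)
  Hx <- .hermite_table(Rprime[, 1], eap$Nmax, eap$scales[1])
  Hy <- .hermite_table(Rprime[, 2], eap$Nmax, eap$scales[2])
  Hz <- .hermite_table(Rprime[, 3], eap$Nmax, eap$scales[3])
  val <- numeric(nrow(Rprime))
  for (k in seq_along(eap$a)) {
    if (eap$a[k] == 0) next
    val <- val + eap$a[k] *
      Hx[, eap$index$n1[k] + 1] *
      Hy[, eap$index$n2[k] + 1] *
      Hz[, eap$index$n3[k] + 1]
  }
  val
}

#' Evaluate a MAP-MRI EAP in the measurement frame
#'
#' Convenience wrapper: rotates measurement-frame displacements into the
#' EAP's frame and calls [mapmri_eap_pdf()].
#'
#' @inheritParams mapmri_eap_pdf
#' @param R measurement-frame displacement(s), mm.
#' @export
mapmri_pdf <- function(R, eap) {
  mapmri_eap_pdf(.as_points(R) %*% eap$U, eap)
}

# \int H_n(t; s) dt, independent of s; vanishes for odd n.
.hermite_integral <- function(n) {
  if (n %% 2 == 1) return(0)
  stats::integrate(function(u) hermite_basis_1d(n, u, 1), -Inf, Inf,
                   rel.tol = 1e-12)$value
}

#' Marginal density of a MAP-MRI EAP along one rotated-frame axis
#'
#' The Hermite expansion is separable, so integrating out two axes
#' reduces each term to the 1-D basis function on the kept axis times
#' the (scale-free) integrals of the other two.  Used as the numerical
#' marginalization oracle for distributional tests of the sampler.
#'
#' @param eap a [mapmri_eap()].
#' @param axis 1, 2 or 3 (rotated-frame axis).
#' @return a vectorized function of displacement (mm) returning the
#'   marginal density (mm^-1).
#' @export
mapmri_marginal_pdf <- function(eap, axis = 1) {
  stopifnot(axis %in% 1:3)
  Mn <- vapply(0:eap$Nmax, .hermite_integral, numeric(1))
  keep <- c("n1", "n2", "n3")[axis]
  drop <- setdiff(c("n1", "n2", "n3"), keep)
  w <- eap$a * Mn[eap$index[[drop[1]]] + 1] * Mn[eap$index[[drop[2]]] + 1]
  s <- eap$scales[axis]
  nk <- eap$index[[keep]]
  function(x) {
    H <- .hermite_table(x, eap$Nmax, s)
    out <- numeric(length(x))
    for (k in seq_along(w)) {
      if (w[k] == 0) next
      out <- out + w[k] * H[, nk[k] + 1]
    }
    out
  }
}

#' Total mass of a MAP-MRI EAP
#'
#' Integral of the expansion over all of space, computed exactly from
#' the separable per-axis Hermite integrals.
#'
#' @param eap a [mapmri_eap()].
#' @return scalar mass (1 for a properly normalized EAP).
#' @export
mapmri_mass <- function(eap) {
  Mn <- vapply(0:eap$Nmax, .hermite_integral, numeric(1))
  sum(eap$a * Mn[eap$index$n1 + 1] * Mn[eap$index$n2 + 1] *
        Mn[eap$index$n3 + 1])
}
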