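# Shared ground-truth fixtures for the sampler / simulator tests.
# Every fixture is a pure function: identical calls give identical
# objects, so tests that freeze expected values stay reproducible.

fx_tau <- function() 0.0557 - 0.0166 / 3  # cardiac PGSE: Delta - delta/3, s

# Fixed non-trivial rotation (z by 30 deg, then x by 45 deg)
fx_rotation <- function() {
  rz <- matrix(c(cos(pi / 6), sin(pi / 6), 0,
                 -sin(pi / 6), cos(pi / 6), 0,
                 0, 0, 1), 3, 3)
  rx <- matrix(c(1, 0, 0,
                 0, cos(pi / 4), sin(pi / 4),
                 0, -sin(pi / 4), cos(pi / 4)), 3, 3)
  rx %*% rz
}

fx_tensor <- function(kind = "generic") {
  lam <- switch(kind,
                iso = c(1, 1, 1) * 1e-3,
                prolate = c(2, 0.5, 0.5) * 1e-3,
                oblate = c(1.5, 1.5, 0.4) * 1e-3,
                generic = c(2, 1, 0.5) * 1e-3,
                stop("unknown tensor fixture"))
  U <- fx_rotation()
  diffusion_tensor(U %*% (lam * t(U)))
}

# MAP-MRI expansion equal to the Gaussian EAP of a tensor (a000 = 1)
fx_mapmri_gauss <- function(tensor, tau = fx_tau(), Nmax = 6) {
  fr <- dt_spectrum_to_frame(tensor, tau)
  n <- nrow(mapmri_index_set(Nmax))
  mapmri_eap(c(1, rep(0, n - 1)), Nmax, fr$s, fr$U, tau)
}

# Frozen non-Gaussian MAP-MRI fixture: unit-mass, non-negative on the
# [-5,5)^3 normalized lattice, strongly non-mono-exponential at high b.
fx_mapmri_nongauss <- function(tau = fx_tau()) {
  fr <- dt_spectrum_to_frame(diffusion_tensor(diag(c(1.6, 0.7, 0.4)) * 1e-3),
                             tau)
  co <- data.frame(n1 = c(0, 2, 0, 0, 4),
                   n2 = c(0, 0, 2, 0, 0),
                   n3 = c(0, 0, 0, 2, 0),
                   a = c(1, 0.10, -0.02, 0.04, 0.02))
  eap <- mapmri_eap(co, 6, fr$s, diag(3), tau)
  eap$a <- eap$a / mapmri_mass(eap)
  eap
}

fx_fodf_uniform <- function(L = 6) {
  sh_coefficients(c(1 / sqrt(4 * pi), rep(0, nrow(sh_index_set(L)) - 1)), L)
}

# Antipodally symmetrized von Mises-Fisher peak(s) projected to L = 6,
# unit mass.
fx_fodf_peaks <- function(mus, kappa = 15, L = 6) {
  f <- function(theta, phi) {
    v <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    out <- 0
    cn <- kappa / (4 * pi * sinh(kappa))
    for (mu in mus) {
      d <- as.numeric(v %*% mu)
      out <- out + cn * (exp(kappa * d) + exp(-kappa * d)) / 2
    }
    out / length(mus)
  }
  co <- project_to_sh(f, L, n_theta = 4 * L, n_phi = 8 * L)
  co$phi <- co$phi / (co$phi[1] * sqrt(4 * pi))
  co
}

fx_sc_twofiber <- function(tau = fx_tau()) {
  sc_eap(fx_fodf_peaks(list(c(1, 0, 0), c(0, 0, 1))),
         lambda_par = 2e-3, lambda_perp = 0.5e-3, tau = tau)
}

# CDF from a vectorized 1-D pdf by dense trapezoid, for ks.test
fx_cdf_from_pdf <- function(pdf, lower, upper, n = 4001) {
  x <- seq(lower, upper, length.out = n)
  d <- pdf(x)
  cdf <- cumsum((d[-1] + d[-n]) / 2 * diff(x))
  cdf <- c(0, cdf) / cdf[n - 1]
  stats::approxfun(x, cdf, yleft = 0, yright = 1)
}

# brute-force metric re-implementations used as oracles
naive_nmse <- function(sim, ref, idx) {
  sapply(seq_len(nrow(sim)), function(p)
    sum((sim[p, idx] - ref[p, idx])^2) / sum(ref[p, idx]^2))
}
naive_cor <- function(sim, ref, idx) {
  sapply(seq_len(nrow(sim)), function(p) cor(sim[p, idx], ref[p, idx]))
}

# Numeric PGSE phase oracle: Riemann integral of gamma * G(t) . r(t)
# over both pulses (sign flipped on the second), independent of the
# closed form it checks.
fx_phase_numeric <- function(r0, R, seq, nt = 20000) {
  path <- function(t) {
    frac <- pmin(pmax(t, 0), seq$Delta + seq$delta) / seq$Delta
    sweep(outer(frac, R), 2, r0, `+`)
  }
  Gvec <- seq$G * seq$dir
  int_pulse <- function(t0) {
    t <- seq(t0, t0 + seq$delta, length.out = nt)
    dt <- t[2] - t[1]
    gr <- as.numeric(path(t) %*% Gvec)
    (sum(gr) - (gr[1] + gr[nt]) / 2) * dt
  }
  seq$gamma * (int_pulse(0) - int_pulse(seq$Delta))
}
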