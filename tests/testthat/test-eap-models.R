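test_that("normalized Hermite functions reduce to the Gaussian at order 0", {
  expect_equal(hermite_basis_1d(0, 0, 1), 1 / sqrt(2 * pi))
  for (s in c(0.01, 1, 3)) {
    x <- seq(-3 * s, 3 * s, length.out = 11)
    expect_equal(hermite_basis_1d(0, x, s), dnorm(x, 0, s))
  }
  # odd orders vanish at the origin; order 2 has the closed-form value
  for (n in c(1, 3, 5)) expect_equal(hermite_basis_1d(n, 0, 1), 0)
  expect_equal(hermite_basis_1d(2, 0, 1), -2 / sqrt(16 * pi))
})

test_that("Gaussian EAP density matches its closed form and has unit mass", {
  dt <- diffusion_tensor(diag(3) * 1e-3)
  tau <- 0.05
  expect_equal(gaussian_eap_pdf(c(0, 0, 0), dt, tau),
               (4 * pi * tau * 1e-3)^(-1.5))
  # antipodal symmetry for a generic anisotropic tensor
  dtg <- fx_tensor("generic")
  R <- matrix(rnorm(30, sd = 0.01), 10, 3)
  expect_equal(gaussian_eap_pdf(R, dtg, tau), gaussian_eap_pdf(-R, dtg, tau))
  # 3-D trapezoid quadrature mass ~ 1
  g <- seq(-0.05, 0.05, length.out = 41)
  h <- g[2] - g[1]
  gr <- as.matrix(expand.grid(g, g, g))
  mass <- sum(gaussian_eap_pdf(gr, dt, tau)) * h^3
  expect_lt(abs(mass - 1), 1e-3)
  expect_error(gaussian_eap_pdf(c(0, 0, 0),
                                diffusion_tensor(diag(c(1e-3, 1e-3, 0))),
                                tau),
               "singular")
})

test_that("tensor spectrum maps to displacement scales s_i = sqrt(2 tau lambda_i)", {
  tau <- 0.05
  dt <- fx_tensor("generic")
  fr <- dt_spectrum_to_frame(dt, tau)
  expect_equal(fr$s, sqrt(2 * tau * dt$lambda))
  expect_equal(fr$s[1], sqrt(2 * 0.05 * 2e-3), tolerance = 1e-12)
  expect_true(all(diff(fr$s) <= 0))
  # U diag(s^2) U' reconstructs 2 tau D
  expect_equal(fr$U %*% (fr$s^2 * t(fr$U)), 2 * tau * dt$D,
               tolerance = 1e-12)
  # isotropic tensor: equal scales
  iso <- dt_spectrum_to_frame(diffusion_tensor(diag(3) * 1e-3), tau)
  expect_equal(iso$s, rep(sqrt(2 * tau * 1e-3), 3))
  expect_error(diffusion_tensor(diag(c(1, 1, -1)) * 1e-3), "negative")
})

test_that("MAP-MRI index set has the expected size and parity", {
  idx <- mapmri_index_set(6)
  expect_equal(nrow(idx), 50)  # 1 + 6 + 15 + 28
  expect_true(all((idx$n1 + idx$n2 + idx$n3) %% 2 == 0))
  expect_equal(nrow(mapmri_index_set(0)), 1)
})

test_that("a000-only MAP-MRI expansion is exactly the Gaussian EAP", {
  tau <- fx_tau()
  dt <- fx_tensor("prolate")
  eap <- fx_mapmri_gauss(dt, tau)
  R <- matrix(rnorm(300, sd = 0.008), 100, 3)
  expect_equal(mapmri_pdf(R, eap), gaussian_eap_pdf(R, dt, tau),
               tolerance = 1e-9)
  # unit scales at the origin: product of three H0(0; 1)
  eap1 <- mapmri_eap(c(1, rep(0, 49)), 6, c(1, 1, 1))
  expect_equal(mapmri_eap_pdf(c(0, 0, 0), eap1), (2 * pi)^(-1.5))
  expect_equal(mapmri_mass(eap), 1)
})

test_that("even-order MAP-MRI densities are antipodally symmetric", {
  eap <- fx_mapmri_nongauss()
  R <- matrix(rnorm(60, sd = 0.01), 20, 3)
  expect_equal(mapmri_eap_pdf(R, eap), mapmri_eap_pdf(-R, eap))
  expect_equal(mapmri_mass(eap), 1, tolerance = 1e-9)
})

test_that("real symmetric SH basis is orthonormal under spherical quadrature", {
  expect_equal(sh_basis(0, 0, 0.3, 1.2), 1 / sqrt(4 * pi))
  idx <- sh_index_set(6)
  expect_equal(nrow(idx), 28)
  q <- sphere_quadrature(16, 32)
  B <- sapply(seq_len(nrow(idx)), function(k)
    sh_basis(idx$l[k], idx$m[k], q$theta, q$phi))
  G <- t(B) %*% (q$w * B)
  expect_lt(max(abs(G - diag(nrow(idx)))), 1e-8)
  # m = 0 terms do not depend on phi
  phis <- seq(0, 2 * pi, length.out = 7)
  expect_equal(diff(range(sh_basis(4, 0, rep(1, 7), phis))), 0)
  expect_error(sh_basis(3, 0, 0.1, 0.1), "even")
  expect_error(sh_basis(2, 3, 0.1, 0.1), "exceed")
})

test_that("fODF evaluation is antipodally symmetric with quadrature mass phi00*sqrt(4pi)", {
  co <- fx_fodf_peaks(list(c(0, 0, 1)))
  th <- runif(15, 0, pi); ph <- runif(15, 0, 2 * pi)
  expect_equal(fodf_eval(co, th, ph),
               fodf_eval(co, pi - th, (ph + pi) %% (2 * pi)),
               tolerance = 1e-12)
  q <- sphere_quadrature(16, 32)
  expect_equal(sum(q$w * fodf_eval(co, q$theta, q$phi)),
               co$phi[1] * sqrt(4 * pi), tolerance = 1e-10)
  # phi00-only fODF is the uniform density
  u <- fx_fodf_uniform()
  expect_equal(fodf_eval(u, th, ph), rep(1 / (4 * pi), 15))
})

test_that("isotropic-kernel SC EAP equals the isotropic Gaussian EAP", {
  tau <- fx_tau()
  sc <- sc_eap(fx_fodf_uniform(), 1e-3, 1e-3, tau)
  dt <- diffusion_tensor(diag(3) * 1e-3)
  g <- seq(-0.04, 0.04, length.out = 21)
  gr <- as.matrix(expand.grid(g, g, g))
  ref <- gaussian_eap_pdf(gr, dt, tau)
  expect_lt(max(abs(sc_eap_pdf(gr, sc) - ref) / max(ref)), 1e-9)
  # antipodal symmetry of the anisotropic mixture
  tf <- fx_sc_twofiber(tau)
  R <- matrix(rnorm(30, sd = 0.01), 10, 3)
  expect_equal(sc_eap_pdf(R, tf), sc_eap_pdf(-R, tf), tolerance = 1e-12)
  expect_error(sc_eap(fx_fodf_uniform(), 1e-3, 2e-3, tau), "kernel")
})

test_that("uniform-fODF SC second moment is 2 tau (lpar + 2 lperp)/3 I", {
  tau <- fx_tau()
  sc <- sc_eap(fx_fodf_uniform(), 2e-3, 0.5e-3, tau)
  # quadrature of R R' against the density on a +-4 sd box
  sd_max <- sqrt(2 * tau * 2e-3)
  g <- seq(-4 * sd_max, 4 * sd_max, length.out = 25)
  h <- g[2] - g[1]
  gr <- as.matrix(expand.grid(g, g, g))
  d <- sc_eap_pdf(gr, sc)
  M <- unname(t(gr) %*% (d * gr) * h^3)
  expected <- 2 * tau * (2e-3 + 2 * 0.5e-3) / 3 * diag(3)
  expect_equal(M, expected, tolerance = 5e-3)
})
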