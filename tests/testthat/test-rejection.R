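test_that("rejection sampling accepts everything when target equals wrapper", {
  set.seed(11)
  res <- rejection_sample(
    target_pdf = function(u) dnorm(u[, 1]),
    wrapper_pdf = function(u) dnorm(u[, 1]),
    wrapper_sampler = function(k) matrix(rnorm(k), k, 1),
    c = 1, n = 5000)
  expect_equal(res$acceptance_rate, 1)
  expect_equal(nrow(res$samples), 5000)
})

test_that("1-D rejection samples follow the target law (KS) with rate near 1/c", {
  set.seed(12)
  cc <- 1.2 * dnorm(0) / dnorm(0, 0, 1.2)  # exact sup ratio = 1.2
  res <- rejection_sample(
    target_pdf = function(u) dnorm(u[, 1]),
    wrapper_pdf = function(u) dnorm(u[, 1], 0, 1.2),
    wrapper_sampler = function(k) matrix(rnorm(k, 0, 1.2), k, 1),
    c = 1.2, n = 1e5)
  expect_gt(ks.test(res$samples[, 1], pnorm)$p.value, 0.01)
  se <- sqrt((1 / 1.2) * (1 - 1 / 1.2) / (1e5 / res$acceptance_rate))
  expect_lt(abs(res$acceptance_rate - 1 / 1.2), 3 * se)
})

test_that("hopeless wrapper bounds raise a diagnostic error naming c", {
  set.seed(13)
  expect_error(
    rejection_sample(
      target_pdf = function(u) dnorm(u[, 1]),
      wrapper_pdf = function(u) dnorm(u[, 1]),
      wrapper_sampler = function(k) matrix(rnorm(k), k, 1),
      c = 5000, n = 100),
    "acceptance rate")
})

test_that("negative target regions are cropped: no sample lands there", {
  set.seed(14)
  target <- function(u) ifelse(u[, 1] > 0, 2 * dnorm(u[, 1]), -0.5)
  res <- rejection_sample(
    target_pdf = target,
    wrapper_pdf = function(u) dnorm(u[, 1], 0, 1.5),
    wrapper_sampler = function(k) matrix(rnorm(k, 0, 1.5), k, 1),
    c = 2 * dnorm(0) / dnorm(0, 0, 1.5) * 1.05, n = 2e4)
  expect_true(all(res$samples[, 1] > 0))
})

test_that("MAP-MRI wrapper search returns nu = 1.1 with c = nu^3 for a pure Gaussian", {
  eap <- fx_mapmri_gauss(fx_tensor("generic"))
  w <- build_mapmri_wrapper(eap)
  expect_equal(w$nu, 1.1)
  expect_equal(w$c_raw, 1.1^3, tolerance = 1e-12)
  expect_equal(w$c_by_nu, seq(1.1, 1.5, 0.1)^3, tolerance = 1e-12)
  expect_equal(w$c, 1.05 * 1.1^3, tolerance = 1e-12)
  expect_gte(w$c, 1)
  # perturbing the expansion can only increase the sup ratio
  wn <- build_mapmri_wrapper(fx_mapmri_nongauss())
  expect_gt(wn$c_raw, 1.1^3)
})

test_that("fODF wrapper constant is the lattice max of the fODF-to-uniform ratio", {
  wu <- build_fodf_wrapper(fx_fodf_uniform())
  expect_equal(wu$c_raw, 1, tolerance = 1e-12)
  expect_gte(wu$c, 1)
  co <- fx_fodf_peaks(list(c(1, 0, 0), c(0, 0, 1)))
  w <- build_fodf_wrapper(co)
  expect_gte(w$c_raw, 1)
  # brute-force max on a denser lattice agrees within 1%
  th <- pi * (0:539) / 540; ph <- 2 * pi * (0:1079) / 1080
  gr <- expand.grid(th = th, ph = ph)
  cmax <- 4 * pi * max(fodf_eval(co, gr$th, gr$ph))
  expect_lt(abs(w$c_raw - cmax) / cmax, 0.01)
})

test_that("MAP-MRI sampler reproduces Gaussian moments and is seed-deterministic", {
  tau <- fx_tau()
  dt <- fx_tensor("prolate")
  eap <- fx_mapmri_gauss(dt, tau)
  w <- build_mapmri_wrapper(eap)
  b <- sample_mapmri(eap, 3e4, seed = 21, wrapper = w)
  cv <- cov(b$displacements)
  ref <- 2 * tau * dt$D
  expect_lt(norm(cv - ref, "F") / norm(ref, "F"), 0.03)
  # zero mean within 4 sd / sqrt(n) per axis
  sds <- sqrt(diag(ref))
  expect_true(all(abs(colMeans(b$displacements)) < 4 * sds / sqrt(3e4)))
  b2 <- sample_mapmri(eap, 3e4, seed = 21, wrapper = w)
  expect_identical(b$displacements, b2$displacements)
})

test_that("SC sampler covariance matches the orientation-mixture prediction", {
  tau <- fx_tau()
  # concentrated single peak along z: covariance ~ single-tensor
  co <- fx_fodf_peaks(list(c(0, 0, 1)), kappa = 30)
  sc <- sc_eap(co, 2e-3, 0.5e-3, tau)
  b <- sample_sc(sc, 3e4, seed = 22)
  cv <- cov(b$displacements)
  # mixture covariance from the same quadrature the density uses
  q <- sphere_quadrature(48, 96)
  f <- pmax(fodf_eval(co, q$theta, q$phi), 0)
  wts <- q$w * f / sum(q$w * f)
  V <- cbind(q$vx, q$vy, q$vz)
  ref <- 2 * tau * (0.5e-3 * diag(3) +
                      (2e-3 - 0.5e-3) * t(V) %*% (wts * V))
  expect_lt(norm(cv - ref, "F") / norm(ref, "F"), 0.05)
  # uniform fODF: isotropic covariance 2 tau (lpar + 2 lperp)/3 I
  bu <- sample_sc(sc_eap(fx_fodf_uniform(), 2e-3, 0.5e-3, tau), 3e4,
                  seed = 23)
  refu <- 2 * tau * (2e-3 + 2 * 0.5e-3) / 3 * diag(3)
  expect_lt(norm(cov(bu$displacements) - refu, "F") / norm(refu, "F"), 0.05)
})

test_that("equal kernel eigenvalues make the SC sampler isotropic Gaussian", {
  tau <- fx_tau()
  sc <- sc_eap(fx_fodf_peaks(list(c(1, 0, 0))), 1e-3, 1e-3, tau)
  b <- sample_sc(sc, 3e4, seed = 24)
  sd0 <- sqrt(2 * tau * 1e-3)
  for (ax in 1:3)
    expect_gt(ks.test(b$displacements[, ax], pnorm, 0, sd0)$p.value, 0.01)
})

test_that("direct Gaussian sampling has covariance 2 tau D with ordered axis variances", {
  tau <- 0.05
  dt <- diffusion_tensor(diag(c(2, 1, 0.5)) * 1e-3)
  b <- sample_gaussian(dt, tau, 3e4, seed = 25)
  ref <- 2 * tau * dt$D
  expect_lt(norm(cov(b$displacements) - ref, "F") / norm(ref, "F"), 0.03)
  v <- apply(b$displacements, 2, var)
  expect_true(all(diff(v) < 0))  # follows lambda_x >= lambda_y >= lambda_z
  # degenerate tensor: all displacements zero
  b0 <- sample_gaussian(diffusion_tensor(matrix(0, 3, 3)), tau, 100,
                        seed = 26)
  expect_true(all(b0$displacements == 0))
})
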