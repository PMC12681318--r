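test_that("NMSE matches its definition and a brute-force reimplementation", {
  set.seed(51)
  sim <- matrix(runif(20 * 12, 0.5, 2), 20, 12)
  ref <- matrix(runif(20 * 12, 0.5, 2), 20, 12)
  shells <- list(`300` = 1:6, `600` = 7:12)
  out <- nmse(sim, ref, shells)
  for (k in 1:2)
    expect_equal(out[, k], naive_nmse(sim, ref, shells[[k]]),
                 tolerance = 1e-12)
  expect_equal(unname(nmse(ref, ref, shells)),
               matrix(0, 20, 2))
  expect_equal(unname(nmse(2 * ref, ref, shells)),
               matrix(1, 20, 2), tolerance = 1e-12)
  # single-gradient shell with additive error
  expect_equal(nmse(ref + 0.1, ref, list(s = 3))[, 1],
               0.01 / ref[, 3]^2, tolerance = 1e-12)
  # zero reference energy -> NA
  ref0 <- ref; ref0[1, 1:6] <- 0
  expect_true(is.na(nmse(sim, ref0, shells)[1, 1]))
})

test_that("global least-squares calibration recovers proportional scales", {
  set.seed(52)
  ref <- matrix(runif(50, 1, 3), 10, 5)
  out <- normalize_scale(ref / 3, ref)
  expect_equal(attr(out, "alpha"), 3, tolerance = 1e-12)
  expect_equal(as.numeric(out), as.numeric(ref), tolerance = 1e-12)
  expect_equal(attr(normalize_scale(ref, ref), "alpha"), 1,
               tolerance = 1e-12)
  # orthogonal inputs: degenerate zero factor
  a <- c(1, 0); b <- c(0, 1)
  out2 <- normalize_scale(a, b)
  expect_equal(attr(out2, "alpha"), 0)
  expect_true(isTRUE(attr(out2, "degenerate")))
  expect_error(normalize_scale(c(0, 0), b), "all-zero")
})

test_that("correlation maps accept proportional signals at every level", {
  set.seed(53)
  ref <- matrix(runif(8 * 10, 1, 2), 8, 10)
  shells <- list(`1000` = 1:10)
  cm <- correlation_map(2 * ref + 1, ref, shells)[[1]]
  expect_equal(cm$r, rep(1, 8))
  expect_equal(cm$level, rep(0.9, 8))
  expect_equal(cm$color, rep("purple", 8))
  # anti-correlated signals are black
  cm2 <- correlation_map(-ref, ref, shells)[[1]]
  expect_true(all(cm2$r < 0))
  expect_true(all(is.na(cm2$level)))
  expect_equal(cm2$color, rep("black", 8))
  # zero-variance rows are flagged black, not errors
  sim <- ref; sim[1, ] <- 5
  cm3 <- correlation_map(sim, ref, shells)[[1]]
  expect_true(is.na(cm3$r[1]) && cm3$color[1] == "black")
  expect_error(correlation_map(ref, ref, list(s = 1:3)), "fewer than 4")
})

test_that("accepted correlation levels are downward closed and match brute force", {
  set.seed(54)
  sim <- matrix(rnorm(40 * 16, 10, 2), 40, 16)
  ref <- sim + matrix(rnorm(40 * 16, 0, 2), 40, 16)
  shells <- list(b = 1:16)
  cm <- correlation_map(sim, ref, shells, alpha = 0.05)[[1]]
  expect_equal(cm$r, naive_cor(sim, ref, 1:16), tolerance = 1e-12)
  # reconstruct acceptance per level and check downward closure + max
  levels <- seq(0.5, 0.9, 0.1)
  for (p in 1:40) {
    acc <- sapply(levels, function(rho0)
      (atanh(cm$r[p]) - atanh(rho0)) * sqrt(16 - 3) >= qnorm(0.05))
    expect_equal(cm$level[p],
                 if (any(acc)) max(levels[acc]) else NA_real_)
    if (any(acc)) expect_true(all(acc[seq_len(max(which(acc)))]))
  }
})

test_that("log-linear DTI fit recovers noise-free tensors to machine precision", {
  tab <- make_gradient_table(shells = c(300, 600, 900, 1200),
                             directions_per_shell = 8)
  dt <- fx_tensor("generic")
  att <- exp(-tab$b * rowSums((tab$dirs %*% dt$D) * tab$dirs))
  S <- rbind(1000 * att, 800 * att)  # two pixels, different baselines
  fit <- fit_dti(S, tab)
  for (p in 1:2) {
    D <- matrix(c(fit$dxx[p], fit$dxy[p], fit$dxz[p],
                  fit$dxy[p], fit$dyy[p], fit$dyz[p],
                  fit$dxz[p], fit$dyz[p], fit$dzz[p]), 3, 3)
    expect_equal(D, dt$D, tolerance = 1e-12)
  }
  # isotropic signals: FA = 0
  iso <- exp(-tab$b * 1e-3)
  fiso <- fit_dti(matrix(iso, 1, byrow = TRUE), tab)
  expect_equal(fiso$fa, 0, tolerance = 1e-9)
  # permutation invariance of the design
  perm <- c(1, sample(2:length(tab$b)))
  tab2 <- gradient_table(tab$b[perm], tab$dirs[perm, ])
  fit2 <- fit_dti(S[, perm, drop = FALSE], tab2)
  expect_equal(fit2$dxx, fit$dxx, tolerance = 1e-12)
  # non-positive signals exclude the pixel
  bad <- S; bad[1, 5] <- 0
  expect_true(is.na(fit_dti(bad, tab)$fa[1]))
})

test_that("orientation color code is FA-weighted |e1| with antipodal invariance", {
  fit <- data.frame(fa = c(1, 0, 0.5),
                    e1x = c(1, 1, -0.6), e1y = c(0, 0, 0.8),
                    e1z = c(0, 0, 0))
  rgb <- color_orientation_map(fit)
  expect_equal(rgb[1, ], c(r = 1, g = 0, b = 0))      # right-left = red
  expect_equal(rgb[2, ], c(r = 0, g = 0, b = 0))      # FA 0 = black
  fit2 <- fit; fit2$e1x <- -fit$e1x; fit2$e1y <- -fit$e1y
  expect_equal(color_orientation_map(fit2), rgb)
})

test_that("proton density inverts the ideal spin-echo weighting", {
  # the cardiac protocol's TE/TR with T1 = 1 s, T2 = 50 ms
  rho <- estimate_pd(100, T1 = 1, T2 = 0.05, TE = 0.113725, TR = 50.033)
  expect_equal(as.numeric(rho),
               100 / ((1 - exp(-50.033 / 1)) * exp(-0.113725 / 0.05)),
               tolerance = 1e-12)
  expect_equal(as.numeric(rho), 971.9, tolerance = 0.005)
  # TE -> 0 and TR >> T1: rho = S
  expect_equal(as.numeric(estimate_pd(42, 1, 0.05, 0, 100)), 42,
               tolerance = 1e-9)
  # monotone in TE
  tes <- seq(0.01, 0.2, length.out = 8)
  vals <- sapply(tes, function(te) estimate_pd(10, 1, 0.05, te, 50))
  expect_true(all(diff(vals) > 0))
  # unstable flag when the denominator vanishes
  u <- estimate_pd(1, T1 = 1000, T2 = 0.001, TE = 0.1, TR = 0.001)
  expect_true(attr(u, "unstable"))
})
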