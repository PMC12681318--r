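#' Multi-shell gradient table
#'
#' Constructs a gradient table in the FSL dialect (b-values plus unit
#' direction columns, zero columns for b = 0).  Directions within each
#' shell are placed on a deterministic spherical Fibonacci lattice
#' (golden-angle spiral), which spreads points more evenly than random
#' draws.
#'
#' @param shells b-values, s/mm^2 (default: the 6-shell cardiac
#'   protocol 300/600/900/1200/2000/3600).
#' @param directions_per_shell number of directions on each shell.
#' @param n_b0 number of baseline (b = 0) entries, prepended.
#' @return object of class `gradient_table`: data.frame-backed list
#'   with `b` (length n) and `dirs` (n x 3, unit rows; zero rows for
#'   baselines).
#' @export
make_gradient_table <- function(shells = c(300, 600, 900, 1200, 2000, 3600),
                                directions_per_shell = 32, n_b0 = 1) {
  stopifnot(directions_per_shell >= 1, n_b0 >= 0)
  dirs1 <- .fibonacci_sphere(directions_per_shell)
  b <- c(rep(0, n_b0), rep(shells, each = directions_per_shell))
  dirs <- rbind(matrix(0, n_b0, 3),
                dirs1[rep(seq_len(directions_per_shell), length(shells)), ,
                      drop = FALSE])
  gradient_table(b, dirs)
}

#' @rdname make_gradient_table
#' @param b numeric b-values, s/mm^2.
#' @param dirs n x 3 direction matrix; non-unit rows with b > 0 are
#'   normalized with a warning.
#' @export
gradient_table <- function(b, dirs) {
  dirs <- .as_points(dirs)
  dimnames(dirs) <- NULL
  if (length(b) != nrow(dirs))
    stop("b-values and directions have mismatched lengths")
  nrm <- sqrt(rowSums(dirs^2))
  if (any(b > 0 & nrm == 0)) stop("zero direction with non-zero b-value")
  bad <- b > 0 & abs(nrm - 1) > 1e-6
  if (any(bad)) {
    warning(sum(bad), " non-unit direction(s) normalized")
    dirs[bad, ] <- dirs[bad, ] / nrm[bad]
  }
  dirs[b == 0, ] <- 0
  structure(list(b = as.numeric(b), dirs = dirs), class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  sh <- sort(unique(x$b[x$b > 0]))
  cat(sprintf("gradient_table: %d entries (%d baseline), shells: %s\n",
              length(x$b), sum(x$b == 0), paste(sh, collapse = " ")))
  invisible(x)
}

# Deterministic golden-angle spiral on the unit sphere.
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shell grouping of a gradient table
#'
#' Maps each non-baseline entry to its shell; b = 0 entries are
#' excluded from every shell.
#'
#' @param table a [gradient_table()].
#' @param tol relative tolerance when matching b-values to shells.
#' @return named list: one integer index vector per shell (names are
#'   the shell b-values, ascending).
#' @export
shell_grouping <- function(table, tol = 1e-6) {
  stopifnot(inherits(table, "gradient_table"))
  b <- table$b
  shells <- sort(unique(b[b > 0]))
  out <- lapply(shells, function(s) which(abs(b - s) <= tol * max(s, 1)))
  names(out) <- as.character(shells)
  out
}

#' Synthetic phantom fiber fields
#'
#' Builds a 2-D grid phantom whose voxels carry ground-truth EAPs and
#' tissue parameters, emulating the kind of object a cardiac DWI study
#' images without requiring any acquisition:
#'
#' * `uniform` - every voxel holds the same diffusion tensor (default
#'   `diag(2, 1, 0.5) * 1e-3 mm^2/s`); a full rectangle.
#' * `circular_myocardium` - an annulus in which the principal
#'   eigenvector is tangent to concentric circles around the grid
#'   center, mimicking the smoothly rotating fiber field of a
#'   short-axis myocardial wall; tensors have eigenvalues
#'   `(lambda_par, lambda_perp, lambda_perp)`.
#' * `crossing` - spherical-convolution fODFs: a single peak along x on
#'   the left third, along y on the right third, and a two-peak
#'   crossing fODF in the central band.  Peaks are antipodally
#'   symmetrized von Mises-Fisher lobes projected to degree `L`.
#'
#' Tissue defaults are cardiac-like: T1 = 1 s, T2 = 0.05 s, PD = 1.
#' All generators are pure functions of `(preset, grid, seed)`.
#'
#' @param preset one of `"uniform"`, `"circular_myocardium"`,
#'   `"crossing"`.
#' @param grid integer length-2 grid shape.
#' @param spacing voxel spacing, mm.
#' @param seed integer recorded in the spec (generators are
#'   deterministic; the seed feeds any randomized extension).
#' @param lambda_par,lambda_perp tensor/kernel eigenvalues, mm^2/s.
#' @param tau diffusion time attached to SC EAPs, s.
#' @param L maximum SH degree for fODF presets.
#' @param kappa von Mises-Fisher concentration of fODF peaks.
#' @param T1,T2,PD tissue parameters (s, s, a.u.).
#' @return object of class `phantom_spec`: list with `dims`, `spacing`,
#'   `preset`, `seed`, `voxels` (data.frame `ix`, `iy`, `x`, `y`,
#'   `eap_id`), `eaps` (list of EAP objects), `tissue` (data.frame
#'   `T1`, `T2`, `PD` per voxel).
#' @export
make_fiber_field <- function(preset = c("uniform", "circular_myocardium",
                                        "crossing"),
                             grid = c(16, 16), spacing = 1, seed = 0,
                             lambda_par = 2e-3, lambda_perp = 0.5e-3,
                             tau = 0.05, L = 6, kappa = 15,
                             T1 = 1, T2 = 0.05, PD = 1) {
  preset <- match.arg(preset)
  stopifnot(length(grid) == 2, all(grid >= 2))
  nx <- grid[1]; ny <- grid[2]
  ctr <- (c(nx, ny) + 1) / 2
  vox <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  vox$x <- (vox$ix - ctr[1]) * spacing
  vox$y <- (vox$iy - ctr[2]) * spacing

  if (preset == "uniform") {
    eaps <- list(diffusion_tensor(diag(c(2, 1, 0.5)) * 1e-3))
    eap_id <- rep(1L, nrow(vox))
  } else if (preset == "circular_myocardium") {
    half <- min(nx, ny) / 2 * spacing
    r <- sqrt(vox$x^2 + vox$y^2)
    inside <- r >= 0.55 * half & r <= 0.90 * half
    vox <- vox[inside, , drop = FALSE]
    r <- r[inside]
    eaps <- vector("list", nrow(vox))
    for (k in seq_len(nrow(vox))) {
      radial <- c(vox$x[k], vox$y[k], 0) / r[k]
      tangent <- c(-radial[2], radial[1], 0)
      U <- cbind(tangent, radial, c(0, 0, 1))
      D <- U %*% (c(lambda_par, lambda_perp, lambda_perp) * t(U))
      eaps[[k]] <- diffusion_tensor(D)
    }
    eap_id <- seq_len(nrow(vox))
  } else {  # crossing
    fod_x <- .peak_fodf(list(c(1, 0, 0)), kappa, L)
    fod_y <- .peak_fodf(list(c(0, 1, 0)), kappa, L)
    fod_xy <- .peak_fodf(list(c(1, 0, 0), c(0, 1, 0)), kappa, L)
    eaps <- list(sc_eap(fod_x, lambda_par, lambda_perp, tau),
                 sc_eap(fod_xy, lambda_par, lambda_perp, tau),
                 sc_eap(fod_y, lambda_par, lambda_perp, tau))
    band <- cut(vox$ix, breaks = c(0, nx / 3, 2 * nx / 3, nx),
                labels = FALSE)
    eap_id <- as.integer(band)
  }
  rownames(vox) <- NULL
  vox$eap_id <- eap_id
  structure(list(dims = grid, spacing = spacing, preset = preset,
                 seed = seed, voxels = vox, eaps = eaps,
                 tissue = data.frame(T1 = rep(T1, nrow(vox)),
                                     T2 = rep(T2, nrow(vox)),
                                     PD = rep(PD, nrow(vox)))),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec '%s': %d x %d grid, %d voxels, %d unique EAP(s)\n",
              x$preset, x$dims[1], x$dims[2], nrow(x$voxels),
              length(x$eaps)))
  invisible(x)
}

# Antipodally symmetrized von Mises-Fisher mixture projected to SH,
# renormalized to unit spherical mass.
.peak_fodf <- function(mus, kappa, L) {
  f <- function(theta, phi) {
    v <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    out <- 0
    cnorm <- kappa / (4 * pi * sinh(kappa))
    for (mu in mus) {
      d <- as.numeric(v %*% mu)
      out <- out + cnorm * (exp(kappa * d) + exp(-kappa * d)) / 2
    }
    out / length(mus)
  }
  co <- project_to_sh(f, L, n_theta = 4 * L, n_phi = 8 * L)
  co$phi <- co$phi / (co$phi[1] * sqrt(4 * pi))
  co
}

#' Analytic PGSE signal of an EAP
#'
#' Expected attenuation `E[exp(-i q . R)]` (the EAP characteristic
#' function at the q-vector), computed independently of any sampling:
#'
#' * Gaussian tensor: closed form `exp(-tau q' D q)`, i.e.
#'   `exp(-b ghat' D ghat)`.
#' * Spherical convolution: spherical quadrature of the fODF against
#'   the per-orientation Gaussian closed form.  Negative fODF lobes
#'   (truncation artifacts) are cropped and the weights renormalized,
#'   matching the law the rejection sampler draws from.
#' * MAP-MRI: the Fourier integral separates per axis, so each term is
#'   a product of three 1-D quadratures of Hermite basis functions
#'   against `exp(-i q t)` (dense trapezoid; the Gaussian decay makes
#'   the truncation error negligible).
#'
#' This is the universal oracle against which the spin-level simulator
#' is validated.
#'
#' @param eap a `diffusion_tensor`, `mapmri_eap` or `sc_eap`.
#' @param q q-vector(s), rad/mm: length-3 vector or n x 3 matrix.
#' @param tau diffusion time, s (tensor EAPs only).
#' @param n_theta,n_phi spherical quadrature orders (SC only).
#' @return complex attenuation(s); 1 at q = 0 for unit-mass EAPs.
#' @export
analytic_signal <- function(eap, q, tau = NULL, n_theta = 48, n_phi = 96) {
  q <- .as_points(q)
  if (inherits(eap, "diffusion_tensor")) {
    if (is.null(tau)) stop("tau is required for tensor EAPs")
    qf <- rowSums((q %*% eap$D) * q)
    return(complex(real = exp(-tau * qf)))
  }
  if (inherits(eap, "sc_eap")) {
    nd <- .sc_nodes(eap, n_theta, n_phi)
    # negative truncation lobes are cropped and renormalized: this is
    # the density the rejection sampler actually draws from
    wf <- pmax(nd$wf, 0)
    wf <- wf / sum(wf)
    qv <- q %*% t(nd$V)                 # n_q x n_nodes
    q2 <- rowSums(q^2)
    expo <- exp(-eap$tau *
                  (q2 %o% rep(eap$lambda_perp, ncol(qv)) +
                     qv^2 * (eap$lambda_par - eap$lambda_perp)))
    return(complex(real = as.numeric(expo %*% wf)))
  }
  if (inherits(eap, "mapmri_eap")) {
    qp <- q %*% eap$U
    out <- complex(length.out = nrow(q))
    # 1-D Fourier integrals I_n(q; s) for every needed order and axis
    for (j in seq_len(nrow(q))) {
      I <- matrix(0i, eap$Nmax + 1, 3)
      for (ax in 1:3) {
        s <- eap$scales[ax]
        tgrid <- seq(-8 * s, 8 * s, length.out = 4001)
        dt <- tgrid[2] - tgrid[1]
        ph <- exp(-1i * qp[j, ax] * tgrid)
        for (n in 0:eap$Nmax)
          I[n + 1, ax] <- sum(hermite_basis_1d(n, tgrid, s) * ph) * dt
      }
      out[j] <- sum(eap$a *
                      I[eap$index$n1 + 1, 1] *
                      I[eap$index$n2 + 1, 2] *
                      I[eap$index$n3 + 1, 3])
    }
    return(out)
  }
  stop("unsupported EAP class")
}
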