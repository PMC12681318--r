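#' Simulate a diffusion-weighted image stack from a spin phantom
#'
#' Monte-Carlo spin-level PGSE simulation.  Each grid position is
#' populated with `spins_per_voxel` spins (default 2000) sharing the
#' voxel's EAP and tissue tuple `(T1, T2, PD)`; each spin draws an
#' independent net displacement from the EAP and accrues the phase
#' `-q . R` of the constant-velocity linear path.  The complex voxel
#' signal is the relaxation-weighted phasor sum; at b = 0 it equals the
#' baseline exactly.
#'
#' Displacements are redrawn independently for every gradient by
#' default (each DWI is an independent diffusion experiment); set
#' `redraw_per_gradient = FALSE` to freeze one draw per voxel across
#' the whole table (variance studies).  Gradient amplitudes are solved
#' from each table b-value with the template's fixed `(delta, Delta)`.
#'
#' Gaussian-tensor voxels use the exact direct sampler, vectorized
#' across the whole phantom; MAP-MRI and SC voxels go through the
#' rejection samplers, with one wrapper built per distinct EAP and
#' reused across gradients.
#'
#' @param phantom a [make_fiber_field()] `phantom_spec`.
#' @param table a [gradient_table()].
#' @param seq_template a [pgse_sequence()] providing `delta`, `Delta`,
#'   `TE`, `TR`, `gamma`.
#' @param spins_per_voxel spins per grid position.
#' @param seed integer seed for all sampling in the stack.
#' @param redraw_per_gradient logical, see above.
#' @return object of class `dwi_stack`: list with `signal` (complex
#'   n_voxels x n_entries), `table`, `voxels`, `baseline_index`,
#'   `spins_per_voxel`, `seed`, and `sampler_info` (per distinct EAP:
#'   c, nu, acceptance rate).
#' @export
simulate_dwi_stack <- function(phantom, table, seq_template,
                               spins_per_voxel = 2000, seed = NULL,
                               redraw_per_gradient = TRUE) {
  stopifnot(inherits(phantom, "phantom_spec"),
            inherits(table, "gradient_table"),
            inherits(seq_template, "pgse_sequence"))
  if (!is.null(seed)) set.seed(seed)
  nv <- nrow(phantom$voxels)
  ns <- spins_per_voxel
  ne <- length(table$b)
  tau <- seq_template$tau
  w <- phantom$tissue$PD *
    (1 - exp(-seq_template$TR / phantom$tissue$T1)) *
    exp(-seq_template$TE / phantom$tissue$T2)

  qmat <- .table_q(table, seq_template)          # ne x 3, rad/mm
  eap_id <- phantom$voxels$eap_id
  is_gauss <- vapply(phantom$eaps, inherits, logical(1), "diffusion_tensor")
  gauss_vox <- which(is_gauss[eap_id])
  other_ids <- which(!is_gauss)

  # sqrt(2 tau) D^(1/2), one 3x3 per Gaussian voxel, stored row-wise
  A <- NULL
  if (length(gauss_vox)) {
    A <- matrix(0, nv, 9)
    for (id in unique(eap_id[gauss_vox])) {
      dt <- phantom$eaps[[id]]
      Ai <- dt$U %*% (sqrt(2 * tau * dt$lambda) * t(dt$U))
      A[eap_id == id, ] <- matrix(Ai, 1, 9)[rep(1, sum(eap_id == id)), ]
    }
  }
  wrappers <- lapply(other_ids, function(id) {
    e <- phantom$eaps[[id]]
    if (inherits(e, "mapmri_eap")) build_mapmri_wrapper(e)
    else build_fodf_wrapper(e$fodf)
  })
  names(wrappers) <- as.character(other_ids)
  acc_rates <- stats::setNames(rep(NA_real_, length(other_ids)),
                               as.character(other_ids))

  frozen <- NULL
  if (!redraw_per_gradient)
    frozen <- .draw_all_displacements(phantom, A, gauss_vox, other_ids,
                                      wrappers, ns, tau)

  signal <- matrix(complex(real = 0), nv, ne)
  for (j in seq_len(ne)) {
    qj <- qmat[j, ]
    if (all(qj == 0)) {
      signal[, j] <- w * ns
      next
    }
    re <- numeric(nv); im <- numeric(nv)
    if (!is.null(frozen)) {
      phi <- -as.numeric(frozen %*% qj)
      dim(phi) <- c(ns, nv)
      re <- colSums(cos(phi)); im <- colSums(sin(phi))
    } else {
      if (length(gauss_vox)) {
        # phi = -q' A Z = Z . p with p = -A q (A symmetric): draw the
        # standard normals in bulk and project per voxel
        p <- cbind(A[gauss_vox, 1] * qj[1] + A[gauss_vox, 2] * qj[2] +
                     A[gauss_vox, 3] * qj[3],
                   A[gauss_vox, 4] * qj[1] + A[gauss_vox, 5] * qj[2] +
                     A[gauss_vox, 6] * qj[3],
                   A[gauss_vox, 7] * qj[1] + A[gauss_vox, 8] * qj[2] +
                     A[gauss_vox, 9] * qj[3])
        ng <- length(gauss_vox)
        Z <- matrix(stats::rnorm(ns * ng * 3), ns * ng, 3)
        pij <- p[rep(seq_len(ng), each = ns), , drop = FALSE]
        phi <- -(Z[, 1] * pij[, 1] + Z[, 2] * pij[, 2] + Z[, 3] * pij[, 3])
        dim(phi) <- c(ns, ng)
        re[gauss_vox] <- colSums(cos(phi))
        im[gauss_vox] <- colSums(sin(phi))
      }
      for (id in other_ids) {
        vox <- which(eap_id == id)
        if (!length(vox)) next
        batch <- sample_eap(phantom$eaps[[id]], ns * length(vox),
                            wrapper = wrappers[[as.character(id)]])
        acc_rates[as.character(id)] <- batch$acceptance_rate
        phi <- -as.numeric(batch$displacements %*% qj)
        dim(phi) <- c(ns, length(vox))
        re[vox] <- colSums(cos(phi))
        im[vox] <- colSums(sin(phi))
      }
    }
    signal[, j] <- w * complex(real = re, imaginary = im)
  }
  structure(list(signal = signal, table = table,
                 voxels = phantom$voxels, preset = phantom$preset,
                 baseline_index = which(table$b == 0),
                 spins_per_voxel = ns, seed = seed,
                 sampler_info = list(
                   wrappers = wrappers, acceptance_rates = acc_rates)),
            class = "dwi_stack")
}

# q-vectors of every table entry under the sequence template.
.table_q <- function(table, seq_template) {
  G <- sqrt(table$b / (seq_template$gamma^2 * seq_template$delta^2 *
                         seq_template$tau))
  (seq_template$gamma * seq_template$delta * G) * table$dirs
}

# One displacement draw per spin per voxel (ns * nv x 3), voxel-major.
.draw_all_displacements <- function(phantom, A, gauss_vox, other_ids,
                                    wrappers, ns, tau) {
  nv <- nrow(phantom$voxels)
  out <- matrix(0, ns * nv, 3)
  idx <- function(v) ((v - 1) * ns + 1):(v * ns)
  if (length(gauss_vox)) {
    Z <- matrix(stats::rnorm(ns * length(gauss_vox) * 3), ncol = 3)
    for (k in seq_along(gauss_vox)) {
      v <- gauss_vox[k]
      Ai <- matrix(A[v, ], 3, 3)
      out[idx(v), ] <- Z[((k - 1) * ns + 1):(k * ns), ] %*% Ai
    }
  }
  for (id in other_ids) {
    vox <- which(phantom$voxels$eap_id == id)
    if (!length(vox)) next
    batch <- sample_eap(phantom$eaps[[id]], ns * length(vox),
                        wrapper = wrappers[[as.character(id)]])
    for (k in seq_along(vox))
      out[idx(vox[k]), ] <-
        batch$displacements[((k - 1) * ns + 1):(k * ns), ]
  }
  out
}

#' @export
print.dwi_stack <- function(x, ...) {
  cat(sprintf("dwi_stack: %d voxels x %d entries (%d baseline), %d spins/voxel\n",
              nrow(x$signal), ncol(x$signal), length(x$baseline_index),
              x$spins_per_voxel))
  invisible(x)
}

#' Magnitude attenuation of a DWI stack
#'
#' Per-voxel magnitude signal divided by the (mean) baseline magnitude.
#'
#' @param stack a `dwi_stack`.
#' @return numeric matrix, n_voxels x n_entries.
#' @export
stack_attenuation <- function(stack) {
  stopifnot(inherits(stack, "dwi_stack"))
  s0 <- rowMeans(abs(stack$signal[, stack$baseline_index, drop = FALSE]))
  abs(stack$signal) / s0
}

#' Ideal Cartesian k-space encoding of a spin ensemble
#'
#' Simplified imaging layer: samples Cartesian k-space as
#' `S(k) = sum_s w_s exp(i phi_s) exp(-i 2 pi k . r_s)` on an
#' `matrix_size` grid with spacing `1/FOV`, and reconstructs by inverse
#' discrete Fourier transform onto the pixel grid.  Voxelwise
#' magnitudes agree with [voxel_signal()] up to discretization (the
#' point-spread function of the finite matrix).
#'
#' @param r n x 2 spin positions, mm.
#' @param weights per-spin relaxation weights.
#' @param phases per-spin phases, rad.
#' @param matrix_size length-2 integer image matrix.
#' @param fov field of view, mm (isotropic).
#' @return complex image matrix (`matrix_size`), pixel (1,1) at
#'   `-fov/2`.
#' @export
encode_kspace_ideal <- function(r, weights, phases, matrix_size, fov) {
  r <- as.matrix(r)
  stopifnot(ncol(r) == 2, length(matrix_size) == 2)
  if (any(abs(r) > fov / 2))
    warning("spins outside the FOV will alias")
  nx <- matrix_size[1]; ny <- matrix_size[2]
  kx <- (seq_len(nx) - 1 - nx %/% 2) / fov
  ky <- (seq_len(ny) - 1 - ny %/% 2) / fov
  cs <- weights * exp(1i * phases)
  E1 <- exp(-2i * pi * outer(kx, r[, 1]))      # nx x nspins
  E2 <- exp(-2i * pi * outer(r[, 2], ky))      # nspins x ny
  S <- E1 %*% (cs * E2)
  xpix <- (seq_len(nx) - 1 - nx %/% 2) * fov / nx
  ypix <- (seq_len(ny) - 1 - ny %/% 2) * fov / ny
  F1 <- exp(2i * pi * outer(xpix, kx))         # nx x nx (pixels x k)
  F2 <- exp(2i * pi * outer(ky, ypix))         # ny x ny (k x pixels)
  (F1 %*% S %*% F2) / (nx * ny)
}
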