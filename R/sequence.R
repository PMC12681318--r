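#' Pulsed-gradient spin-echo sequence description
#'
#' Stejskal-Tanner PGSE timing: two gradient pulses of duration `delta`
#' (s) and amplitude `G` (mT/mm) along unit direction `dir`, separated
#' by the inter-pulse lapse `Delta` (s), around a refocusing pulse.
#' Derived quantities: effective diffusion time `tau = Delta - delta/3`,
#' q-vector `q = gamma * delta * G * dir` (rad/mm), b-value
#' `b = gamma^2 delta^2 G^2 tau` (s/mm^2).  Either `G` or `b` may be
#' given; the other is derived.
#'
#' Units: seconds, millimeters, mT/mm, rad/(s mT);
#' `gamma = 2.6752e5 rad s^-1 mT^-1` by default, under which b-values in
#' s/mm^2 emerge naturally.
#'
#' @param delta gradient pulse duration, s.
#' @param Delta inter-pulse lapse, s (`delta <= Delta`).
#' @param dir gradient direction (normalized internally).
#' @param G gradient amplitude, mT/mm (alternative to `b`).
#' @param b b-value, s/mm^2 (alternative to `G`).
#' @param TE echo time, s.
#' @param TR repetition time, s.
#' @param gamma gyromagnetic ratio, rad/(s mT).
#' @return object of class `pgse_sequence` with the inputs plus `tau`,
#'   `q` (rad/mm) and `b`.
#' @export
pgse_sequence <- function(delta = 0.0166, Delta = 0.0557,
                          dir = c(1, 0, 0), G = NULL, b = NULL,
                          TE = 0.113725, TR = 50.033,
                          gamma = 2.6752e5) {
  stopifnot(delta > 0, Delta >= delta, TE > 0, TR > 0)
  tau <- Delta - delta / 3
  nrm <- sqrt(sum(dir^2))
  dir <- if (nrm > 0) dir / nrm else c(0, 0, 0)
  if (is.null(G)) {
    if (is.null(b)) b <- 0
    G <- sqrt(b / (gamma^2 * delta^2 * tau))
  }
  b <- gamma^2 * delta^2 * G^2 * tau
  if (all(dir == 0) && b > 0) stop("non-zero b requires a direction")
  structure(list(delta = delta, Delta = Delta, dir = dir, G = G,
                 TE = TE, TR = TR, gamma = gamma, tau = tau,
                 q = gamma * delta * G * dir, b = b),
            class = "pgse_sequence")
}

#' @export
print.pgse_sequence <- function(x, ...) {
  cat(sprintf(
    "PGSE: delta/Delta = %.4g/%.4g s, tau = %.4g s, b = %.4g s/mm^2, |q| = %.4g rad/mm\n",
    x$delta, x$Delta, x$tau, x$b, sqrt(sum(x$q^2))))
  invisible(x)
}

#' Spin trajectory for a sampled end-to-end displacement
#'
#' A spin with initial position `r0` and sampled net displacement `R`
#' moves at the constant velocity `R / Delta`, starting at the onset of
#' the first diffusion pulse (`t = 0` on this clock) and continuing
#' until the end of the second pulse (`t = Delta + delta`).  The
#' displacement window is the `Delta` interval: the spin is at
#' `r0 + R` exactly at `t = Delta`, at `r0 + R/2` at its midpoint, and
#' static outside the motion interval.  This convention makes the
#' accrued PGSE phase exactly `-q . R` (see [pgse_phase()]), tying the
#' sampled displacement at `tau = Delta - delta/3` to the measured
#' signal with no finite-pulse correction.
#'
#' @param r0 initial position(s), mm (length-3 or n x 3).
#' @param R net displacement(s), mm (same shape).
#' @param t time since the first pulse onset, s (scalar).
#' @param seq a [pgse_sequence()].
#' @return position(s), mm.
#' @export
linear_path <- function(r0, R, t, seq) {
  stopifnot(inherits(seq, "pgse_sequence"), length(t) == 1)
  frac <- min(max(t, 0), seq$Delta + seq$delta) / seq$Delta
  r0 + frac * R
}

#' PGSE phase accrued by a moving spin
#'
#' The phase is `gamma * [int_1 G(t).r(t) dt - int_2 G(t).r(t) dt]`
#' over the two pulses (sign flip from the refocusing pulse).  For the
#' constant-velocity path of [linear_path()] the piecewise integral
#' evaluates in closed form to `phi = -q . R` with
#' `q = gamma delta G ghat`, independent of the initial position.
#'
#' @param r0 initial position (unused by the closed form; kept for the
#'   trajectory contract).
#' @param R net displacement(s), mm: length-3 vector or n x 3 matrix.
#' @param seq a [pgse_sequence()].
#' @return phase(s), rad.
#' @export
pgse_phase <- function(r0, R, seq) {
  stopifnot(inherits(seq, "pgse_sequence"))
  R <- .as_points(R)
  as.numeric(-(R %*% seq$q))
}

#' Complex voxel signal from a set of spins
#'
#' Ideal spin-echo signal model: each spin contributes its relaxation
#' weight `PD (1 - exp(-TR/T1)) exp(-TE/T2)` times the phase factor
#' `exp(i phi)` from its displacement.  With all displacements zero the
#' result is the voxel baseline.
#'
#' @param spins list with `R` (n x 3 displacements, mm) and scalars or
#'   per-spin vectors `T1`, `T2` (s), `PD` (arbitrary units).
#' @param seq a [pgse_sequence()].
#' @return complex scalar signal.
#' @export
voxel_signal <- function(spins, seq) {
  R <- .as_points(spins$R)
  if (nrow(R) == 0) {
    warning("empty voxel: signal defined as 0")
    return(complex(real = 0, imaginary = 0))
  }
  w <- spins$PD * (1 - exp(-seq$TR / spins$T1)) * exp(-seq$TE / spins$T2)
  phi <- pgse_phase(NULL, R, seq)
  sum(w * exp(1i * phi))
}
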