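#' Normalized mean squared error per pixel and shell
#'
#' `NMSE(x, s) = sum_j (S_sim - S_ref)^2 / sum_j S_ref^2`, the sums
#' running over the gradients of shell `s`.  Either a model-synthesized
#' or an acquired DWI set can serve as the reference.  Pixels with zero
#' reference energy in a shell are reported as `NA`.
#'
#' @param S_sim,S_ref numeric matrices, pixels x gradients (same
#'   shape; magnitudes).
#' @param shells shell grouping as returned by [shell_grouping()]
#'   (named list of gradient index vectors).
#' @return numeric matrix, pixels x shells (columns named by shell).
#' @export
nmse <- function(S_sim, S_ref, shells) {
  S_sim <- as.matrix(S_sim); S_ref <- as.matrix(S_ref)
  if (!all(dim(S_sim) == dim(S_ref))) stop("shape mismatch")
  out <- matrix(NA_real_, nrow(S_sim), length(shells),
                dimnames = list(NULL, names(shells)))
  for (k in seq_along(shells)) {
    j <- shells[[k]]
    num <- rowSums((S_sim[, j, drop = FALSE] -
                      S_ref[, j, drop = FALSE])^2)
    den <- rowSums(S_ref[, j, drop = FALSE]^2)
    out[, k] <- ifelse(den > 0, num / den, NA_real_)
  }
  out
}

#' Global least-squares intensity calibration
#'
#' Scales the simulated DWIs by the single factor `alpha` minimizing
#' `sum (alpha S_sim - S_ref)^2`, i.e.
#' `alpha = sum(S_sim S_ref) / sum(S_sim^2)`, eliminating the influence
#' of arbitrary scale factors before NMSE/correlation comparisons.
#'
#' @param S_sim,S_ref numeric arrays of identical shape.
#' @return `alpha * S_sim`, with the factor attached as attribute
#'   `alpha` (and `degenerate = TRUE` when the least-squares factor is
#'   0, i.e. the inputs are orthogonal).
#' @export
normalize_scale <- function(S_sim, S_ref) {
  ss <- sum(S_sim^2)
  if (ss == 0) stop("all-zero simulation cannot be calibrated")
  alpha <- sum(S_sim * S_ref) / ss
  out <- alpha * S_sim
  attr(out, "alpha") <- alpha
  if (alpha == 0) attr(out, "degenerate") <- TRUE
  out
}

#' Pixelwise Fisher-tested correlation map
#'
#' For each pixel and shell, the Pearson correlation `r` between the
#' simulated and reference DWI values across the shell's gradients is
#' Fisher-transformed (`z = atanh(r)`) and tested one-sidedly at each
#' candidate level `rho0`: under the default `direction = "ge"` a level
#' is accepted when H0: `rho >= rho0` is *not* rejected against
#' `rho < rho0`, i.e. when `(z - atanh(rho0)) sqrt(N - 3) >=
#' qnorm(alpha)`; `direction = "gt"` instead requires rejecting
#' H0: `rho <= rho0` in favor of `rho > rho0`.  The pixel is labeled
#' with the largest accepted level (accepted levels are downward
#' closed by monotonicity of the statistic), or none ("black") if the
#' smallest level fails.  Color bins follow the blue/green/yellow/red/
#' purple temperature code for [0.5,0.6) ... [0.9,1].
#'
#' @param S_sim,S_ref pixels x gradients magnitude matrices.
#' @param shells shell grouping ([shell_grouping()]); each shell needs
#'   at least 4 gradients.
#' @param levels candidate correlation levels.
#' @param alpha significance level of the unilateral test.
#' @param direction `"ge"` (default) or `"gt"`, see above.
#' @return list with one element per shell: data.frame with `r`,
#'   `level` (NA = black), `color`.
#' @export
correlation_map <- function(S_sim, S_ref, shells,
                            levels = seq(0.5, 0.9, by = 0.1),
                            alpha = 0.05, direction = c("ge", "gt")) {
  direction <- match.arg(direction)
  S_sim <- as.matrix(S_sim); S_ref <- as.matrix(S_ref)
  if (!all(dim(S_sim) == dim(S_ref))) stop("shape mismatch")
  levels <- sort(levels)
  cols <- c("blue", "green", "yellow", "red", "purple")
  out <- lapply(seq_along(shells), function(k) {
    j <- shells[[k]]
    if (length(j) < 4) stop("shell ", names(shells)[k],
                            " has fewer than 4 gradients")
    r <- .row_cor(S_sim[, j, drop = FALSE], S_ref[, j, drop = FALSE])
    z <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
    sn <- sqrt(length(j) - 3)
    lev <- rep(NA_real_, length(r))
    for (rho0 in levels) {
      stat <- (z - atanh(rho0)) * sn
      ok <- if (direction == "ge") stat >= stats::qnorm(alpha)
            else stat > stats::qnorm(1 - alpha)
      ok[is.na(r)] <- FALSE
      lev[ok] <- rho0
    }
    color <- rep("black", length(r))
    has <- !is.na(lev)
    color[has] <- cols[findInterval(lev[has], levels)]
    data.frame(r = r, level = lev, color = color)
  })
  names(out) <- names(shells)
  out
}

# Rowwise Pearson correlation; NA for zero-variance rows.
.row_cor <- function(X, Y) {
  n <- ncol(X)
  mx <- rowMeans(X); my <- rowMeans(Y)
  cxy <- rowSums(X * Y) - n * mx * my
  vx <- rowSums(X^2) - n * mx^2
  vy <- rowSums(Y^2) - n * my^2
  ifelse(vx > 0 & vy > 0, cxy / sqrt(vx * vy), NA_real_)
}

#' Log-linear least-squares diffusion tensor fit
#'
#' Fits `ln(S/S0) = -b ghat' D ghat` per pixel by unweighted linear
#' least squares over the selected shells (default: all b-values up to
#' `bmax = 1200 s/mm^2`, the mono-exponential regime), using the mean
#' of the baseline entries as `S0`.  Eigenvalues are clipped at zero
#' and the fractional anisotropy computed from the spectrum.  Pixels
#' with any non-positive signal among the used entries are excluded
#' (all-NA row).
#'
#' @param S pixels x entries magnitude matrix (a full stack including
#'   baselines), or a `dwi_stack` (magnitudes taken).
#' @param table the matching [gradient_table()].
#' @param bmax largest b-value included in the fit.
#' @param shells optional explicit entry indices to fit on (overrides
#'   `bmax`).
#' @return data.frame, one row per pixel: tensor components `dxx, dyy,
#'   dzz, dxy, dxz, dyz`, eigenvalues `l1 >= l2 >= l3`, `fa`, and
#'   principal eigenvector `e1x, e1y, e1z`.
#' @export
fit_dti <- function(S, table, bmax = 1200, shells = NULL) {
  if (inherits(S, "dwi_stack")) S <- abs(S$signal)
  S <- as.matrix(S)
  stopifnot(inherits(table, "gradient_table"),
            ncol(S) == length(table$b))
  b0 <- which(table$b == 0)
  if (!length(b0)) stop("no baseline entry in the table")
  use <- if (!is.null(shells)) shells else which(table$b > 0 & table$b <= bmax)
  if (length(use) < 6) stop("need at least 6 diffusion-weighted entries")
  g <- table$dirs[use, , drop = FALSE]
  B <- table$b[use] * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                            2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                            2 * g[, 2] * g[, 3])
  if (qr(B)$rank < 6) stop("gradient directions are collinear: rank-deficient design")
  S0 <- rowMeans(S[, b0, drop = FALSE])
  ok <- S0 > 0 & apply(S[, use, drop = FALSE] > 0, 1, all)
  out <- data.frame(matrix(NA_real_, nrow(S), 13))
  names(out) <- c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz",
                  "l1", "l2", "l3", "fa", "e1x", "e1y", "e1z")
  if (!any(ok)) return(out)
  Y <- -log(S[ok, use, drop = FALSE] / S0[ok])     # n_ok x n_use
  coefs <- t(qr.solve(B, t(Y)))                    # n_ok x 6
  rows <- which(ok)
  for (i in seq_along(rows)) {
    d <- coefs[i, ]
    D <- matrix(c(d[1], d[4], d[5],
                  d[4], d[2], d[6],
                  d[5], d[6], d[3]), 3, 3)
    e <- eigen(D, symmetric = TRUE)
    l <- pmax(e$values, 0)
    md <- mean(l)
    fa <- if (sum(l^2) > 0)
      sqrt(1.5 * sum((l - md)^2) / sum(l^2)) else 0
    e1 <- .fix_frame(e$vectors)[, 1]
    out[rows[i], ] <- c(d, l, fa, e1)
  }
  out
}

#' FA-weighted RGB orientation map
#'
#' Standard DTI color code: the RGB triple is the fractional anisotropy
#' times the absolute components of the principal eigenvector, with red
#' for right-left (x), green for anterior-posterior (y) and blue for
#' inferior-superior (z).  Antipodal eigenvectors map to the same
#' color; FA = 0 gives black.
#'
#' @param fit a [fit_dti()] result.
#' @return numeric matrix, pixels x 3 (`r`, `g`, `b` in [0, 1]; NA for
#'   excluded pixels).
#' @export
color_orientation_map <- function(fit) {
  rgb <- fit$fa * abs(as.matrix(fit[, c("e1x", "e1y", "e1z")]))
  rgb <- pmin(pmax(rgb, 0), 1)
  colnames(rgb) <- c("r", "g", "b")
  rgb
}

#' Proton-density estimate from the diffusion baseline
#'
#' Ideal spin-echo signal model inversion:
#' `rho = S / ((1 - exp(-TR/T1)) exp(-TE/T2))`.  Pixels whose
#' relaxation denominator vanishes (TR << T1 and/or extreme TE/T2) are
#' flagged unstable via the `unstable` attribute.
#'
#' @param S baseline magnitude(s).
#' @param T1,T2 relaxation times, s.
#' @param TE,TR sequence echo/repetition times, s.
#' @param tol denominator threshold below which a pixel is flagged.
#' @return proton density estimate(s), arbitrary units.
#' @export
estimate_pd <- function(S, T1, T2, TE, TR, tol = 1e-6) {
  stopifnot(all(T1 > 0), all(T2 > 0))
  denom <- (1 - exp(-TR / T1)) * exp(-TE / T2)
  out <- S / denom
  attr(out, "unstable") <- denom < tol
  out
}
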