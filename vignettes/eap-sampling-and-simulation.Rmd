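---
title: "Sampling ensemble average propagators and simulating PGSE diffusion MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling ensemble average propagators and simulating PGSE diffusion MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eapsim)
```

## The model

The quantity being sampled is the Ensemble Average Propagator (EAP): the
probability density $P(\mathbf{R};\tau)$ of a water molecule's net
displacement $\mathbf{R}\in\mathbb{R}^3$ over the effective diffusion
time $\tau=\Delta-\delta/3$ of a pulsed-gradient spin-echo (PGSE)
sequence.  Any valid EAP is non-negative, unit mass and antipodally
symmetric.  Three representations are supported.

**Gaussian (diffusion tensor).**
$P(\mathbf{R}) = (4\pi\tau)^{-3/2}|\mathbf{D}|^{-1/2}
\exp(-\mathbf{R}^{\mathsf T}\mathbf{D}^{-1}\mathbf{R}/4\tau)$, sampled
directly as $\mathbf{R}=\sqrt{2\tau}\,\mathbf{D}^{1/2}\mathbf{S}$ with
$\mathbf{S}\sim N(0,\mathbf{I}_3)$.  The $\sqrt{2\tau}$ factor is what
makes $\operatorname{Var}(\mathbf{R})=2\tau\mathbf{D}$ consistent with
the density above; the package treats that consistency as definitional
and verifies it through the characteristic-function tests.

**MAP-MRI.**  A truncated expansion in products of normalized 1-D
Hermite functions
$\mathcal{H}_n(t;s)=[2^{n+1}\pi\,n!]^{-1/2}s^{-1}
e^{-t^2/2s^2}H_n(t/s)$ (physicists' $H_n$), evaluated in a
tensor-adapted frame: coordinates rotated by the eigenvector matrix
$\mathbf{U}$ and scaled per axis by $s_i=\sqrt{2\tau\lambda_i}$.  Only
even total orders $n_1+n_2+n_3 \le N_{\max}$ appear (50 coefficients at
$N_{\max}=6$), so the density is antipodally symmetric by construction.
The normalization of $\mathcal{H}_n$ is fixed so that
$\mathcal{H}_0(\cdot\,;s)$ **is** the $N(0,s^2)$ density: among the
conventions in circulation this is the only one under which a single
unit zeroth coefficient reproduces the Gaussian EAP exactly, and that
identity is enforced by test (max relative deviation $<10^{-9}$ on a
$21^3$ grid).

**Spherical convolution (SC).**  The mixture
$P(\mathbf{R})=\iint_{\mathcal S}\Phi(\mathbf{v})\,
\kappa(\mathbf{R};\mathbf{v},\lambda_\parallel,\lambda_\perp,\tau)\,
d\mathbf{v}$, where $\kappa$ is the Gaussian EAP of the axisymmetric
tensor with principal axis $\mathbf{v}$ and eigenvalues
$(\lambda_\parallel,\lambda_\perp,\lambda_\perp)$, and the fODF $\Phi$
is expanded in even-degree real symmetric spherical harmonics
$\tilde Y_l^m$ with normalization
$\sqrt{\tfrac{2l+1}{2\pi}\tfrac{(l-|m|)!}{(l+|m|)!}}\,
P_l^{|m|}(\cos\theta)\,\mathcal{T}(m\varphi)$,
$\mathcal{T}$ being the sine ($m>0$), cosine ($m<0$) or $2^{-1/2}$
($m=0$).  Associated Legendre functions are evaluated *without* the
Condon–Shortley phase; whether a published convention includes the
phase varies, so the package pins the basis down operationally instead:
the quadrature Gram matrix up to $L=6$ must be the identity to
$10^{-8}$, which any correctly normalized real basis satisfies and any
mis-normalized one does not.

## Rejection sampling and wrapper design

Both non-Gaussian representations are sampled by plain rejection: a
wrapper density $f_U$ with a constant $c$ such that
$f_X \le c\,f_U$ everywhere, proposals from $f_U$, and acceptance when a
uniform height $v \sim U(0, c f_U(u))$ falls at or below $f_X(u)$.

*MAP-MRI.*  Sampling happens in normalized coordinates $t_i=x_i'/s_i$,
in which the Jacobian cancels the scale factors and the target is the
unit-scale Hermite expansion — this makes the search grid and the
$\nu$-candidates scale-free.  Because each basis function is a Gaussian
times a polynomial, a slightly wider Gaussian dominates it everywhere:
the wrapper is the product of three $N(0,\nu^2)$ densities with
$\nu>1$.  For each $\nu\in\{1.1,\dots,1.5\}$ the bound
$c(\nu)$ is the maximum of target/wrapper over the lattice $[-5,5)^3$
with step 0.1, and the $\nu$ minimizing $c$ is kept.  For a pure
Gaussian target the ratio is
$\nu^3\exp(-(1-\nu^{-2})\|t\|^2/2)$, maximal at the origin, so the
search provably returns $\nu=1.1$, $c=1.331$ — a property used as a
regression test.  A finite lattice can under-bound the true supremum,
so the constant in use is inflated by a 5% safety factor; the
acceptance-rate law ($\text{rate}\to 1/c$ for unit-mass targets) is
asserted against the inflated constant.

*SC.*  The fODF lives on the compact sphere, so the wrapper is the
uniform density per unit solid angle, $1/4\pi$, with proposals drawn as
$\cos\theta\sim U(-1,1)$, $\varphi\sim U(0,2\pi)$ and the accept ratio
formed per unit solid angle.  $c$ is the lattice maximum of
$4\pi\Phi$ on a 1° grid, inflated by the same safety factor.  Accepted
orientations build the kernel frame
$\mathbf{u}_1=[\sin\theta\cos\varphi,\sin\theta\sin\varphi,\cos\theta]$,
$\mathbf{u}_2=[-\sin\varphi,\cos\varphi,0]$,
$\mathbf{u}_3=\mathbf{u}_1\times\mathbf{u}_2$, and the conditional draw
is the Gaussian kernel sample in that frame.  At the poles the azimuth
is undefined; the frame convention $\mathbf{u}_2=[0,1,0]$ is applied
(numerically: $\sin\theta<10^{-12}$).

*Cropping.*  Truncated expansions can dip below zero.  Candidate
heights are never negative, so proposals landing where $f_X<0$ are
rejected automatically — the sampled law is the cropped, renormalized
density.  Every oracle in the package (marginal densities, the
characteristic-function quadrature for SC) crops the same way, so
samplers and oracles describe the same law.  Fixture EAPs used for
distributional tests are chosen non-negative on the whole search
lattice, keeping the cropped and raw laws indistinguishable at test
resolution.

## The spin-level PGSE simulator

Each grid position holds 2000 spins by default (the trade-off between
Monte-Carlo noise and cost adopted for all experiments here), sharing
one EAP and one tissue tuple $(T_1, T_2, PD)$ but drawing independent
displacements.  A spin moves at the constant velocity
$\mathbf{R}/\Delta$ from the onset of the first diffusion pulse through
the end of the second; the displacement window is the $\Delta$
interval, so the spin sits at $\mathbf{r}_0+\mathbf{R}$ exactly at
$t=\Delta$.  Under this convention the piecewise phase integral
$\gamma[\int_1 \mathbf{G}\cdot\mathbf{r}\,dt-\int_2
\mathbf{G}\cdot\mathbf{r}\,dt]$ collapses exactly to
$\varphi=-\mathbf{q}\cdot\mathbf{R}$ with
$\mathbf{q}=\gamma\delta G\hat{\mathbf{g}}$, independent of position:
the simulated attenuation equals the EAP characteristic function at
$\mathbf{q}$ with **no** finite-pulse correction.  That identity is the
central correctness property of the package, and the one alternative
conventions (e.g. freezing the spin during the second pulse) break.
The closed form is cross-checked in the tests against a numeric
time-quadrature of the gradient waveform.

Relaxation enters as a per-spin scalar weight
$PD\,(1-e^{-TR/T_1})\,e^{-TE/T_2}$ applied at the echo — the ideal
spin-echo model, matching the proton-density inversion
`estimate_pd()`; no relaxation is modeled during readout.
Displacements are redrawn independently for every gradient (each DWI is
an independent diffusion experiment); `redraw_per_gradient = FALSE`
freezes one draw per voxel for variance studies.  Gradient amplitudes
are solved from the table b-values at fixed $(\delta,\Delta)$ with no
hardware ceiling.  The imaging layer is a deliberately ideal Cartesian
k-space encoder (`encode_kspace_ideal()`); EPI trajectories, multicoil
reception and off-resonance are out of scope.

Units throughout: seconds, millimeters, mm²/s, mT/mm, and
$\gamma = 2.6752\times10^5$ rad s⁻¹ mT⁻¹, under which b-values come out
in s/mm².  Sequence defaults follow a cardiac ex-vivo protocol:
$\Delta/\delta = 55.7/16.6$ ms, TE $= 113.725$ ms, TR $= 50.033$ s, six
shells at 300–3600 s/mm².

## Validation metrics

* **NMSE** per pixel and shell:
  $\sum_j (S_{\text{sim}}-S_{\text{ref}})^2 / \sum_j S_{\text{ref}}^2$,
  after a single *global* least-squares scale factor
  $\alpha=\sum S_{\text{sim}}S_{\text{ref}}/\sum S_{\text{sim}}^2$ —
  one factor per stack, not per pixel, since its purpose is intensity
  calibration, not per-pixel fitting.
* **Correlation maps**: per pixel and shell, the Pearson $r$ across the
  shell's gradients is Fisher-transformed and tested one-sidedly at
  levels $\rho_0\in\{0.5,\dots,0.9\}$.  A level is *accepted* when
  $H_0{:}\ \rho\ge\rho_0$ is not rejected against $\rho<\rho_0$
  (statistic $(\operatorname{atanh} r - \operatorname{atanh}\rho_0)
  \sqrt{N-3}$ versus $z_\alpha$); the stricter reading — rejecting
  $H_0{:}\ \rho\le\rho_0$ in favor of $\rho>\rho_0$ — is available via
  `direction = "gt"`.  The default $\alpha=0.05$ is a convention, made
  configurable because nothing in the protocol pins it down.  Accepted
  levels are downward closed by monotonicity of the statistic, so "the
  largest accepted level" is well defined; pixels failing at 0.5 are
  black, and the blue/green/yellow/red/purple temperature code covers
  $[0.5,0.6)\ldots[0.9,1]$.
* **DTI fits**: unweighted log-linear least squares of
  $\ln(S/S_0) = -b\,\hat{\mathbf g}^{\mathsf T}\mathbf D\hat{\mathbf g}$
  on all shells up to 1200 s/mm² by default (configurable, since
  per-shell fits are equally legitimate); exact on noise-free
  mono-exponential data, eigenvalues clipped at zero, FA-weighted
  $|\mathbf e_1|$ RGB maps with red = x, green = y, blue = z.

The type-I error of the Fisher test is itself validated by Monte Carlo
at true $\rho=\rho_0$.  The toy stacks for that check use 128 gradients
per shell: the $z$-transform carries an $O(\rho_0/N)$ bias, so at the
protocol minimum ($N_{gs}=4$) *no* implementation holds the nominal
level — 128 gradients make the property testable without changing the
implementation under test.

## Synthetic phantoms and what they do (not) show

`make_fiber_field()` provides three presets: a uniform tensor field, a
circular-myocardium annulus whose principal eigenvector is tangent to
concentric rings (the smoothly rotating fiber field of a short-axis
cardiac slice; on a 64×64 grid with radius fractions 0.55–0.90 of the
half-extent it holds ~1640 voxels, the scale of one acquired slice),
and a crossing-fiber field with two-peak SC fODFs in the central band.
fODF fixtures are antipodally symmetrized von Mises–Fisher peaks
(default concentration 15) projected to $L=6$ — smooth, band-limited
stand-ins for deconvolved fODFs.  Default kernel eigenvalues
$\lambda_\parallel = 2\times10^{-3}$,
$\lambda_\perp = 0.5\times10^{-3}$ mm²/s are physiologically plausible
white-matter/myocardium values.  The non-Gaussian MAP-MRI fixture
perturbs $a_{000}=1$ with small $a_{200}, a_{020}, a_{002}, a_{400}$
terms, renormalized to unit mass and verified non-negative on the
search lattice, and deviates from the mono-exponential extrapolation by
far more than 5% at b = 3600 s/mm² — a genuinely non-Gaussian test
case.

What passing tests show: the samplers draw from exactly the densities
the coefficient sets define, and the simulator maps those densities to
signals through the correct Fourier relation.  What they do not show:
fidelity to any *acquired* data.  Real coefficient sets come from
fitting noisy acquisitions (MAPL with positivity constraints,
spherical deconvolution), carry estimation error and negative lobes
larger than these fixtures, and real signals include readout, noise and
hardware effects the simulator deliberately omits.  Reproducing an
acquired dataset's error tables therefore requires that acquisition;
the package reproduces the *procedures* and validates them on synthetic
ground truth.

## Numerical choices

* Spherical quadrature: product Gauss–Legendre in $\cos\theta$ ×
  periodic trapezoid in $\varphi$, exact for band-limited integrands;
  projections refuse rules below order $L+1$ / $2L+1$.  Density and
  characteristic-function quadratures for SC use 24×48 and 48×96 nodes
  respectively — the mixture integrand is smooth but not band-limited,
  and these orders leave quadrature error far below Monte-Carlo
  resolution at $n=10^5$.
* MAP-MRI Fourier oracle: the 3-D integral separates into per-axis 1-D
  integrals of $\mathcal{H}_n$ against $e^{-iqt}$, evaluated by dense
  trapezoid on $\pm 8s$ (4001 points); the Gaussian decay makes the
  truncation error negligible ($<10^{-6}$ against the closed form).
* Hermite normalization constants are computed in the log domain, so
  high orders neither overflow nor lose precision.
* Eigen-decompositions fix signs deterministically (largest-magnitude
  component positive, $\det\mathbf U=+1$), making frames reproducible
  across runs and platforms even for degenerate spectra.
* Rejection sampling proposes in chunks sized by the expected
  acceptance, and raises a diagnostic error naming $c$ if the observed
  rate falls below $10^{-3}$ after a 10⁴-proposal probe — a loose bound
  fails loudly instead of looping.
* Seeds: every sampling entry point takes a `seed`; a stack simulation
  seeds once and proceeds in a fixed voxel/gradient order, so identical
  seeds give bit-identical stacks.

## Problem sizes

Distributional acceptance checks use $10^5$ samples per EAP (KS at
$\alpha=0.01$ against numerically marginalized targets), moment checks
$10^5$, characteristic-function checks $5\times10^4$ spins at 10
q-values, Stejskal–Tanner recovery $2\times10^4$ spins across the six
shells, and the end-to-end run three ~1640-voxel circular slices at
2000 spins/voxel over 6 shells × 8 directions.  These sizes keep the
full suite within a few minutes on one CPU while leaving Monte-Carlo
error well inside every asserted tolerance.

## Known limitations

* The simulation is valid only at the diffusion time that produced the
  EAP coefficients; τ cannot be retargeted without refitting — the
  price of avoiding an explicit microstructure model.
* Fitting MAP-MRI or SC coefficients from measured DWIs is out of
  scope; coefficients are inputs.
* No noise model beyond Monte-Carlo sampling noise; no Bloch-equation
  time stepping, slice profiles, multicoil reception or k-space
  trajectory imperfections.
* Rejection efficiency degrades for extremely peaked fODFs (c grows
  with $4\pi\max\Phi$); adaptive or squeeze schemes are deliberately
  not implemented.
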