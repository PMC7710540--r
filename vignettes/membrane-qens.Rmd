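---
title: "Separating lateral and internal lipid motion in QENS spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating lateral and internal lipid motion in QENS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(qensmem)
library(dplyr)
```

## The measurement and the model

Quasielastic neutron scattering (QENS) on a backscattering spectrometer
measures the dynamic structure factor $S(Q, E)$ of a sample — here a
suspension of lipid-membrane vesicles in D$_2$O — over wave-vector
transfers $Q \approx 0.5\text{–}1.8\,\mathrm{\AA^{-1}}$ and energy
transfers of order $1\,$meV, with an energy resolution of
$17\,\mu$eV FWHM.  On the few-to-hundred picosecond timescale this window
selects, hydrogen-dominated incoherent scattering from the lipids reports
two distinct stochastic motions:

1. **Lateral diffusion** of whole lipids within a leaflet.  Continuous
   (Fickian) diffusion turns the elastic line into a Lorentzian
   $L(\Gamma_\mathrm{lat}, E)$ whose half-width grows as
   $\Gamma_\mathrm{lat} = \hbar D_\mathrm{lat} Q^2$, through the origin.
2. **Internal motion** of the hydrogen atoms — conformational moves,
   reorientations, large-amplitude oscillations — which is spatially
   confined by the molecular architecture.  Confinement leaves a finite
   elastic fraction $A(Q)$ (the elastic incoherent structure factor, EISF)
   next to a quasielastic part:
   $S_\mathrm{int}(Q,E) = A(Q)\,\delta(E) + (1 - A(Q))\,L(\Gamma_\mathrm{int}, E).$

Assuming the two motions are independent, the membrane scattering law is
their convolution.  Because a Lorentzian convolved with a Lorentzian is a
Lorentzian with the summed width, the composite law collapses to the
two-component form used by the per-Q fitting stage:

$$S_\mathrm{mem}(Q,E) = A(Q)\,L(\Gamma_\mathrm{lat}, E) +
  (1 - A(Q))\,L(\Gamma_\mathrm{lat} + \Gamma_\mathrm{int}, E),$$

which is convolved with the instrument resolution and compared with the
data by error-weighted least squares, independently at each $Q$, over
$\{A, \Gamma_\mathrm{lat}, \Gamma_\mathrm{int}, \mathrm{scale},
\mathrm{background}\}$.

Everything internal runs in meV / Å / ps.  In this system
$\hbar = 0.6582$ meV ps and $k_B = 0.08617$ meV/K are order-one numbers,
and $\hbar D Q^2$ is directly an energy: with
$D = 0.0116\,\mathrm{\AA^2/ps}$ ($= 11.6\times10^{-7}\,\mathrm{cm^2/s}$)
and $Q = 1.8\,\mathrm{\AA^{-1}}$ the lateral width is $0.025$ meV, inside
the instrument window.  Diffusivities cross to cm$^2$/s only at the
reporting boundary ($1\,\mathrm{\AA^2/ps} = 10^{-4}\,\mathrm{cm^2/s}$).

## Diffusion in a sphere: the internal-motion model

The internal motion is modelled as localized translational diffusion
(LTD): a particle diffusing with coefficient $D_\mathrm{int}$ inside a
sphere of radius $R$ with reflecting walls, with a fraction $p_x$ of
hydrogens immobile on the observation timescale.  The EISF is

$$A(Q) = p_x + (1 - p_x)\left[\frac{3 j_1(QR)}{QR}\right]^2,$$

and the quasielastic part is an infinite sum of Lorentzians whose widths
$\hbar x_{nl}^2 D_\mathrm{int} / R^2$ are fixed by the eigenvalues
$x_{nl}$ — the positive roots of $j_l'(x) = 0$ — while their weights
$(2l{+}1) A_{nl}(QR)$ depend on $Q$ only through $QR$.

The package computes this model from first principles:

* `vd_eigenvalues()` brackets and refines the roots of $j_l'$ to
  $|j_l'(x)| \le 10^{-10}$.  The default pool ($l \le 25$, $n \le 12$)
  comfortably contains the first 100 modes by ascending eigenvalue, the
  truncation used everywhere by default; the pool matters because the
  ordering interleaves $l$ and $n$.
* `vd_structure_factors()` obtains the weights by projecting the plane
  wave onto the normalized radial eigenfunctions with 400-node
  Gauss–Legendre quadrature, rather than transcribing closed-form
  coefficient tables.  Correctness is enforced by two independent checks:
  the completeness sum rule $A_0^0 + \sum (2l{+}1) A_{nl} = 1$ (satisfied
  to $10^{-3}$ for $QR \le 5.4$ at the 100-term truncation, and to a few
  $10^{-4}$ of that by the truncation alone) and agreement of the
  reconstructed intermediate scattering function with a Monte-Carlo
  random walk in a reflecting sphere.
* `vd_hwhm()` extracts the half-width of the quasielastic sum
  numerically (no closed form exists): a bisection on a function whose
  bracketing interval is grown geometrically from
  $20\,\hbar D/R^2 \max(1, (QR)^2)$, refined to $10^{-10}$ meV.  The
  immobile fraction scales out.  The curve has the two limits that make
  the model recognizable in data: a plateau
  $\hbar x_{11}^2 D/R^2$ ($x_{11} = 2.0816$) for $QR \ll \pi$, and
  $DQ^2$ behaviour at large $QR$.

```{r vd-curve}
q <- seq(0.1, 2.0, by = 0.05)
plot(q, vd_hwhm(q, d_int = 0.123, radius = 2.8), type = "l",
     xlab = "Q (1/A)", ylab = "Gamma_int (meV)")
abline(h = qens_constants$hbar * 2.08158^2 * 0.123 / 2.8^2, lty = 2)
```

One caution established by the package's own oracle: the approach to the
free-diffusion law is *slow*.  Both the spectral expansion and the
Monte-Carlo walk give $\Gamma/( \hbar D Q^2) \approx 0.785$ at $QR = 12$,
and the ratio only passes $0.9$ near $QR \approx 40$.  Claims that the
$DQ^2$ regime is reached just beyond $QR \sim \pi$ are qualitative;
quantitative work at intermediate $QR$ must use the numerical curve.

## The two-stage analysis

`run_pipeline()` chains the stages exactly as an instrument scientist
would:

1. optional weighted solvent (D$_2$O) subtraction, with errors combined
   in quadrature and negative residuals retained so later fits stay
   unbiased;
2. independent per-Q fits of the resolution-convolved composite model
   (bounded Levenberg–Marquardt; `minpack.lm`);
3. stage-2 extraction: $D_\mathrm{lat}$ from the weighted through-origin
   regression of $\Gamma_\mathrm{lat}$ on $\hbar Q^2$ (closed-form normal
   equations); $(p_x, R)$ from a multi-start weighted fit of the sphere
   EISF; $D_\mathrm{int}$ from the numerical LTD half-width curve with
   $(p_x, R)$ held at their EISF values.  Because the LTD half-width is
   exactly linear in $D$ at fixed $R$, this last fit also has a closed
   form: a weighted through-origin regression of $\Gamma_\mathrm{int}$ on
   $h(Q) = $ `vd_hwhm(Q, 1, R)`.

Stage-2 weights are the stage-1 covariance errors; stage-2 uncertainties
come from the weighted-fit covariance, inflated by
$\sqrt{\chi^2_\mathrm{red}}$ when $\chi^2_\mathrm{red} > 1$.

Choices that were genuinely open, and how they were settled:

* **Label degeneracy.**  A two-Lorentzian mixture is exchange-degenerate.
  The broad component is *structurally* assigned the width
  $\Gamma_\mathrm{lat} + \Gamma_\mathrm{int}$ with
  $\Gamma_\mathrm{int} > 0$, which makes the swapped labelling
  unrepresentable; initialization of $\Gamma_\mathrm{lat}$ from Fick's
  law with a configurable prior diffusivity (`d0_init`, default
  $0.01\,\mathrm{\AA^2/ps}$) and deterministic multi-starts do the rest.
  A converged fit is accepted early only if its reduced chi-square is
  good in the absolute sense (< 1.5); otherwise the remaining starts are
  tried and the lowest deviance wins.
* **Resolution.**  Default is a Gaussian of FWHM 0.017 meV; a measured
  vanadium line shape per Q can replace it.  The true backscattering
  line shape is asymmetric; a Gaussian is an emulation choice, and any
  systematic it introduces cancels in round-trip tests because generator
  and fit share the convolution.
* **Convolution.**  Direct discrete convolution on a 4× oversampled grid
  extended by the kernel support, then decimation — no periodic
  wrap-around on the asymmetric window.  Against an adaptive-quadrature
  Voigt oracle the error is below $10^{-8}$ relative, far inside the
  $10^{-4}$ the fits need.  The elastic line is carried as a scalar
  weight and materialized only as the resolution shape itself.
* **Background.**  A flat term is fitted per Q (default truth 0 in the
  generator).  Energy-dependent backgrounds and detailed-balance
  asymmetry are out of scope.
* **Q-averaging and susceptibility.**  `q_average()` is unweighted;
  `susceptibility_transform()` uses the high-temperature Bose
  approximation $n_B \approx k_B T / E$ (at 310 K and 1 meV,
  $E/k_BT \approx 0.04$, so the approximation is excellent; the full
  factor is available behind `full_bose = TRUE`).

## What the synthetic generator emulates — and what it does not

`generate_dataset()` stands in for the beamline deposition.  It emulates:
the instrument window ($-0.3$ to $+1.0$ meV, 261 points), ten Q groups
across $0.5$–$1.8\,\mathrm{\AA^{-1}}$ (the real grouping is not public;
the count is configurable), Gaussian resolution, a flat background, a
broad-Lorentzian D$_2$O surrogate (HWHM 0.1 meV) scaled by a solvent
weight of 0.95 (a 5% w/w suspension surrogate), and counting noise as
Gaussian with $\sigma = \mathrm{noise} \cdot \sqrt{I \cdot I_\mathrm{peak}}$
— the high-count Poisson limit, normalized so the peak error is 1% of the
peak at the default noise level, chosen so recovery uncertainties are
comparable to the parenthetical errors a real experiment reports.

Two generator modes matter:

* `"effective"` generates from the same two-Lorentzian law the fitting
  stage assumes, with $\Gamma_\mathrm{int}(Q)$ from the numerical LTD
  curve.  Round trips are then exact inverses: noiseless recovery is at
  the $10^{-6}$ level, and every preset's published parameter set is
  recovered within 1%.
* `"full"` generates from the complete multi-Lorentzian LTD law.
  Fitting it with the effective model measures the approximation
  everyone in the field makes: the package finds that the single
  effective Lorentzian, forced to cover the broad high-order modes,
  *overestimates* $\Gamma_\mathrm{int}$ by tens of percent and
  $D_\mathrm{int}$ by roughly 55–70% under these instrument conditions,
  while $D_\mathrm{lat}$ is essentially untouched and $p_x$ shifts by
  less than 0.1.  Passing effective-mode tests therefore validates the
  *machinery*, not the physical adequacy of the one-Lorentzian internal
  model; results on real data carry this model systematic.

What the generator does not emulate: event-level statistics, detector
efficiency and solid-angle weighting, multiple scattering,
detailed-balance asymmetry, and the true asymmetric resolution shape.

## Numerical sizes and determinism

The default problem sizes — 10 Q groups × 261 energy points, 100
eigenmodes, 400 quadrature nodes, 20-seed noise ensembles in the
validation suite — were chosen as the smallest sizes at which every
numerical layer is converged well past the precision the science needs
(sum rule $10^{-3}$, convolution $10^{-8}$, recovery $10^{-6}$ noiseless).
All randomness flows through explicit integer seeds; the generator
restores the caller's RNG state, and identical inputs produce identical
results bit for bit.

## Known limitations

* The effective-Lorentzian internal model carries the systematic
  quantified above; the package reports it rather than hides it.
* Per-Q fits are independent; no global-across-Q fitting.
* No Bayesian posteriors; uncertainties are covariance-based with the
  standard $\sqrt{\chi^2_\mathrm{red}}$ inflation.
* The Gaussian resolution default understates the wings of a real
  backscattering line shape; supply a measured vanadium spectrum for
  real data.
* Raw event reduction, absolute calibration, and multiple-scattering
  corrections are out of scope: input is already-grouped $S(Q, E)$.
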