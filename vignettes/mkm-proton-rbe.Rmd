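---
title: "Methods: MKM RBE-weighted dose estimation for proton beams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MKM RBE-weighted dose estimation for proton beams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mkmrbe)
```

## The model

The microdosimetric kinetic model (MKM) treats the cell nucleus as a
collection of sub-micrometre *domains* (radius $r_d$) in which radiation
deposits energy stochastically. Its radiation-quality variable is the
saturation-corrected dose-mean specific energy per event,

$$
z^*_{1D} \;=\; \frac{\bar l}{m}\,y^* \;=\;
\frac{0.1602}{\rho\,\pi r_d^2}\; y_0^2 \int_0^\infty
\frac{1 - e^{-y^2/y_0^2}}{y}\, d(y)\, \mathrm{d}y \quad [\mathrm{Gy}],
$$

where $d(y)$ is the dose probability density of lineal energy $y$
(keV/μm), $\bar l = \tfrac{2}{3}\cdot 2 r_d$-type chord-length and domain
mass combine into $1/(\rho \pi r_d^2)$ for a sphere, and
$0.1602$ converts keV/μm per μm²·(g/cm³) to Gy
($1\,\mathrm{keV} = 1.602\times10^{-16}$ J, $1$ μm³ of unit-density tissue
$= 10^{-15}$ kg). The saturation parameter $y_0$ caps the effectiveness of
very densely ionizing events (overkill): since $1-e^{-x} \le x$, always
$0 < y^* \le \bar y_D$, with equality approached when the whole spectrum
lies far below $y_0$. A typeset form of the saturation integral without the
$1/y$ factor circulates in the literature; only the form above reduces to
$\bar y_D$ in the low-$y$ limit, so it is the one implemented (the
alternative reading is dimensionally inconsistent with that limit and is
rejected, not silently ignored).

Cell survival follows the linear-quadratic (LQ) model
$S(D) = \exp(-\alpha D - \beta D^2)$ with

$$\alpha = \alpha_0 + \beta\, z^*_{1D},$$

$\beta$ taken as independent of radiation quality. The RBE at surviving
fraction $S$ (default $S = 0.1$, with no dose or dose-rate dependence
modelled) is the dose ratio $D_\mathrm{ref}(S)/D_\mathrm{beam}(S)$ against
200 kVp X-rays ($\alpha_X = 0.19$ Gy⁻¹, $\beta_X = 0.05$ Gy⁻²). The
RBE-weighted dose is RBE × physical dose, per depth.

## Parameters

Two immutable HSG-cell parameter sets ship with the package:

| set | $\alpha_0$ (Gy⁻¹) | $\beta$ (Gy⁻²) | $r_d$ (μm) | $y_0$ (keV/μm) | used for |
|-----|------|--------|-------|-------|----------|
| `SET_A` | 0.155 | 0.0615 | 0.282 | 93.4 | survival-depth analysis |
| `SET_B` | 0.13  | 0.05   | 0.42  | 150  | RBE-weighted dose (default) |

Both were fitted to heavy-ion survival data and are applied to protons
unchanged — no proton-specific recalibration is attempted. The two sets
answer different questions and give visibly different $z^*_{1D}$ for the
same spectrum (the smaller `SET_A` domain roughly doubles it); which set
pairs with which sensitive-site diameter for spectrum scoring is not
uniquely determined, so the site diameter (default 0.564 μm, twice the
`SET_A` domain radius) is carried as spectrum metadata and never silently
coupled to a parameter set.

Spectra are averaged over a ±1.5 mm depth window before reduction
(`window_mm`), emulating the axial extent of a tissue-equivalent
proportional counter. When per-depth physical dose is available the window
average is dose-weighted, otherwise uniform — the weighting convention is a
package choice, as the averaging is conventionally described without one.

## Numerical choices

* **Quadrature.** All spectral functionals use the trapezoid rule on the
  native $y$ grid. Spectra are smooth and the grid is user-controlled;
  a deterministic rule is exactly reproducible and easy to cross-check by
  Monte Carlo (the test-suite does so with $10^6$ samples, agreeing within
  0.5%). Halving the grid spacing moves $y^*$ by well under 0.1% for
  smooth spectra.
* **LQ inversion.** $D(S)$ is evaluated as
  $-2\ln S / (\alpha + \sqrt{\alpha^2 - 4\beta \ln S})$, which avoids the
  catastrophic cancellation of the textbook root form at small $\beta$ and
  passes continuously to the linear limit $-\ln S/\alpha$ (branch below
  $\beta = 10^{-12}$). Forward and inverse compose to the identity within
  $10^{-10}$ over $\alpha \in [0.05, 0.5]$, $\beta \in [0, 0.1]$,
  $S \in [10^{-3}, 0.9]$.
* **Grid union.** Window averaging interpolates member spectra linearly in
  $(y, d(y))$ onto the union of their grids, treating values outside a
  member's support as zero — the simplest mass-safe choice.
* **Degenerate inputs.** Grids with $y \le 0$ are rejected outright (the
  $1/y$ integrands make clipping unsafe); all-zero or negative densities
  are errors, not warnings. Unnormalized spectra entering a moment are
  renormalized with a warning.
* **Anchors.** "Bragg peak" is the argmax of physical dose; "SOBP center"
  is the midpoint of the region where dose is within 95% of its maximum.
  The center of a spread-out peak has no universal operational definition;
  the 95% convention is recorded in the output metadata so downstream
  consumers can see it.

## The synthetic beam generator

The generator replaces Monte Carlo particle transport with the minimal
analytic structure that preserves what the MKM chain actually consumes:

* **Range–energy.** Bragg–Kleeman power law $R = \alpha_{BK} E^{p}$ with
  the textbook water constants $\alpha_{BK} = 0.0022$ cm·MeV⁻ᵖ,
  $p = 1.77$. The default entrance energy, 136.7 MeV, puts the pristine
  Bragg peak near 132 mm — the deepest spectral scoring depth of the
  reference clinical setup this emulates, where a nominal 155 MeV beam
  reaches the phantom after beamline losses.
* **Depth dose.** Stopping power $S(E) \propto E^{1-p}$ convolved with a
  Gaussian range-straggling kernel, $\sigma_R/R = 0.012$, and attenuated
  1%/cm for nuclear fluence loss. $S \propto r^{1/p-1}$ is integrably
  singular at the end of range; substituting $t = r^{1/p}$ turns the
  convolution into a smooth integral
  $\mathrm{dose}(z) \propto \int \varphi((z + t^p - R)/\sigma_R)\,
  \mathrm{d}t$ that plain quadrature handles to near machine accuracy.
  Without the substitution, per-depth quadrature noise of a few percent
  masquerades as dose ripple and defeats SOBP flattening.
* **SOBP.** A 60 mm modulation superposes 31 range-shifted pristine peaks
  with non-negative least-squares weights targeting a flat dose from the
  proximal modulation edge to 3 mm short of the deepest range. Two
  resolutions matter here. First, peak spacing must stay near the
  straggling width: widely spaced peaks (9 over 60 mm ≈ 7.5 mm spacing vs
  $\sigma_R \approx 1.3$–$1.6$ mm) leave an irreducible superposition
  ripple of order 15% that **no** weighting can remove — `sobp_weights()`
  reports the achieved deviation in a structured error rather than
  pretending. 31 components (~2 mm spacing) emulate the quasi-continuous
  modulation of a clinical bar ridge filter and bring the ripple to
  ~0.1%. Second, the flat-dose fit must be constrained from the proximal
  edge itself: leaving a proximal margin lets the solver place arbitrarily
  large weight on the shallowest components just outside the fitted
  region. A tiny Tikhonov ridge ($10^{-6}$ relative) selects the
  minimum-norm weights when components are nearly collinear.
* **Spectra.** At each depth, each contributing component is resolved over
  its straggled range distribution into sub-components; each contributes a
  log-normal $d(y)$ whose *median equals the local stopping power* in
  keV/μm and whose log-width is 0.35, plus a 5% dose fraction in a second
  log-normal a decade higher standing in for secondary particles. The
  width and tail defaults place the entrance $\bar y_D$ near 1 keV/μm,
  the sparsely-ionizing regime in which proton RBE against 200 kVp X-rays
  falls below one; because residual energy falls with depth, $\bar y_D$
  hardens monotonically toward the peak. These are free parameters of the
  emulation, not fits to track-structure physics.
* **Determinism.** The generator is a pure function of its configuration.
  Optional multiplicative counting noise on $d(y)$ (`noise_cv`) is the
  only stochastic element and is fully controlled by `rng_seed`.

What the generator does **not** emulate: nuclear fragmentation spectra,
beamline hardware (scatterers, ridge-filter geometry, collimators),
lateral profiles, measured-detector response, or transport-code accuracy.
Consequently, passing the end-to-end checks demonstrates that the MKM
chain transforms spectra correctly and reproduces the qualitative depth
structure of proton RBE (entrance RBE < 1, RBE and RBE-weighted dose
rising toward the distal edge, spectral hardening with depth) — it does
not validate dosimetric accuracy against real beam data, which requires a
transport code and measurements.

## Problem sizes

The shipped checks use depth grids of 0.5–1 mm over 150 mm, $10^3$ random
spectra for the saturation bounds, $10^6$ Monte Carlo samples per spectrum
for the quadrature cross-check, and a 31-component 60 mm SOBP — sizes at
which every identity above is resolved comfortably while the whole suite
runs in well under a minute of compute.

## Known limitations

* MKM parameters are heavy-ion fits applied to protons unchanged; absolute
  RBE values inherit that approximation.
* A single $(\alpha_0, \beta)$ cell line; no dose-rate, fractionation,
  oxygen, or repair-kinetics effects; no alternative models (LEM, RMF).
* The survival-depth prescription exposes both readings of a "2 Gy at the
  SOBP center" prescription (physical or RBE-weighted), since the
  convention is ambiguous in common usage; callers must choose.
* Synthetic spectra are log-normal mixtures, not track-structure
  calculations; their high-$y$ tails are schematic, so saturation-corrected
  quantities near the distal edge are qualitative.
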