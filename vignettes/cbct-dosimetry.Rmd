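---
title: "Cone-beam CT dose index and dose-length product: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cone-beam CT dose index and dose-length product: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbctdi)
```

## The problem

A single-rotation cone-beam CT (CBCT) scan deposits an axial dose profile
$D(z)$ whose scatter tails extend 30–100 cm along the rotation axis — far
beyond the 100 mm pencil ionization chamber that conventional CT dosimetry
relies on. A CTDI$_{100}$ measurement therefore truncates a large part of
the profile integral, and the standard 15 cm PMMA phantoms are too short to
contain it. This package implements the aperture-normalized formulation of
the CT dose index, which remains meaningful for wide cone beams, together
with the quantities built on it:

* the dose-profile integral over a range $l$,
  $\mathrm{DPI}_l = \int_{-l/2}^{l/2} D(z)\,dz$;
* the aperture-normalized index
  $\mathrm{CTDI}_{a,l} = \mathrm{DPI}_l / T$, where $T$ is the **actual**
  beam width at isocenter (the physical collimation, 1–3 cm wider than the
  console's nominal width), constant across apertures at equilibrium;
* the weighted index
  $\mathrm{CTDI}_{w,l} = \tfrac12\,\mathrm{CTDI}_{a,l}^{\mathrm{center}} +
  \tfrac12\,\overline{\mathrm{CTDI}}_{a,l}^{\mathrm{periphery}}$
  over the center and four peripheral positions (12, 3, 6, 9 o'clock, 1 cm
  below the phantom surface) — the $(\tfrac12,\tfrac12)$ coefficients
  follow Bakalyar's plausible-function-variation argument; the conventional
  CT weighting $(\tfrac13,\tfrac23)$ is available through
  `ctdi_config(weights = c(1/3, 2/3))` for cross-checks but is never the
  default;
* the scan-level mean $\overline{\mathrm{CTDI}_{w,l}}$ across beam widths,
  a single representative dose index for a protocol, and the dose-length
  product $\mathrm{DLP} = \overline{\mathrm{CTDI}_{w,l}} \times T$
  (cGy·cm);
* the truncated pencil-chamber indices CTDI$_{100}$, $\bar D_{100}$ and
  CTDI$_{300}$, and the central ray dose $f(0) = D(0)$, which a point
  measurement with a small chamber in a standard phantom estimates.

Two protocols are modeled: full-fan (head, 16 cm PMMA phantom, integration
range $l = 600$ mm) and half-fan (body, 32 cm phantom, $l = 900$ mm), both
at 125 kVp, 80 mA, 660 projections per rotation.

## The synthetic profile model

No photon-transport simulation ships with this package. Instead, axial
profiles are generated from a parametric decomposition of the cone beam
into narrow-beam profiles: the aperture rectangle of width $T$ convolved
with a narrow-beam line-spread function

$$\mathrm{lsf}(z) = (1-\eta)\, g(z;\sigma) + \frac{\eta}{2d} e^{-|z|/d},$$

with $g$ a unit-area Gaussian ($\sigma = 0$ gives a Dirac core). The
parameters, per measurement position:

| parameter | meaning | unit | default (head center) |
|---|---|---|---|
| $h$ | equilibrium (infinite-beam) plateau dose | cGy | 8.8 |
| $\eta$ | scatter fraction, $[0,1)$ | — | 0.60 |
| $d$ | scatter tail decay length | mm | 60 |
| $\sigma$ | penumbra blur of the aperture edges | mm | 0 |
| noise CV | multiplicative Gaussian noise per sample | — | 0.01 |

This is the simplest kernel that reproduces the three behaviours wide-beam
dosimetry exhibits: (i) a unit-area kernel preserves the rectangle's area,
so $\int D\,dz = hT$ exactly and CTDI$_a$ is constant across apertures;
(ii) the central value $f(0) = h\,(1 - \eta e^{-T/2d})$ rises monotonically
with $T$ and saturates at $h$, because an ever smaller fraction of scatter
reaches the center as the beam widens; (iii) the tails decay exponentially
over a configurable length. Central profiles are required to be at least as
broad as peripheral ones ($\eta$ and $d$), matching phantom measurements.
Profiles are symmetric in $z$: the anode axis is perpendicular to the
rotation axis, so any heel effect is smeared out by the rotation and is not
modeled.

The default parameter sets (head center/periphery $h = 8.8/8.8$ cGy, body
center/periphery $3.1/5.5$ cGy, with the $\eta$, $d$ values in
`default_scatter_params()`) are **illustrative, not fitted**: they land the
weighted index in the qualitative range of clinical head and body tables
(about 8.8 and 4.3 cGy) so that pipeline output looks sensible, but no
published absolute value is claimed from them — those require a validated
transport model of the actual tube, bowtie and phantom. What the generator
does emulate faithfully is the *structure* of simulated profile data: flat
primary core of the actual width, center-broader-than-periphery exponential
tails, about 1% multiplicative statistical noise, and no asymmetry.
Passing tests on synthetic data therefore validate the dose *arithmetic*
and the model's stated invariants, not the absolute dosimetry of any
scanner.

## Numerical choices

* **Grid.** 0.5 mm spacing over ±450 mm by default: ±450 mm covers the
  900 mm body integration range, and at 0.5 mm the discrete profile agrees
  with the closed forms to well under 0.1%. The generator refuses grids
  with half-length below $3d + T$ (visible tail truncation).
* **Convolution.** The rectangle enters as per-cell coverage fractions and
  the exponential kernel as exact per-cell masses, so the discrete
  convolution reproduces the piecewise-analytic profile essentially exactly
  except within one cell of the aperture edge; the Gaussian-blurred core is
  evaluated through the normal CDF.
* **Integration.** Trapezoid rule with linear interpolation at the $\pm
  l/2$ endpoints when they fall between samples. Simpson's rule offers no
  measurable benefit at 0.5 mm spacing and complicates even sample counts.
* **Rounding.** Full precision internally; report output rounds half *up*
  at 2 decimals (`round_half_up()`), the convention of printed dose tables
  (8.495 → 8.50) — base `round()` is half-even and disagrees on exactly
  these cells. DLP is computed from the report-precision mean, matching how
  published tables chain their own printed values; with the full-precision
  mean, one head cell (T = 124 mm) would differ by 0.01 cGy·cm.
* **Noise.** Multiplicative Gaussian, clipped at zero to preserve
  nonnegativity; one integer seed per profile set, consumed position-major
  (center, then 12, 3, 6, 9 o'clock) so fixtures are stable across runs.
* **Film calibration.** The pixel-value → exposure map is a monotone
  Fritsch–Carlson piecewise cubic through the calibration points: a
  dosimetric calibration must not oscillate between knots, which an
  unconstrained cubic can. Evaluation outside the calibrated range is
  refused rather than clamped — silent clamping biases profile tails.
  Net optical density uses the reflective convention
  $\mathrm{NOD} = \log_{10}(\mathrm{PV}_0/\mathrm{PV})$. Only the red
  channel is read (where the film's absorption is most sensitive).
  Exposure converts to dose via the roentgen-to-rad factor 0.869 and a
  dose-to-film factor of 1.00.
* **Beam width from film.** FWHM with linear sub-pixel crossing
  interpolation; at 72 dpi the pixel pitch is $25.4/72 = 0.3528$ mm.
  Extracted profiles are recentered at the centroid of the above-half-max
  region and normalized to their central value.

## Design choices where the design was open

* **Actual beam widths are a lookup, not a model.** The ten calibrated
  nominal → actual pairs per fan mode are measured system data; with no
  collimator geometry available, interpolation between console settings is
  refused.
* **Peripheral geometry.** Four positions at 90° spacing, 1 cm below the
  surface — the CTDI-phantom convention; the angular positions are a
  convention here, not a measured fact.
* **Point-dose comparison.** `percent_difference()` treats the measured
  value as reference and reports one decimal, mirroring how method
  differences are quoted clinically.
* **Problem sizes.** The test-suite and the acceptance script use the
  default 1801-point grid, ten beam widths per scan, and 1000 noise
  replicates on a coarser (1 mm) grid — sizes at which every check runs in
  seconds while the statistical checks (noise CV within [0.008, 0.012])
  retain comfortable margins.

## Known limitations

* No photon transport: spectra, bowtie filters, heel effect, phantom
  heterogeneity and detector response are all outside the model; absolute
  doses from the generator are illustrative.
* The film module models a single (red) channel with a static calibration;
  darkening kinetics, scanner flat-field and multi-channel dosimetry are
  not covered.
* Effective-dose conversion from DLP is out of scope; DLP characterizes
  dose to a body section, not organ dose or risk.

## Reproducing the published relationships

`scripts/acceptance.R` recomputes, from the packaged reference tables and
the synthetic model, the mean weighted CTDI per scan, the DLP cells, the
four point-dose CTDI$_w$ values with their 3.2%/1.2% method differences,
the CTDI$_a$ constancy coefficient of variation, the closed-form agreement
of $f(0)$, the noise-model CV, and the roentgen-to-rad constant — see the
README for how to run it.
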