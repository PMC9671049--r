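---
title: "Nanobubble characterization and uptake quantification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nanobubble characterization and uptake quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbkit)
```

This vignette documents the models behind `nbkit`, their assumptions,
the tunable parameters that matter, what the synthetic-data generators
do and do not emulate, and the numerical choices made where a method
description leaves the design open.

## Flotation model

Sub-micron bubbles rise under buoyancy at the Stokes terminal velocity
of a small rigid sphere,

$$U = \frac{g\,d^2\,\Delta\rho}{18\,\mu},$$

with $d$ the diameter (m), $\Delta\rho$ the density difference between
medium and gas core (kg/m³) and $\mu$ the dynamic viscosity (Pa·s).
Defaults describe perfluoropropane-core bubbles in water:
$\mu = 8.9\times10^{-4}$ Pa·s, $\Delta\rho = 998 - 8 = 990$ kg/m³,
$g = 9.81$ m/s². The model assumes creeping flow (Reynolds numbers here
are $\sim 10^{-8}$), a rigid no-slip interface, and instantaneous
attainment of terminal velocity — the inertial transient for these
particles is sub-microsecond, so `rise_distance()` simply multiplies
$U$ by the duration.

The denominator constant 18 is the rigid-sphere Stokes value, but it is
exposed (`drag_constant`) because lipid-shelled bubbles need not obey
rigid-sphere drag exactly: shell mobility, surfactant gradients and
wall proximity all perturb the effective drag. All flotation results in
this package use 18 unless the user overrides it.

`flotation_transfer_fraction()` adds one further assumption: bubbles
start uniformly distributed over the channel depth $h$, so the fraction
of size-$d$ bubbles reaching the ceiling within $t$ is
$\min(1, U t / h)$. Hindered settling, bubble–bubble interactions and
wall effects are ignored; the result is an upper bound that is exact
for dilute suspensions. A useful analytic consequence, used as a test
oracle: below the full-transfer cutoff the transfer weight is $d^2$, so
a lognormal population with median $m$ and log-SD $s$ has its mode
moved from $m e^{-s^2}$ to $m e^{+s^2}$.

## Rayleigh scattering and the detection model

For particles much smaller than the wavelength (size parameter
$x = \pi d / \lambda \ll 1$), the scattering cross-section is

$$\sigma_s = \frac{2\pi^5}{3}\,\frac{d^6}{\lambda^4}
  \left(\frac{m^2-1}{m^2+2}\right)^2, \qquad m = n_\mathrm{p}/n_\mathrm{m}.$$

`rayleigh_cross_section()` warns (but does not fail) when $x > 0.3$,
the conventional edge of the Rayleigh regime; the $2\pi^5/3$ prefactor
is the standard form, and every downstream use is a ratio, which is
prefactor-independent. The bubble/liposome contrast — gas core
($n = 1.00$) versus aqueous core ($n = 1.38$) in water ($n = 1.33$) —
is

```{r}
scattering_ratio(100e-9, bubble_optics(), liposome_optics())
```

independent of diameter and wavelength, because it depends only on the
two relative indices.

Particle-tracking instruments bundle gain, shutter time and a display
histogram limit into a "camera level". `detection_signal()` models the
per-particle signal as

$$S = \kappa\,\sigma_s(d)\,\times\,\mathrm{gain}\times\mathrm{shutter},$$

i.e. scattered power integrated over the shutter and amplified by the
gain; the histogram limit only rescales the display, so it is
deliberately left out of the signal model. The single calibration
constant $\kappa = 5.1\times10^{15}$ au/(m²·ms·gain-unit) was fixed
once, as the geometric midpoint between two anchor observations at
90 nm and 488 nm illumination: the brightest setting at which a 90 nm
liposome must remain invisible (gain 15, shutter 7.93 ms) and the
faintest at which a 90 nm bubble must be visible (gain 15, shutter
0.33 ms). With the default detection threshold of 1 au this one
constant reproduces the full qualitative pattern — liposomes invisible
at levels 3–5 and 8, visible at level 12; bubbles visible from
level 3 — and the signal model's $d^6$ dependence then predicts the
size cutoff of each level.

## Size-distribution analytics

`size_distribution` objects are binned: strictly increasing diameter
bin centers (nm) against number concentration per bin (/mL). Statistics
follow the conventions that keep them stable on coarse grids:

- **Mode**: bin center of the maximum bin; ties break toward the
  smaller diameter (deterministic, so repeated analyses agree).
- **Percentiles / fraction below**: the cumulative number curve is
  treated as piecewise linear through the bin centers and interpolated
  inside the crossing bin. The step-function alternative was rejected
  because it makes percentiles jump by whole bins under tiny
  concentration perturbations; with the linear convention
  `percentile_size()` and `fraction_below()` are exact mutual inverses,
  which the tests exploit.
- **Volume weighting / gas volume fraction**: per-bin weight
  $(\pi/6) d^3$; the gas volume fraction is reported in percent of the
  suspension volume.

Dynamic-light-scattering summary sizes (Z-average, PDI) are instrument
outputs of a cumulants analysis this package does not reimplement;
`intensity_weighted_harmonic_mean()` is provided as a rough
intensity-weighted helper and is documented as non-validated.

## Stability analysis

Decay series are fitted to a single exponential without offset,
$C(t) = C_0 e^{-kt}$, $\tau_{1/2} = \ln 2 / k$. An additive plateau
term was rejected deliberately: on a 60 min observation window an
offset is barely identifiable and destroys the interpretability of the
half-life. The default fit is unweighted Levenberg–Marquardt on the raw
concentrations (started from the log-linear regression);
`log_domain = TRUE` instead uses the log-linear fit itself, the
maximum-likelihood choice under multiplicative noise. Both modes are
exposed because neither is canonical for this kind of data; on the
synthetic generator (5 % multiplicative noise) they agree to well
within the fit standard errors. Half-life uncertainty is propagated
from the rate-constant standard error by the delta method
($\mathrm{se}_\tau = \ln 2 \, \mathrm{se}_k / k^2$). A series whose
fitted decay over the whole window is negative or indistinguishable
from zero ($k\,t_\max < 10^{-6}$) is flagged `non-decaying` with
infinite half-life rather than failing, so batch reports keep going.

Retention after storage is normalized as
$100 \times C_\mathrm{final} \times \mathrm{dilution} / C_\mathrm{initial}$,
and the free (non-shell) lipid carried along with a dilution is
$\mathrm{stock}/\mathrm{dilution}$ with a 40 µg/mL stock default, both
configurable. The retention-vs-spacing model
$R(l/d) = A e^{-(l/d)/B}$ is a two-parameter exponential chosen for
extrapolation stability; `required_spacing_for_full_stability()` solves
$R = 100\,\%$ in closed form, $B \ln(A/100)$, and refuses to
extrapolate when $A \le 100$ (the curve never crosses full retention).

## Uptake imaging pipeline

`quantify_uptake()` composes six stages, each exposed individually:

1. **Mask** (`make_cell_mask`): Otsu threshold on the live-stain
   channel (parameter-free and deterministic; a fixed threshold can be
   supplied), then morphological opening (disk radius `r_open = 2` px,
   removing speckle) and dilation (`r_dil = 3` px, growing the mask so
   entire cells — including rims dimmer than the stain threshold — are
   included). Defaults suit cell-scale objects a few pixels and up;
   both radii are configurable.
2. **Background** (`subtract_background`): scalar background = median
   intensity outside the mask (robust to any uptake signal, which lives
   inside the mask), clipped at zero.
3. **Profile** (`masked_axial_profile`): per-column mean of the tracer
   over mask pixels only, with x in mm along the chip (the long image
   axis by default). Columns without mask pixels are filled by linear
   interpolation and flagged.
4. **Smooth + baseline** (`smooth_and_baseline`): Savitzky–Golay
   (order 2, 2 mm window — the window is converted to an odd sample
   count) followed by baseline subtraction. The baseline is a stiff
   Whittaker smoother (second-difference penalty; stiffness set by
   `baseline_scale_mm = 7`, the scale below which the baseline refuses
   to bend) refitted iteratively with points more than 2.5 robust SDs
   *above* the current baseline excluded. This one-sided peak-rejection
   scheme was chosen over classical asymmetric least squares after
   noting that AsLS tracks the lower noise envelope, which leaves a
   systematic positive offset on peak-free profiles; the rejection
   variant is unbiased on pure noise (the package tests assert a mean
   within 2 SE of zero) yet still refuses to absorb genuine peaks.
5. **Peak fit** (`fit_gaussian_peak`): Levenberg–Marquardt fit of
   $A e^{-(x-x_c)^2/2\sigma^2} + c$, initialized from the maximum and
   its half-max width. "No clear uptake" needed an operational
   definition; the fit is successful only if it converges with $x_c$
   inside the profile, $\sigma \in (0.1\ \mathrm{mm},
   \mathrm{extent}/2)$, and $A > 3\times$ the noise scale. The noise
   scale is taken from the *raw* profile (median absolute deviation of
   raw minus smoothed): the fit's own residuals on smoothed data are
   far smaller than the true noise and would let smoothed-noise bumps
   masquerade as peaks.
6. **Integration** (`total_fluorescence_intensity`): trapezoidal
   integral of the unsmoothed profile, after removal of the estimated
   baseline, over $[x_c - 2\sigma,\, x_c + 2\sigma]$ — capturing
   $\operatorname{erf}(\sqrt 2) = 95.45\,\%$ of a Gaussian peak — or
   over a central 7 mm window when the fit failed. Windows reaching
   past the profile are clipped with a warning, not failed. The
   integrand is baseline-removed on purpose: pixel-level clipping at
   zero gives any noise-only profile a small constant positive offset
   (mean of a half-normal), and integrating it raw would bias control
   measurements away from zero; the baseline removes exactly this kind
   of slowly varying offset while leaving the peak intact.

TFI is reported in au·mm. The intensity scale has no absolute
calibration, so only within-study comparisons (treated vs. control,
dose–response slopes) are meaningful; the package validates the
pipeline by recovery of planted synthetic uptake, not by absolute
values.

Brightfield bubble counting (`count_ovb`) detects dark spots more than
5 robust SDs below the median, labels connected components, applies
area bounds (default ≥ 4 px, rejecting single-pixel noise), and
converts counts to concentration via the imaged volume (field area ×
chamber depth, 50 µm default). `ovb_detection_limit()` gives the
one-bubble-per-volume floor, about $10^6$/mL for a
$2\times10^4$ µm² field at 50 µm depth.

## Synthetic data: what it emulates, and what it does not

The generators under `generator_spec()` emulate the statistical
structure the analyses assume, with defaults chosen to mirror typical
isolated-nanobubble experiments:

- **Size distributions**: lognormal (right-skewed, strictly positive —
  the standard shape for tracking-based sizing), median 300 nm,
  $\sigma_{\ln} = 0.35$, $10^{10}$/mL, on a 10 nm grid over
  50–1000 nm (the working range of tracking instruments). The liposome
  subpopulation is parameterized by its 90 nm mode,
  $\sigma_{\ln} = 0.2$, $2.3\times10^{12}$/mL, and hard-truncated at
  150 nm: precursor vesicle preparations contain essentially no large
  vesicles, and without truncation the $d^6$ signal scaling would make
  an (unphysical) lognormal tail of large liposomes visible at low
  camera levels.
- **Decay**: exponential with multiplicative lognormal noise (counting
  error grows with concentration), default 5 %, 13 points over 60 min,
  $C_0 = 10^9$/mL.
- **Confocal maps**: a 17 × 3.8 mm channel sampled at 20 µm/px
  (850 × 190 px) — much coarser than a real tile scan, but the
  pipeline consumes only mask coverage and masked column means, so
  this keeps the full test suite fast without touching the quantities
  under test. Cells are uniform disks (radius 6 px) whose tracer
  content is modulated by a planted Gaussian stripe (center 8.5 mm,
  σ = 1.5 mm, amplitude 50 au over a 10 au background, noise SD 2 au);
  the live stain marks a smaller core disk (radius 3 px), mirroring
  real stains that binarize only the cell interior — which is exactly
  why the mask pipeline dilates. No point-spread function, no z-depth,
  no realistic cell morphology: passing tests demonstrate correct
  *pipeline arithmetic* (mask coverage, profile extraction, window
  selection, integration), not robustness to real microscope artefacts.
- **Brightfield**: dark disks on a bright noisy background, placed
  without overlap by rejection sampling.

Every generator is bit-reproducible under its seed, restores the
caller's RNG state, and returns its planted ground truth as a `"truth"`
attribute; all round-trip tests consume those records rather than
hand-entered numbers.

## Problem sizes and determinism

The packaged validation uses sizes chosen to make every property
statistically decisive while keeping a full run interactive: 200 seeded
replicates per half-life for decay recovery, 50 treated plus 50 control
maps for the TFI pipeline, 850-sample profiles. The whole suite runs in
well under a minute on a single core. All randomness flows from
explicit integer seeds; the analysis pipeline itself contains no
randomness at all, so identical inputs give bit-identical results.

## Known limitations

- No Mie scattering: above $x \approx 0.3$ the Rayleigh cross-section
  is extrapolated with a warning, and the ~46× bubble/liposome contrast
  applies to the small-particle limit only.
- No mechanistic dissolution model (Epstein–Plesset) and no
  oscillation dynamics; the stability module fits and interprets decay
  curves, it does not predict them from physics.
- The flotation model ignores hindered settling, coalescence during
  rise, and any interaction with the channel walls.
- TIFF round-trips are limited by 32-bit float precision (~$10^{-7}$
  relative); CSV and JSON adapters round-trip at full double precision.
- The fitted camera-level model is a single-constant calibration of a
  proportional signal law; it reproduces the documented visibility
  pattern but is not a radiometric model of any particular instrument.
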