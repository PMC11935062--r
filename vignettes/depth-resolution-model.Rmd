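---
title: "Modeling axial resolution and attenuation in confocal through-plane scans"
author: "depthPSF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling axial resolution and attenuation in confocal through-plane scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depthPSF)
```

## The problem

A confocal microscope (fluorescence or Raman) can image *through* a
translucent sample by stepping the focus along the optical axis. Two
artifacts degrade such through-plane scans with increasing focus depth:

* the axial resolution worsens, because refraction at index-mismatched
  interfaces spreads marginal and paraxial rays onto different focal
  points, and
* the collected intensity decays, because scattering, absorption and
  defocusing remove signal (Beer–Lambert-like extinction).

`depthPSF` quantifies both from a *single* through-plane scan of a
planar, homogeneous layer (or a stack of spectrally distinct layers). It
returns the axial point-spread-function (PSF) full width at half maximum
(FWHM) at the upper and the lower interface of each layer, the
resolution decay per distance, and the attenuation coefficient.

## The forward model

The measured depth signal is the convolution of the instrument's axial
PSF with the sample's ideal (infinite-resolution) composition profile.
For a single layer between interfaces $z_1 < z_2$ (optical thickness
$t = z_2 - z_1$):

$$S(z) \;=\; \int_{-\infty}^{+\infty}
  \mathrm{rect}_{[z_1,z_2]}(y)\; h\, e^{-\mu (y - z_1)}\;
  L\!\left(z - y;\, \gamma(z)\right)\, dy$$

with

* $L(u;\gamma) = \dfrac{1}{\pi}\dfrac{\gamma/2}{u^2 + (\gamma/2)^2}$, a
  unit-area Lorentzian of FWHM $\gamma$ — the axial PSF form that
  describes confocal Raman calibration scans well (a Gaussian
  alternative is available behind the `form` switch);
* $\gamma(z) = \gamma_1 + (\gamma_2-\gamma_1)\,(z - z_1)/t$, a linear
  growth of the PSF FWHM between the interfaces, the first-order
  consequence of refraction theory; $\gamma(z)$ is clamped to
  $\gamma_1$ above and $\gamma_2$ below the layer (the minimal extension
  that keeps the immersion-side resolution at its calibrated value);
* $h\,e^{-\mu (y-z_1)}$, the ideal in-layer intensity: amplitude $h$ at
  the first interface decaying with the attenuation coefficient $\mu$
  (units 1/µm). The decay argument is the depth below the *first
  interface*, so $h$ has a fixed physical meaning; whether $\mu$ acts
  along nominal or refraction-corrected depth is not resolvable from a
  single scan, and the nominal (stage) depth of the fit coordinate
  system is used.

The kernel FWHM depends on the *evaluation* point $z$, not on the
integration variable — resolution is a property of where the focus sits.
Outside the layer the ideal profile is zero by default; two optional
background plateaus (`topLevel` above $z_1$, `bottomLevel` below $z_2$)
model uneven background such as fluorescence or spectral overlap with
the immersion medium, and are estimated by averaging the first and last
five scan points (`estimateBackgroundPlateaus()`).

Four parameters — $\gamma_1$, $\gamma_2$, $\mu$, $h$ — are free; the
interfaces come from the detection step below.

### Numerical evaluation

`convolveModel()` splits the layer into uniform sub-cells (default width
$\Delta z/8$, at least 32 cells; narrower than $\Delta z/4$ is
enforced). Within each cell the decaying exponential is expanded to
second order around the cell midpoint, while the kernel's zeroth, first
and second moments over the cell are integrated *in closed form* with
the arctangent antiderivative family of the Lorentzian (error-function
family for the Gaussian). The plateau contributions are exact arctangent
terms, so the total kernel mass is exactly 1 by construction: truncation
can bias neither $h$ nor $\mu$. The only discretization error is the
third-order remainder of the in-cell expansion, about
$O((\mu\,\mathrm{res})^3)$ — near $10^{-10}$ relative at the defaults,
confirmed against a brute-force fine-grid Riemann oracle in the test
suite. Refining the sub-cell width changes the curve by far less than
$10^{-4}$ relative.

`psfKernelMass()` documents the kernel normalization the traditional
way: midpoint quadrature over a ±40-FWHM window plus the closed-form
arctangent tail mass, which recovers 1 to better than $10^{-4}$.

## Interface detection

An interface appears as an intensity swap: the transition between
background level and a material lobe. Mathematically it is an inflection
point — the zero of the profile's second derivative — and each flank is
summarized by a four-parameter sigmoid

$$f(z) = a + \frac{b}{1 + e^{\mp c (z - d)}},$$

whose fitted inflection $d$ estimates the interface (sign by edge
direction). `detectInterfaces()` proceeds as follows:

1. smooth the normalized profile with a 3-point moving average;
2. threshold at 12% of the amplitude above the background level (the
   smaller of the two scan-end means) to find the intensity lobes; if
   more lobes separate than layers were declared, the dominant ones are
   kept — interfaces are the dominant intensity swaps;
3. anchor one rising segment at each lobe entry and one falling segment
   at each lobe exit, spanning from the adjacent background plateau to
   just past the edge shoulder (30% of the lobe amplitude, plus a small
   pad). Bounding the segments matters: under strong attenuation the
   exponential decay ramp has a larger total amplitude than the faint
   second-interface edge, and an unbounded segment would lock onto the
   ramp instead of the edge;
4. fit the sigmoid per segment (`minpack.lm::nlsLM`, steepness seeded
   from the observed maximum slope, up to three deterministic restarts
   with shifted $d$), then refit once or twice on a window of width
   $4/c$ around the fitted inflection, rejecting refinement steps that
   race toward the lobe peak (the signature of the decay ramp taking
   over the window).

When the automatic test fails — heavy noise, extreme decay — detection
raises a condition directing to `setInterfaces()`, the manual override;
positions can be exported and re-imported as a two-column text file to
support that workflow. Non-planar or tilted interfaces are out of scope:
the model is only valid for phase transitions perpendicular to the
optical axis.

### From inflection to interface

With attenuation, the inflection of the *measured* curve sits
systematically inside the true interface — linearizing the model around
the edge gives a shift of about $\mu\gamma^2/4$ for a Lorentzian kernel,
plus a comparable contribution from the asymmetry of the flanking
signal. `fitLayer()` therefore treats detected positions as
initializers: after the parameter sweep, each interface is re-located on
a fine grid (±4 µm in steps of the convolution resolution, coarse to
fine) minimizing the residual sum of squares of the model, with a small
adaptive parameter grid per candidate so the strongly correlated
$(z_2, \gamma_2, h)$ ridge cannot stall the search, and the final sweep
stage is re-run at the refined positions. Interfaces set manually are
left untouched by default (`refineInterfaces = FALSE` for manual
provenance).

## The parameter sweep

`fitLayer()` minimizes the residual sum of squares
$\mathrm{LSQ} = \sum_i (y_i - S(z_i))^2$ by an exhaustive Cartesian grid
sweep over $(\gamma_1, \gamma_2, \mu, h)$ — deliberately simple,
derivative-free and global within its ranges. Defaults
(`SweepConfig()`):

| parameter  | range            | final increment |
|------------|------------------|-----------------|
| $\gamma_1$ | 0.3–20 µm        | 0.1 µm          |
| $\gamma_2$ | 0.3–20 µm        | 0.1 µm          |
| $\mu$      | 0–0.3 1/µm       | 0.002 1/µm      |
| $h$        | 1–3              | 0.02            |

Two coarse-to-fine stages (contraction 5×): stage 1 runs the full range
at 5× the final increment, stage 2 re-centers a range of 1/5 the width
on the incumbent at the final increment. The incumbent always lies on
the refined grid, so refinement can never worsen the LSQ. Ties break
toward the lexicographically smallest $(\gamma_2, \gamma_1, \mu, h)$ for
reproducibility. Because the model is linear in $h$, each
$(\gamma_1,\gamma_2,\mu)$ grid point evaluates the entire $h$ grid from
two inner products; the sweep over all four parameters is preserved, it
is merely evaluated efficiently. The ranges bracket the parameter
magnitudes of typical polymer films under air, water and oil objectives;
for thick or otherwise expensive scans the ranges and increments should
be adapted to the sample, which is also how the reference workflow
keeps its computation times low.

The sweep can be parallelized (`workers`); blocks of the $\gamma_2$ grid
are computed identically regardless of the worker count and reduced
deterministically, so results are bitwise independent of parallelism.

### The free normalization offset

The measured profile is min–max normalized, which pins its *smallest
sample* to zero. That zero is arbitrary: the heavy Lorentzian tails keep
the true signal near 2% of peak even at the scan edges, and under noise
the minimum sample sits a couple of standard deviations below the signal
floor. The comparison therefore allows one global additive constant,
solved in closed form together with each grid combination (equivalent to
mean-centering residual and model curve). Without it the fitted
$\gamma_2$ inflates to chase the forced zero. The constant is reported
as `FitResult@offset`; when background plateaus are enabled they take
this role and no extra offset is fitted. $h$ continues to absorb the
normalization *scale*.

### Quality control and statistics

`qcEvaluate()` flags `poor_fit` when $R^2 < 0.99$ — with
$R^2 = 1 - \mathrm{LSQ}/SS_\mathrm{tot}$ where $SS_\mathrm{tot}$ is the
*uncentered* total sum of squares $\sum_i y_i^2$ of the data (the
definition used with this model; the conventional mean-centered form is
available via `centered = TRUE`) — `negligible_attenuation` when
$\mu \le 10^{-3}$ 1/µm, and `subresolution_gamma1` when $\gamma_1$
falls below a supplied calibrated objective FWHM (paraxial focus
compression at strongly mismatched interfaces produces such apparent
super-resolution; the paraxial projection
`paraxialCorrectedDepth()`/`correctedThickness()`, $z_{focus} = \Delta n
\, z_0$, converts optical to geometric thickness). `range_boundary`
marks an optimum pinned to a sweep-range edge.

`aggregateReplicates()` reports mean ± standard deviation (over
replicates, $n-1$ denominator) per descriptor across independent scans
of the same configuration. When every replicate is flagged
`negligible_attenuation`, statistics on $\mu$ are suppressed and printed
as "-": a decay at or below $10^{-3}$ 1/µm is not meaningfully
quantifiable from these scans.

## PSF calibration and the analytic optics formulas

The diffraction-limited axial FWHM of an objective is measured by
scanning an *optically thin* sample (much thinner than the diffraction
limit, e.g. a monolayer or a strongly absorbing wafer surface): the scan
then reads out the PSF directly, and `calibratePSF()` fits amplitude,
center, constant baseline and FWHM jointly (the baseline because real
thin-sample scans have nonzero background). A fitted FWHM above half the
scan span triggers a thin-sample warning. The analytic companions —
`lateralFWHM()` ($0.4\lambda/\mathrm{NA}$), `idealAxialFWHM()`
($0.64\lambda/(n - \sqrt{n^2-\mathrm{NA}^2})$, ideal pinhole) and the
refraction-based `depthOfFocus()` — are diagnostics only and never enter
the fit; the depth-of-focus formula in particular overestimates the
focal spread because it neglects the confocal aperture, and is restricted
to $\mathrm{NA} < 1$. The immersion-medium index enters the ideal axial
FWHM while the sample index enters the refraction formulas; the two are
deliberately separate `OpticsConfig` fields.

## Multilayer stacks

For a stack of spectrally distinct layers, one sum-filter window per
material separates the scan into per-label depth profiles
(`splitComponents()`; overlapping windows are allowed but warned about).
Each layer is fitted *pairwise* between its own interfaces, in depth
order. For a label occurring twice (e.g. the same polymer above and
below an interlayer), the deeper lobe is renormalized on its own local
extrema (`renormalizeDeeper()`) to compensate the intensity lost above
it — elevating background levels outside the lobe, which is reported.
Additionally, `fitStack()` subtracts the fitted forward-model curves of
a label's *other* occurrences before renormalizing and fitting a lobe,
and runs a second refit pass: the heavy kernel tails of the neighboring
lobe otherwise leak into the segment and bias the lobe-facing FWHM by
several increments. Continuity — the absolute difference of the FWHM
reconstructed at a shared depth from the two adjacent layers — is
reported as a diagnostic but never enforced, since real stacks can show
genuinely different decay rates per layer. Joint optimization over all
layers simultaneously is a non-goal.

## The synthetic-scan generator

`generateProfile()`/`generateHyperspectral()` render scans with exactly
the statistical structure the model assumes: the forward curve on the
scan grid (step sizes of 200–666 nm and scan depths of roughly twice the
layer thickness emulate typical acquisitions), plus additive Gaussian
noise with standard deviation expressed as a fraction of the noiseless
peak (1% in most validation studies; a Poisson-on-counts option exists
for hyperspectral rendering), then min–max normalization. Hyperspectral
rendering multiplies each label's depth weight with a synthetic
Lorentzian band (configurable center/width); band overlap reproduces the
immersion-medium spectral-overlap artifact on demand. Ground truth is
returned with amplitudes mapped to post-normalization units
($h' = h/(\max-\min)$ of the pre-normalization signal).

The generator deliberately does *not* simulate refraction or
diffraction: fixtures come from the model itself, which makes them the
correct oracle for the fitter but also means that passing recovery tests
demonstrate the *estimation machinery*, not the physical adequacy of the
linear-FWHM/Beer–Lambert description for any particular real sample.
Real scans additionally contain baseline drift, cosmic rays and
correlated noise that the generator omits (spectral background
subtraction is expected upstream, as is usual for commercial
acquisition software).

## Validation studies and problem sizes

The test suite regenerates every fixture and re-derives every expected
value at run time. The main studies, with the problem sizes chosen for
them:

* **Oracle equivalence** — 50 random layer models against an
  independent brute-force Riemann oracle at 40× finer resolution
  (tolerance $10^{-6}$ relative; the implementation itself is exact to
  about $10^{-10}$, the margin is dominated by the oracle's own midpoint
  boundary error), and exact agreement of the sweep with an exhaustive
  quadruple loop on a frozen grid.
* **Parameter recovery** — 20 single-layer scans with truths drawn from
  $\gamma_1 \in [0.7, 1.8]$, $\gamma_2 \in [1.6, 4.3]$ µm,
  $\mu \in [0, 0.1]$ 1/µm, $t \in [14, 30]$ µm at 1% noise; median
  absolute error within two final increments per parameter. The FWHM
  sweep ranges are bracketed to [0.3, 8] µm for these studies, as one
  would for any sample known to this magnitude.
* **Fit quality** — minimum $R^2$ over four replicates at 1% noise:
  at least 0.996 for the negligible-mismatch regime
  ($\gamma_1=\gamma_2=1.5$ µm, $\mu = 0$, $t = 29$ µm) and at least
  0.99 for the strong-decay regime ($\gamma_1 = 0.9$, $\gamma_2 = 3.9$
  µm, $\mu = 0.0945$ 1/µm, $t = 14$ µm).
* **Failure regime** — a 78-µm layer with extreme decay
  ($\gamma_2/\gamma_1 > 15$, $\mu = 0.034$ 1/µm): at least half of 20
  seeds must fail quality control. This reproduces the documented limit
  of the method qualitatively — the faint, heavily blurred second
  interface defeats automatic detection — and is where the manual
  interface workflow becomes mandatory.
* **Multilayer consistency** — a three-layer stack with a globally
  linear $\gamma(z)$; the FWHM reconstructed at each shared interface
  from both adjacent layers agrees with the truth and across layers
  within two increments (0.2 µm).

## Known limitations

* Interface positions drive everything; at extreme decay or poor
  signal-to-noise they are unreliable, and the model-based refinement
  can only correct initializations that are roughly right.
* The linear FWHM growth and the single exponential decay are
  first-order descriptions; materials with internal structure
  (crystallinity, scattering anisotropy) can show decay that these four
  parameters absorb only effectively.
* Layers thinner than about 4 sub-cells × 8 per step cannot be
  quadratured (a hard error asks for a finer resolution); layers thinner
  than the local PSF are better treated by `calibratePSF()`.
* The free normalization offset assumes the scan's floor is a constant;
  a sloped background should instead be handled with the plateau option
  or upstream background subtraction.
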