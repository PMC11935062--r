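# depthPSF

Confocal microscopes (Raman or fluorescence) can image *through*
translucent samples, but the axial resolution degrades and the signal
decays with focus depth: refraction at index-mismatched interfaces
spreads the focal volume, and scattering/absorption attenuate the
signal. `depthPSF` extracts all of this from a **single through-plane
scan** of a planar layer: the axial point-spread-function (PSF) FWHM at
the upper and lower interface, the resolution decay per distance, and
the Beer–Lambert attenuation coefficient. It is aimed at microscopists
doing depth profiling of polymer films, membranes and other layered
translucent materials who need to know how trustworthy feature sizes and
component weights in their depth scans are.

## The model

The measured depth signal is modeled as the convolution of the axial PSF
with the ideal composition profile of the layer:

```
S(z) = ∫ rect[z1,z2](y) · h·exp(−μ(y−z1)) · L(z−y; γ(z)) dy
L(u; γ) = (1/π) (γ/2) / (u² + (γ/2)²)           (unit-area Lorentzian)
γ(z)   = γ1 + (γ2−γ1)(z−z1)/t                    (linear FWHM growth)
```

Interfaces `z1, z2` are located by sigmoid fits at the inflection points
of the profile (with a manual override); the four parameters
`(γ1, γ2, μ, h)` are optimized by an exhaustive coarse-to-fine grid
sweep of the residual sum of squares, and fit quality is reported as
`R² = 1 − LSQ/Σy²`. Optically thin samples calibrate the objective's
diffraction-limited FWHM (`calibratePSF()`); the paraxial projection
`z_focus = Δn·z0` converts optical to geometric thickness. Multilayer
stacks of spectrally distinct materials are separated by per-band sum
filters and fitted layer by layer. A synthetic-scan generator with known
ground truth backs the entire validation suite.

See the vignette (`vignettes/depth-resolution-model.Rmd`) for the
numerical scheme, parameter defaults, design decisions and limitations.

## Worked example

Simulate a strongly attenuating 14-µm polymer layer scanned in air
(truth: γ1 = 0.9 µm, γ2 = 3.9 µm, μ = 0.0945 µm⁻¹, interfaces at 7 and
21 µm, 1% noise), then run the full pipeline:

```r
library(depthPSF)

spec <- SyntheticSpec(
  LayerModel(7, 21, gamma1 = 0.9, gamma2 = 3.9, mu = 0.0945, h = 1.2),
  zRange = c(0, 28), stepSize = 0.5, noiseSigma = 0.01, seed = 1L)
gp <- generateProfile(spec)

ifaces <- detectInterfaces(gp$profile, nLayers = 1)
ifaces
#> InterfaceSet: 2 interfaces (1 layer(s))
#>   positions (um): 6.891 [auto], 20.339 [auto]
#>   optical thickness (um): 13.448

fit <- fitLayer(gp$profile, ifaces,
                SweepConfig(gamma1Range = c(0.3, 8),
                            gamma2Range = c(0.3, 8)))
fit
#> FitResult
#>   FWHM first interface : 0.900 um
#>   FWHM second interface: 3.800 um
#>   resolution decay     : 0.2070 um/um
#>   attenuation mu       : 0.096 1/um
#>   optical thickness    : 14.011 um
#>   R^2 = 0.999690 (LSQ = 0.004169), 833826 grid points evaluated
```

The fit recovers the generating parameters to within one sweep increment
each: the resolution at the first interface (0.9 µm) matches the
objective's calibrated PSF, the resolution at the second interface has
degraded to 3.8 µm (decay 0.21 µm per µm of focus depth), and the layer
attenuates with μ ≈ 0.096 µm⁻¹. Note the fitted optical thickness
(14.0 µm) improves on the raw inflection-point distance (13.4 µm): with
attenuation, inflections sit systematically inside the true interfaces,
so the detected positions are refined against the forward model. With
the sample and immersion refractive indices the geometric thickness
follows from the paraxial correction:

```r
correctedThickness(fit, OpticsConfig(532, 0.9, nImmersion = 1.0,
                                     nSample = 1.58))
#> [1] 22.13704
```

A command-line interface wrapping the same pipeline (subcommands
`calibrate-psf`, `fit-layer`, `fit-stack`, `simulate`) is installed at
`inst/cli/depthPSF.R`:

```sh
Rscript inst/cli/depthPSF.R simulate --out /tmp/demo --seed 7
Rscript inst/cli/depthPSF.R fit-layer --input /tmp/demo/synthetic.profile.csv \
    --out /tmp/demo/fit --gamma-range 0.3,8
```

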