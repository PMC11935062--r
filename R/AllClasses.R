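#' @import methods
NULL

## Central data containers. All depths are in micrometers (um), wavenumbers
## in 1/cm, intensities in detector counts before normalization and
## dimensionless afterwards.

#' SpectralScan: a hyperspectral confocal through-plane scan
#'
#' One background-subtracted spectrum per axial focus position. Rows of
#' `intensities` correspond to `zPositions`, columns to `wavenumbers`.
#'
#' @slot z Numeric, axial focus positions (um), strictly ascending and
#'   uniformly spaced (within 1\% relative tolerance).
#' @slot wavenumbers Numeric, spectral axis (1/cm).
#' @slot intensities Numeric matrix of counts, `length(z)` rows and
#'   `length(wavenumbers)` columns; all values finite.
#' @slot stepSize Numeric scalar, the axial step of the scan (um).
#' @slot meta Character, free-text objective/immersion labels.
#'
#' @seealso [SpectralScan()], [loadScan()], [sumFilter()]
#' @exportClass SpectralScan
setClass("SpectralScan",
    slots = c(
        z = "numeric",
        wavenumbers = "numeric",
        intensities = "matrix",
        stepSize = "numeric",
        meta = "character"
    )
)

setValidity("SpectralScan", function(object) {
    msg <- character()
    z <- object@z
    if (length(z) < 2L)
        msg <- c(msg, "need at least two axial positions")
    if (any(diff(z) <= 0))
        msg <- c(msg, "z positions must be strictly increasing")
    if (length(z) >= 3L) {
        dz <- diff(z)
        if ((max(dz) - min(dz)) / mean(dz) > 0.01)
            msg <- c(msg, "z spacing must be uniform within 1% relative tolerance")
    }
    if (nrow(object@intensities) != length(z))
        msg <- c(msg, "intensity matrix must have one row per z position")
    if (ncol(object@intensities) != length(object@wavenumbers))
        msg <- c(msg, "intensity matrix must have one column per wavenumber")
    if (!all(is.finite(object@intensities)))
        msg <- c(msg, "all intensities must be finite")
    if (length(object@stepSize) != 1L || object@stepSize <= 0)
        msg <- c(msg, "stepSize must be a positive scalar")
    if (length(msg)) msg else TRUE
})

#' DepthProfile: an integrated, min-max normalized depth profile
#'
#' The experimentally observed through-plane signal S(z): the sum-filtered
#' (band-integrated) intensity at each focus depth, min-max normalized so
#' the smallest sample is 0 and the largest 1. `rawMin`/`rawMax` record the
#' normalization; `topLevel`/`bottomLevel` hold background plateau estimates
#' (see [estimateBackgroundPlateaus()]), `NA` until estimated.
#'
#' @slot z Numeric, focus depths (um), strictly ascending, uniform spacing.
#' @slot intensity Numeric, normalized intensity in `[0, 1]`.
#' @slot stepSize Numeric scalar, axial step (um).
#' @slot rawMin,rawMax Numeric scalars, pre-normalization extrema (counts).
#' @slot topLevel,bottomLevel Numeric scalars, plateau estimates above /
#'   below the sample (normalized units), `NA_real_` if not estimated.
#'
#' @seealso [DepthProfile()], [sumFilter()], [detectInterfaces()]
#' @exportClass DepthProfile
setClass("DepthProfile",
    slots = c(
        z = "numeric",
        intensity = "numeric",
        stepSize = "numeric",
        rawMin = "numeric",
        rawMax = "numeric",
        topLevel = "numeric",
        bottomLevel = "numeric"
    )
)

setValidity("DepthProfile", function(object) {
    msg <- character()
    z <- object@z
    y <- object@intensity
    if (length(z) != length(y))
        msg <- c(msg, "z and intensity must have equal length")
    if (length(z) < 8L)
        msg <- c(msg, "a depth profile needs at least 8 points")
    if (any(diff(z) <= 0))
        msg <- c(msg, "z must be strictly increasing")
    if (length(z) >= 3L) {
        dz <- diff(z)
        if ((max(dz) - min(dz)) / mean(dz) > 0.01)
            msg <- c(msg, "z spacing must be uniform within 1% relative tolerance")
    }
    if (!all(is.finite(y)))
        msg <- c(msg, "intensities must be finite")
    if (length(y) && (abs(min(y)) > 1e-12 || abs(max(y) - 1) > 1e-12))
        msg <- c(msg, "profile must be min-max normalized (min 0, max 1)")
    if (length(msg)) msg else TRUE
})

#' SigmoidFit: a fitted interface edge
#'
#' Least-squares parameters of the logistic edge model
#' `f(z) = a + b / (1 + exp(-s * c * (z - d)))` fitted to one rising or
#' falling flank of a depth profile; `d` is the inflection point and the
#' interface estimate, `s = +1` for a rising and `-1` for a falling edge.
#'
#' @slot a Baseline offset (normalized intensity).
#' @slot b Amplitude (normalized intensity).
#' @slot c Steepness (1/um), positive; the edge direction is in `edge`.
#' @slot d Inflection position (um).
#' @slot rss Residual sum of squares of the sigmoid fit.
#' @slot edge `"rising"` or `"falling"`.
#'
#' @seealso [fitSigmoid()]
#' @exportClass SigmoidFit
setClass("SigmoidFit",
    slots = c(a = "numeric", b = "numeric", c = "numeric", d = "numeric",
              rss = "numeric", edge = "character")
)

setValidity("SigmoidFit", function(object) {
    msg <- character()
    if (!object@edge %in% c("rising", "falling"))
        msg <- c(msg, "edge must be 'rising' or 'falling'")
    if (!is.finite(object@c) || object@c <= 0)
        msg <- c(msg, "steepness c must be positive")
    if (!is.finite(object@b) || object@b == 0)
        msg <- c(msg, "amplitude b must be nonzero")
    if (length(msg)) msg else TRUE
})

#' InterfaceSet: ordered material interfaces of a scan
#'
#' Interface depths of one depth profile, two per traversed layer (entry
#' and exit), each flagged by provenance (`"auto"` from sigmoid detection
#' or `"manual"`).
#'
#' @slot positions Numeric, strictly increasing interface depths (um).
#' @slot provenance Character, `"auto"` or `"manual"` per interface.
#' @slot nLayers Integer, declared number of traversed layers.
#' @slot zRange Numeric length-2, the scan range the positions must lie in.
#'
#' @seealso [detectInterfaces()], [setInterfaces()], [opticalThickness()]
#' @exportClass InterfaceSet
setClass("InterfaceSet",
    slots = c(positions = "numeric", provenance = "character",
              nLayers = "integer", zRange = "numeric")
)

setValidity("InterfaceSet", function(object) {
    msg <- character()
    p <- object@positions
    if (any(diff(p) <= 0))
        msg <- c(msg, "interface positions must be strictly increasing")
    if (length(p) != 2L * object@nLayers)
        msg <- c(msg, sprintf("expected %d interfaces (2 per layer), got %d",
                              2L * object@nLayers, length(p)))
    if (length(object@provenance) != length(p) ||
        !all(object@provenance %in% c("auto", "manual")))
        msg <- c(msg, "provenance must be 'auto'/'manual', one per interface")
    if (length(p) && (min(p) < object@zRange[1] || max(p) > object@zRange[2]))
        msg <- c(msg, "all interface positions must lie within the scan range")
    if (length(msg)) msg else TRUE
})

#' PSF: the axial point spread function of an objective
#'
#' Parameterized by its full width at half maximum; Lorentzian by default,
#' with a Gaussian alternative behind the `form` switch.
#'
#' @slot gamma FWHM (um), positive.
#' @slot form `"lorentzian"` (default) or `"gaussian"`.
#'
#' @seealso [PSF()], [lorentzianDensity()], [calibratePSF()]
#' @exportClass PSF
setClass("PSF", slots = c(gamma = "numeric", form = "character"))

setValidity("PSF", function(object) {
    msg <- character()
    if (!is.finite(object@gamma) || object@gamma <= 0)
        msg <- c(msg, "gamma (FWHM) must be positive")
    if (!object@form %in% c("lorentzian", "gaussian"))
        msg <- c(msg, "form must be 'lorentzian' or 'gaussian'")
    if (length(msg)) msg else TRUE
})

#' PSFCalibration: result of fitting a PSF to a thin-sample scan
#'
#' @slot psf The fitted [PSF-class].
#' @slot center Peak position (um).
#' @slot amplitude Fitted peak amplitude (normalized intensity).
#' @slot baseline Fitted constant background (normalized intensity).
#' @slot rss Residual sum of squares.
#' @slot thinSampleOK Logical; `FALSE` when the fitted FWHM exceeds half
#'   the scan span, i.e. the optically-thin assumption looks violated.
#'
#' @seealso [calibratePSF()]
#' @exportClass PSFCalibration
setClass("PSFCalibration",
    slots = c(psf = "PSF", center = "numeric", amplitude = "numeric",
              baseline = "numeric", rss = "numeric", thinSampleOK = "logical")
)

#' OpticsConfig: objective and immersion parameters
#'
#' Houses the quantities entering the analytic optics formulas: excitation
#' wavelength, numerical aperture, and the refractive indices of immersion
#' medium and sample. The immersion index enters the ideal confocal axial
#' FWHM; the sample index enters the refraction-based depth-of-focus
#' estimate and the paraxial thickness correction. They are kept as
#' separate fields.
#'
#' @slot wavelength Excitation wavelength (nm).
#' @slot numericalAperture NA of the objective (dimensionless).
#' @slot nImmersion Refractive index of the immersion medium.
#' @slot nSample Refractive index of the sample (`NA_real_` if unknown).
#'
#' @seealso [OpticsConfig()], [lateralFWHM()], [idealAxialFWHM()],
#'   [depthOfFocus()], [correctedThickness()]
#' @exportClass OpticsConfig
setClass("OpticsConfig",
    slots = c(wavelength = "numeric", numericalAperture = "numeric",
              nImmersion = "numeric", nSample = "numeric")
)

setValidity("OpticsConfig", function(object) {
    msg <- character()
    if (!is.finite(object@wavelength) || object@wavelength <= 0)
        msg <- c(msg, "wavelength must be positive")
    if (!is.finite(object@numericalAperture) || object@numericalAperture <= 0)
        msg <- c(msg, "numerical aperture must be positive")
    if (is.finite(object@nImmersion) &&
        object@numericalAperture > object@nImmersion)
        msg <- c(msg, "numerical aperture cannot exceed the immersion index")
    if (length(msg)) msg else TRUE
})

#' LayerModel: physical parameters of one layer in a through-plane scan
#'
#' The ideal (infinite-resolution) composition profile of a single layer is
#' a rectangle between the interfaces `z1 < z2`, with amplitude `h` at the
#' first interface decaying as `h * exp(-mu * (z - z1))` inside the layer
#' (Beer-Lambert attenuation). The imaging kernel is the axial PSF whose
#' FWHM grows linearly from `gamma1` at `z1` to `gamma2` at `z2` (clamped
#' outside). Optional background plateaus `topLevel` (above `z1`) and
#' `bottomLevel` (below `z2`) model uneven background; both default to 0.
#'
#' @slot z1,z2 Interface depths (um), `z1 < z2`.
#' @slot gamma1,gamma2 PSF FWHM at the first / second interface (um).
#' @slot mu Attenuation coefficient (1/um), non-negative.
#' @slot h Ideal-profile amplitude at the first interface (normalized).
#' @slot topLevel,bottomLevel Background plateaus (normalized), default 0.
#'
#' @seealso [LayerModel()], [gammaAt()], [idealProfile()], [convolveModel()]
#' @exportClass LayerModel
setClass("LayerModel",
    slots = c(z1 = "numeric", z2 = "numeric",
              gamma1 = "numeric", gamma2 = "numeric",
              mu = "numeric", h = "numeric",
              topLevel = "numeric", bottomLevel = "numeric")
)

setValidity("LayerModel", function(object) {
    msg <- character()
    if (!is.finite(object@z1) || !is.finite(object@z2) ||
        object@z2 <= object@z1)
        msg <- c(msg, "interfaces must satisfy z1 < z2")
    if (object@gamma1 <= 0 || object@gamma2 <= 0)
        msg <- c(msg, "gamma1 and gamma2 must be positive")
    if (object@mu < 0)
        msg <- c(msg, "mu must be non-negative")
    if (object@h <= 0)
        msg <- c(msg, "h must be positive")
    if (object@topLevel < 0 || object@bottomLevel < 0)
        msg <- c(msg, "background plateaus must be non-negative")
    if (length(msg)) msg else TRUE
})

#' ModelCurve: the forward model evaluated on a depth grid
#'
#' @slot z Evaluation grid (um).
#' @slot sModel Modeled intensity S(z) (normalized units).
#'
#' @seealso [convolveModel()]
#' @exportClass ModelCurve
setClass("ModelCurve", slots = c(z = "numeric", sModel = "numeric"))

setValidity("ModelCurve", function(object) {
    if (length(object@z) != length(object@sModel))
        "z and sModel must have equal length" else TRUE
})

#' SweepConfig: grid-sweep optimization settings
#'
#' Ranges and final-stage increments for the four swept parameters, the
#' number of coarse-to-fine stages and the per-stage contraction. Stage 1
#' uses increment `inc * shrink^(stages - 1)`; each later stage re-centers
#' the range on the incumbent optimum, divides its width by `shrink`, and
#' divides the increment by `shrink`, so the last stage runs at the quoted
#' (final) increments. Results are independent of `workers`.
#'
#' @slot gamma1Range,gamma2Range Numeric length-2, FWHM sweep ranges (um).
#' @slot gammaInc Final FWHM increment (um), default 0.1.
#' @slot muRange Numeric length-2, attenuation range (1/um).
#' @slot muInc Final attenuation increment (1/um).
#' @slot hRange Numeric length-2, amplitude range.
#' @slot hInc Final amplitude increment.
#' @slot stages Integer, number of refinement passes (>= 1).
#' @slot shrink Numeric, per-stage range/increment contraction factor.
#' @slot workers Integer, parallelism degree (deterministic contract).
#'
#' @seealso [SweepConfig()], [fitLayer()]
#' @exportClass SweepConfig
setClass("SweepConfig",
    slots = c(gamma1Range = "numeric", gamma2Range = "numeric",
              gammaInc = "numeric",
              muRange = "numeric", muInc = "numeric",
              hRange = "numeric", hInc = "numeric",
              stages = "integer", shrink = "numeric", workers = "integer")
)

setValidity("SweepConfig", function(object) {
    msg <- character()
    rng <- function(r) length(r) == 2L && all(is.finite(r)) && r[1] < r[2]
    if (!rng(object@gamma1Range) || !rng(object@gamma2Range) ||
        !rng(object@hRange))
        msg <- c(msg, "ranges must be finite length-2 with lo < hi")
    if (length(object@muRange) != 2L || object@muRange[1] < 0 ||
        object@muRange[2] <= object@muRange[1])
        msg <- c(msg, "muRange must be [lo, hi] with 0 <= lo < hi")
    if (object@gammaInc <= 0 || object@muInc <= 0 || object@hInc <= 0)
        msg <- c(msg, "all increments must be positive")
    if (object@stages < 1L)
        msg <- c(msg, "stages must be >= 1")
    if (object@shrink <= 1)
        msg <- c(msg, "shrink must be > 1")
    if (object@workers < 1L)
        msg <- c(msg, "workers must be >= 1")
    if (length(msg)) msg else TRUE
})

#' FitResult: optimal layer model with fit diagnostics
#'
#' @slot model The optimal [LayerModel-class].
#' @slot r2 Coefficient of determination of the fit.
#' @slot lsq Residual sum of squares at the optimum.
#' @slot curve [ModelCurve-class] at the optimum, on the profile grid.
#' @slot decayPerDistance `(gamma2 - gamma1) / t` (um per um).
#' @slot qcFlags Character vector of quality-control warnings.
#' @slot iterations Number of grid points evaluated.
#' @slot offset Fitted global additive offset of the model curve
#'   (normalized units); the arbitrary zero left by the min-max
#'   normalization of the data. 0 when background plateaus are enabled.
#' @slot stageLSQ Incumbent residual sum of squares after each stage.
#' @slot config The [SweepConfig-class] used.
#' @slot profile The fitted [DepthProfile-class].
#'
#' @seealso [fitLayer()], [qcEvaluate()], [descriptors()]
#' @exportClass FitResult
setClass("FitResult",
    slots = c(model = "LayerModel", r2 = "numeric", lsq = "numeric",
              curve = "ModelCurve", decayPerDistance = "numeric",
              qcFlags = "character", iterations = "numeric",
              offset = "numeric",
              stageLSQ = "numeric", config = "SweepConfig",
              profile = "DepthProfile")
)

#' StackSpec: declaration of a multilayer stack
#'
#' Ordered (by depth) layer labels with the sum-filter window of each
#' label's marker band. A label may repeat (e.g. the same polymer above
#' and below an interlayer); each occurrence is fit independently.
#'
#' @slot labels Character, layer labels in depth order.
#' @slot windows Named list of numeric length-2 wavenumber windows (1/cm),
#'   one per distinct label.
#' @slot manualInterfaces Named list (by depth-order index as character) of
#'   numeric length-2 manual interface pairs (um); empty for full auto.
#' @slot nSample Numeric, per-layer sample refractive index (`NA` allowed).
#'
#' @seealso [StackSpec()], [fitStack()], [splitComponents()]
#' @exportClass StackSpec
setClass("StackSpec",
    slots = c(labels = "character", windows = "list",
              manualInterfaces = "list", nSample = "numeric")
)

setValidity("StackSpec", function(object) {
    msg <- character()
    if (length(object@labels) < 1L)
        msg <- c(msg, "at least one layer required")
    if (!all(object@labels %in% names(object@windows)))
        msg <- c(msg, "every label needs a sum-filter window")
    bad <- vapply(object@windows, function(w)
        length(w) != 2L || !all(is.finite(w)) || w[1] >= w[2], logical(1))
    if (any(bad))
        msg <- c(msg, "windows must be finite [lo, hi] with lo < hi")
    if (length(object@nSample) != length(object@labels))
        msg <- c(msg, "nSample must have one entry per layer (NA allowed)")
    if (length(msg)) msg else TRUE
})

#' MultilayerResult: per-layer fits of a stack with continuity diagnostics
#'
#' @slot labels Character, layer labels in depth order.
#' @slot perLayer List of [FitResult-class], ordered by depth.
#' @slot continuity Numeric, per adjacent pair the absolute difference of
#'   the PSF FWHM reconstructed at the shared depth from the two layers
#'   (um). Reported, never enforced.
#'
#' @seealso [fitStack()]
#' @exportClass MultilayerResult
setClass("MultilayerResult",
    slots = c(labels = "character", perLayer = "list", continuity = "numeric")
)

#' SyntheticSpec: ground-truth description of a synthetic scan
#'
#' Drives the fixture generator: one or more true [LayerModel-class]s, the
#' scan geometry, the noise model and the RNG seed. A fixed seed makes the
#' output bitwise reproducible.
#'
#' @slot truth List of [LayerModel-class] (one per layer), depth-ordered.
#' @slot labels Character, one label per truth model (used by the
#'   hyperspectral renderer; a label may repeat).
#' @slot zRange Numeric length-2, scan range (um).
#' @slot stepSize Axial step (um).
#' @slot noiseSigma Additive Gaussian noise sd as a fraction of the peak.
#' @slot noiseModel `"gaussian"` (on the integrated profile) or
#'   `"poisson"` (on hyperspectral counts).
#' @slot seed Integer RNG seed.
#' @slot bands Named list (by label) of `c(center, width, amplitude)`
#'   Lorentzian band definitions (1/cm) for hyperspectral rendering.
#' @slot resolution Sub-grid spacing for the forward convolution (um);
#'   `NA_real_` means `stepSize / 8`.
#'
#' @seealso [SyntheticSpec()], [generateProfile()], [generateHyperspectral()]
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
    slots = c(truth = "list", labels = "character", zRange = "numeric",
              stepSize = "numeric", noiseSigma = "numeric",
              noiseModel = "character", seed = "integer",
              bands = "list", resolution = "numeric")
)

setValidity("SyntheticSpec", function(object) {
    msg <- character()
    if (!length(object@truth) ||
        !all(vapply(object@truth, is, logical(1), "LayerModel")))
        msg <- c(msg, "truth must be a non-empty list of LayerModel objects")
    if (length(object@labels) != length(object@truth))
        msg <- c(msg, "need one label per truth model")
    if (length(object@zRange) != 2L || object@zRange[1] >= object@zRange[2])
        msg <- c(msg, "zRange must be [lo, hi] with lo < hi")
    if (object@stepSize <= 0)
        msg <- c(msg, "stepSize must be positive")
    if (object@noiseSigma < 0)
        msg <- c(msg, "noiseSigma must be non-negative")
    if (!object@noiseModel %in% c("gaussian", "poisson"))
        msg <- c(msg, "noiseModel must be 'gaussian' or 'poisson'")
    if (length(msg)) msg else TRUE
})
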