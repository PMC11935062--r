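## Accessor generics and show methods. Slots are reached through accessors
## throughout the package and tests; direct @ access is internal only.

#' @rdname accessors
#' @export
setGeneric("zPositions", function(x) standardGeneric("zPositions"))
#' @rdname accessors
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("stepSize", function(x) standardGeneric("stepSize"))
#' @rdname accessors
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))
#' @rdname accessors
#' @export
setGeneric("backgroundLevels", function(x) standardGeneric("backgroundLevels"))
#' @rdname accessors
#' @export
setGeneric("interfacePositions",
    function(x) standardGeneric("interfacePositions"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("opticalThickness", function(x) standardGeneric("opticalThickness"))
#' @rdname accessors
#' @export
setGeneric("fwhm", function(x) standardGeneric("fwhm"))
#' @rdname accessors
#' @export
setGeneric("layerModel", function(x) standardGeneric("layerModel"))
#' @rdname accessors
#' @export
setGeneric("modelCurve", function(x) standardGeneric("modelCurve"))
#' @rdname accessors
#' @export
setGeneric("fitR2", function(x) standardGeneric("fitR2"))
#' @rdname accessors
#' @export
setGeneric("fitLSQ", function(x) standardGeneric("fitLSQ"))
#' @rdname accessors
#' @export
setGeneric("qcFlags", function(x) standardGeneric("qcFlags"))
#' @rdname accessors
#' @export
setGeneric("descriptors", function(x) standardGeneric("descriptors"))
#' @rdname accessors
#' @export
setGeneric("perLayer", function(x) standardGeneric("perLayer"))
#' @rdname accessors
#' @export
setGeneric("continuity", function(x) standardGeneric("continuity"))

#' Accessors for depthPSF classes
#'
#' Small read-only accessors for the package's S4 containers:
#' `zPositions()`, `wavenumbers()`, `intensities()` and `stepSize()` for
#' [SpectralScan-class]; `intensity()` and `backgroundLevels()` for
#' [DepthProfile-class]; `interfacePositions()`, `provenance()` and
#' `opticalThickness()` for [InterfaceSet-class]; `fwhm()` for
#' [PSF-class] and [PSFCalibration-class]; `layerModel()`, `modelCurve()`,
#' `fitR2()`, `fitLSQ()`, `qcFlags()` and `descriptors()` for
#' [FitResult-class]; `perLayer()` and `continuity()` for
#' [MultilayerResult-class].
#'
#' `opticalThickness()` returns, per traversed layer, the difference of the
#' consecutive interface pair (exit minus entry depth), i.e. the apparent
#' thickness read from the scan before any refractive-index correction.
#'
#' `descriptors()` returns the named numeric vector
#' `c(fwhm1, fwhm2, decayPerDistance, mu, h, t, r2)`: the PSF FWHM at the
#' two interfaces (um), the resolution decay per distance (um/um), the
#' attenuation coefficient (1/um), the ideal-profile amplitude, the optical
#' thickness (um) and the coefficient of determination.
#'
#' @param x An object of the documented class.
#' @return The slot value (or derived quantity) described above.
#' @name accessors
#' @aliases zPositions wavenumbers intensities stepSize intensity
#'   backgroundLevels interfacePositions provenance opticalThickness fwhm
#'   layerModel modelCurve fitR2 fitLSQ qcFlags descriptors perLayer
#'   continuity
NULL

#' @rdname accessors
#' @export
setMethod("zPositions", "SpectralScan", function(x) x@z)
#' @rdname accessors
#' @export
setMethod("zPositions", "DepthProfile", function(x) x@z)
#' @rdname accessors
#' @export
setMethod("zPositions", "ModelCurve", function(x) x@z)
#' @rdname accessors
#' @export
setMethod("wavenumbers", "SpectralScan", function(x) x@wavenumbers)
#' @rdname accessors
#' @export
setMethod("intensities", "SpectralScan", function(x) x@intensities)
#' @rdname accessors
#' @export
setMethod("stepSize", "SpectralScan", function(x) x@stepSize)
#' @rdname accessors
#' @export
setMethod("stepSize", "DepthProfile", function(x) x@stepSize)
#' @rdname accessors
#' @export
setMethod("intensity", "DepthProfile", function(x) x@intensity)
#' @rdname accessors
#' @export
setMethod("intensity", "ModelCurve", function(x) x@sModel)
#' @rdname accessors
#' @export
setMethod("backgroundLevels", "DepthProfile",
    function(x) c(top = x@topLevel, bottom = x@bottomLevel))
#' @rdname accessors
#' @export
setMethod("interfacePositions", "InterfaceSet", function(x) x@positions)
#' @rdname accessors
#' @export
setMethod("provenance", "InterfaceSet", function(x) x@provenance)
#' @rdname accessors
#' @export
setMethod("opticalThickness", "InterfaceSet", function(x) {
    p <- x@positions
    p[seq(2L, length(p), by = 2L)] - p[seq(1L, length(p), by = 2L)]
})
#' @rdname accessors
#' @export
setMethod("opticalThickness", "LayerModel", function(x) x@z2 - x@z1)
#' @rdname accessors
#' @export
setMethod("opticalThickness", "FitResult",
    function(x) opticalThickness(x@model))
#' @rdname accessors
#' @export
setMethod("fwhm", "PSF", function(x) x@gamma)
#' @rdname accessors
#' @export
setMethod("fwhm", "PSFCalibration", function(x) x@psf@gamma)
#' @rdname accessors
#' @export
setMethod("layerModel", "FitResult", function(x) x@model)
#' @rdname accessors
#' @export
setMethod("modelCurve", "FitResult", function(x) x@curve)
#' @rdname accessors
#' @export
setMethod("fitR2", "FitResult", function(x) x@r2)
#' @rdname accessors
#' @export
setMethod("fitLSQ", "FitResult", function(x) x@lsq)
#' @rdname accessors
#' @export
setMethod("qcFlags", "FitResult", function(x) x@qcFlags)
#' @rdname accessors
#' @export
setMethod("descriptors", "FitResult", function(x) {
    m <- x@model
    c(fwhm1 = m@gamma1, fwhm2 = m@gamma2,
      decayPerDistance = x@decayPerDistance,
      mu = m@mu, h = m@h, t = m@z2 - m@z1, r2 = x@r2)
})
#' @rdname accessors
#' @export
setMethod("perLayer", "MultilayerResult", function(x) x@perLayer)
#' @rdname accessors
#' @export
setMethod("continuity", "MultilayerResult", function(x) x@continuity)

setMethod("show", "SpectralScan", function(object) {
    cat(sprintf(
        "SpectralScan: %d z positions (%.3f..%.3f um, step %.4g um), %d wavenumbers (%.1f..%.1f 1/cm)\n",
        length(object@z), min(object@z), max(object@z), object@stepSize,
        length(object@wavenumbers), min(object@wavenumbers),
        max(object@wavenumbers)))
    if (length(object@meta) && nzchar(object@meta[1]))
        cat("  meta:", object@meta[1], "\n")
})

setMethod("show", "DepthProfile", function(object) {
    cat(sprintf(
        "DepthProfile: %d points, z %.3f..%.3f um (step %.4g um), normalized [0, 1]\n",
        length(object@z), min(object@z), max(object@z), object@stepSize))
    cat(sprintf("  raw range: [%.6g, %.6g] counts\n",
                object@rawMin, object@rawMax))
    if (is.finite(object@topLevel))
        cat(sprintf("  background plateaus: top %.4g, bottom %.4g\n",
                    object@topLevel, object@bottomLevel))
})

setMethod("show", "SigmoidFit", function(object) {
    cat(sprintf(
        "SigmoidFit (%s edge): d = %.4f um, a = %.4f, b = %.4f, c = %.4f 1/um, rss = %.3g\n",
        object@edge, object@d, object@a, object@b, object@c, object@rss))
})

setMethod("show", "InterfaceSet", function(object) {
    cat(sprintf("InterfaceSet: %d interfaces (%d layer(s))\n",
                length(object@positions), object@nLayers))
    cat("  positions (um):",
        paste(sprintf("%.3f [%s]", object@positions, object@provenance),
              collapse = ", "), "\n")
    cat("  optical thickness (um):",
        paste(sprintf("%.3f", opticalThickness(object)), collapse = ", "),
        "\n")
})

setMethod("show", "PSF", function(object) {
    cat(sprintf("PSF: %s, FWHM %.4g um\n", object@form, object@gamma))
})

setMethod("show", "PSFCalibration", function(object) {
    cat(sprintf(
        "PSFCalibration: %s FWHM %.4g um at z = %.3f um (amplitude %.3g, baseline %.3g)\n",
        object@psf@form, object@psf@gamma, object@center, object@amplitude,
        object@baseline))
    if (!object@thinSampleOK)
        cat("  warning: thin-sample assumption looks violated\n")
})

setMethod("show", "LayerModel", function(object) {
    cat(sprintf(
        "LayerModel: z1 = %.3f, z2 = %.3f um (t = %.3f um)\n  gamma1 = %.3f, gamma2 = %.3f um; mu = %.5g 1/um; h = %.4f\n",
        object@z1, object@z2, object@z2 - object@z1,
        object@gamma1, object@gamma2, object@mu, object@h))
    if (object@topLevel > 0 || object@bottomLevel > 0)
        cat(sprintf("  background plateaus: top %.4g, bottom %.4g\n",
                    object@topLevel, object@bottomLevel))
})

setMethod("show", "FitResult", function(object) {
    d <- descriptors(object)
    cat("FitResult\n")
    cat(sprintf("  FWHM first interface : %.3f um\n", d[["fwhm1"]]))
    cat(sprintf("  FWHM second interface: %.3f um\n", d[["fwhm2"]]))
    cat(sprintf("  resolution decay     : %.4f um/um\n",
                d[["decayPerDistance"]]))
    cat(sprintf("  attenuation mu       : %.4g 1/um\n", d[["mu"]]))
    cat(sprintf("  optical thickness    : %.3f um\n", d[["t"]]))
    cat(sprintf("  R^2 = %.6f (LSQ = %.4g), %g grid points evaluated\n",
                object@r2, object@lsq, object@iterations))
    if (length(object@qcFlags))
        cat("  QC flags:", paste(object@qcFlags, collapse = ", "), "\n")
})

setMethod("show", "MultilayerResult", function(object) {
    cat(sprintf("MultilayerResult: %d layers (%s)\n",
                length(object@perLayer),
                paste(object@labels, collapse = " / ")))
    for (i in seq_along(object@perLayer)) {
        if (!is(object@perLayer[[i]], "FitResult")) {
            cat(sprintf("  [%d] %-8s %s\n", i, object@labels[i],
                        as.character(object@perLayer[[i]])))
            next
        }
        d <- descriptors(object@perLayer[[i]])
        cat(sprintf(
            "  [%d] %-8s FWHM %.2f -> %.2f um, decay %.3f um/um, mu %.4g 1/um, R^2 %.4f\n",
            i, object@labels[i], d[["fwhm1"]], d[["fwhm2"]],
            d[["decayPerDistance"]], d[["mu"]], d[["r2"]]))
    }
    if (length(object@continuity))
        cat("  continuity at shared interfaces (um):",
            paste(sprintf("%.3f", object@continuity), collapse = ", "), "\n")
})

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf(
        "SyntheticSpec: %d layer(s), z %.2f..%.2f um, step %.4g um, noise %.3g, seed %d (%s render)\n",
        length(object@truth), object@zRange[1], object@zRange[2],
        object@stepSize, object@noiseSigma, object@seed,
        if (length(object@bands)) "hyperspectral-capable" else "profile"))
})
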