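## Synthetic through-plane scans with known ground truth.
##
## Profiles are rendered by forward-evaluating the convolution model on
## the scan grid, adding noise and min-max normalizing, exactly the
## statistical structure the fitter assumes: a rectangular layer profile
## of stated thickness with exponential decay, blurred by a Lorentzian
## PSF whose FWHM grows linearly between the interfaces, plus additive
## Gaussian noise and optional background plateaus. Hyperspectral
## rendering multiplies each label's depth profile with a synthetic
## Lorentzian band so the sum-filter path can be exercised end to end.
## The generator deliberately does not simulate refraction or diffraction:
## fixtures come from the model itself, which is the correct oracle for
## the fitter.

#' Construct a SyntheticSpec
#'
#' @param truth A [LayerModel-class] or list of them (depth-ordered).
#' @param zRange Scan range (um); typically about twice the layer
#'   thickness, the layer roughly centered.
#' @param stepSize Axial step (um).
#' @param noiseSigma Additive Gaussian noise sd as a fraction of the
#'   noiseless peak (default 0).
#' @param seed Integer RNG seed; fixed seed means bitwise-reproducible
#'   output.
#' @param labels One label per truth model (default `"layer1"`,
#'   `"layer2"`, ...; repeat a label for a repeated material).
#' @param bands Named list (by label) of `c(center, width, amplitude)`
#'   Lorentzian band definitions (1/cm) for hyperspectral rendering.
#' @param noiseModel `"gaussian"` (additive, on the integrated profile or
#'   on hyperspectral counts) or `"poisson"` (hyperspectral counts with
#'   relative noise `noiseSigma` at the peak).
#' @param resolution Forward-convolution sub-cell spacing (um);
#'   `NA` means `stepSize / 8`.
#' @return A validated [SyntheticSpec-class].
#' @export
#' @examples
#' SyntheticSpec(LayerModel(14.5, 43.5, 1.5, 1.5, mu = 0, h = 1.2),
#'               zRange = c(0, 58), stepSize = 0.666, noiseSigma = 0.01,
#'               seed = 1L)
SyntheticSpec <- function(truth, zRange, stepSize, noiseSigma = 0,
                          seed = 1L, labels = NULL, bands = list(),
                          noiseModel = "gaussian", resolution = NA_real_) {
    if (is(truth, "LayerModel"))
        truth <- list(truth)
    if (is.null(labels))
        labels <- paste0("layer", seq_along(truth))
    new("SyntheticSpec", truth = truth, labels = as.character(labels),
        zRange = as.numeric(zRange), stepSize = as.numeric(stepSize),
        noiseSigma = as.numeric(noiseSigma),
        noiseModel = noiseModel, seed = as.integer(seed),
        bands = bands, resolution = as.numeric(resolution))
}

synthGrid <- function(spec) {
    seq(spec@zRange[1], spec@zRange[2], by = spec@stepSize)
}

synthResolution <- function(spec) {
    if (is.finite(spec@resolution)) spec@resolution else spec@stepSize / 8
}

## Noiseless forward curve of a subset of the truth models (sum of their
## convolved contributions; the convolution is linear in the ideal
## profile).
synthCurve <- function(spec, which = seq_along(spec@truth)) {
    zgrid <- synthGrid(spec)
    res <- synthResolution(spec)
    s <- numeric(length(zgrid))
    for (i in which)
        s <- s + convolveModel(spec@truth[[i]], zgrid, res)@sModel
    s
}

#' Generate a synthetic depth profile with ground truth
#'
#' Renders the noiseless forward curve on the scan grid, adds Gaussian
#' noise of sd `noiseSigma * peak`, and min-max normalizes. The returned
#' truth record maps the generating parameters to their
#' post-normalization equivalents: interface positions, FWHMs and the
#' attenuation coefficient are unchanged; the amplitude becomes
#' `h / (max - min)` of the pre-normalization signal (exact when the
#' signal floor is zero, which holds for baseline-free truths up to
#' noise).
#'
#' @param spec A [SyntheticSpec-class].
#' @return List with `profile` (a [DepthProfile-class]) and `truth`
#'   (list: `models` = normalized [LayerModel-class]s, `labels`, `scale`,
#'   `offset`, `peak`, `seed`, `noiseSigma`).
#' @export
generateProfile <- function(spec) {
    stopifnot(is(spec, "SyntheticSpec"))
    s <- synthCurve(spec)
    y <- if (spec@noiseSigma > 0) {
        withSeed(spec@seed,
                 s + stats::rnorm(length(s), 0,
                                  spec@noiseSigma * max(s)))
    } else s
    lo <- min(y)
    hi <- max(y)
    scale <- hi - lo
    models <- lapply(spec@truth, function(m)
        LayerModel(m@z1, m@z2, m@gamma1, m@gamma2, m@mu,
                   h = m@h / scale,
                   topLevel = if (m@topLevel > 0)
                       (m@topLevel - lo) / scale else 0,
                   bottomLevel = if (m@bottomLevel > 0)
                       (m@bottomLevel - lo) / scale else 0))
    list(profile = DepthProfile(z = synthGrid(spec), intensity = y),
         truth = list(models = models, labels = spec@labels,
                      scale = scale, offset = lo, peak = hi,
                      seed = spec@seed, noiseSigma = spec@noiseSigma))
}

## Peak-normalized Lorentzian band shape on the wavenumber axis.
bandShape <- function(w, center, width, amplitude) {
    hw <- width / 2
    amplitude * hw^2 / ((w - center)^2 + hw^2)
}

#' Generate a synthetic hyperspectral scan
#'
#' Each z row is the sum over labels of the label's noiseless depth
#' weight (the convolved ideal profile of its layers) times a synthetic
#' Lorentzian band, plus noise. Applying [sumFilter()] over a label's
#' band window recovers that label's [generateProfile()] output up to
#' noise (exactly, at zero noise and non-overlapping bands). Overlapping
#' bands are allowed but warned about; they emulate the spectral-overlap
#' artifact of an immersion medium sharing bands with the sample.
#'
#' @param spec A [SyntheticSpec-class] with a band definition per label.
#' @param wavenumberStep Spectral axis spacing (1/cm), default 1.
#' @return A [SpectralScan-class].
#' @export
generateHyperspectral <- function(spec, wavenumberStep = 1) {
    stopifnot(is(spec, "SyntheticSpec"))
    labs <- unique(spec@labels)
    if (!all(labs %in% names(spec@bands)))
        stop("every label needs a band definition for hyperspectral rendering")
    bands <- spec@bands[labs]
    centers <- vapply(bands, `[`, numeric(1), 1)
    widths <- vapply(bands, `[`, numeric(1), 2)
    if (length(labs) > 1L) {
        for (i in seq_len(length(labs) - 1L)) {
            for (j in seq(i + 1L, length(labs))) {
                if (abs(centers[i] - centers[j]) <
                    3 * (widths[i] + widths[j]))
                    warning(sprintf(
                        "bands of '%s' and '%s' overlap; sum filters over either window will mix both signals",
                        labs[i], labs[j]))
            }
        }
    }
    w <- seq(min(centers - 8 * widths), max(centers + 8 * widths),
             by = wavenumberStep)
    zgrid <- synthGrid(spec)
    m <- matrix(0, length(zgrid), length(w))
    for (l in labs) {
        weight <- synthCurve(spec, which(spec@labels == l))
        b <- bandShape(w, bands[[l]][1], bands[[l]][2], bands[[l]][3])
        m <- m + outer(weight, b)
    }
    if (spec@noiseSigma > 0) {
        m <- withSeed(spec@seed, {
            if (spec@noiseModel == "poisson") {
                cts <- m / max(m) / spec@noiseSigma^2
                matrix(stats::rpois(length(cts), cts) *
                           max(m) * spec@noiseSigma^2,
                       nrow(m), ncol(m))
            } else {
                m + stats::rnorm(length(m), 0, spec@noiseSigma * max(m))
            }
        })
    }
    SpectralScan(z = zgrid, wavenumbers = w, intensities = m,
                 meta = "synthetic")
}

#' Write a synthetic fixture with its ground-truth sidecar
#'
#' Writes the rendered fixture in the requested reader dialect plus a
#' key-value truth file (`<name>.truth.txt`) recording the generating
#' parameters.
#'
#' @param spec A [SyntheticSpec-class].
#' @param dir Output directory (created if missing).
#' @param name Base file name.
#' @param dialect `"profile"`, `"matrix"` or `"long"` (the latter two
#'   render hyperspectral and need band definitions).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeSyntheticFixture <- function(spec, dir, name = "synthetic",
                                  dialect = c("profile", "matrix",
                                              "long")) {
    stopifnot(is(spec, "SyntheticSpec"))
    dialect <- match.arg(dialect)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    dataPath <- file.path(dir, paste0(
        name, if (dialect == "profile") ".profile.csv" else
            paste0(".", dialect, ".csv")))
    if (dialect == "profile") {
        writeProfile(generateProfile(spec)$profile, dataPath)
    } else {
        writeScan(generateHyperspectral(spec), dataPath, dialect)
    }
    truthPath <- file.path(dir, paste0(name, ".truth.txt"))
    lines <- c(sprintf("seed: %d", spec@seed),
               sprintf("step_size_um: %.6g", spec@stepSize),
               sprintf("noise_sigma: %.6g", spec@noiseSigma),
               sprintf("z_range_um: %.6g %.6g", spec@zRange[1],
                       spec@zRange[2]))
    for (i in seq_along(spec@truth)) {
        m <- spec@truth[[i]]
        lines <- c(lines, sprintf(
            "layer_%d: label=%s z1=%.6g z2=%.6g gamma1=%.6g gamma2=%.6g mu=%.6g h=%.6g",
            i, spec@labels[i], m@z1, m@z2, m@gamma1, m@gamma2, m@mu, m@h))
    }
    writeLines(lines, truthPath)
    invisible(c(data = dataPath, truth = truthPath))
}
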