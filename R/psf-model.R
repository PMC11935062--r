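## The axial point spread function and the analytic optics formulas.
##
## The axial PSF of the confocal system is modeled as a unit-area
## Lorentzian parameterized by its FWHM gamma,
##     L(z) = (1/pi) * (gamma/2) / (z^2 + (gamma/2)^2),
## calibrated by scanning an optically thin sample (a layer much thinner
## than the diffraction limit), whose through-plane profile reads out the
## PSF directly. A Gaussian alternative sits behind the `form` switch; the
## Lorentzian is the default because it describes the calibration scans of
## typical confocal Raman systems best.

#' Construct a PSF
#'
#' @param gamma FWHM (um), positive.
#' @param form `"lorentzian"` (default) or `"gaussian"`.
#' @return A validated [PSF-class].
#' @export
#' @examples
#' PSF(0.9)
PSF <- function(gamma, form = c("lorentzian", "gaussian")) {
    new("PSF", gamma = as.numeric(gamma), form = match.arg(form))
}

#' Construct an OpticsConfig
#'
#' @param wavelength Excitation wavelength (nm).
#' @param numericalAperture NA of the objective.
#' @param nImmersion Refractive index of the immersion medium.
#' @param nSample Refractive index of the sample (optional).
#' @return A validated [OpticsConfig-class].
#' @export
#' @examples
#' OpticsConfig(532, 0.9, nImmersion = 1.0, nSample = 1.58)
OpticsConfig <- function(wavelength, numericalAperture,
                         nImmersion = NA_real_, nSample = NA_real_) {
    new("OpticsConfig", wavelength = as.numeric(wavelength),
        numericalAperture = as.numeric(numericalAperture),
        nImmersion = as.numeric(nImmersion), nSample = as.numeric(nSample))
}

#' Lorentzian PSF density
#'
#' `L(z) = (1/pi) (gamma/2) / (z^2 + (gamma/2)^2)`, normalized to unit
#' integral over the real line; `L(gamma/2) = L(0)/2` by the FWHM
#' definition.
#'
#' @param z Axial offset from the kernel center (um); vectorized.
#' @param gamma FWHM (um), positive.
#' @return Density values (1/um).
#' @export
#' @examples
#' lorentzianDensity(0, 1)  # peak value 2/pi
lorentzianDensity <- function(z, gamma) {
    if (!is.finite(gamma) || gamma <= 0)
        stop("gamma must be positive")
    g2 <- gamma / 2
    (1 / pi) * g2 / (z^2 + g2^2)
}

#' Gaussian PSF density
#'
#' Unit-area Gaussian parameterized by its FWHM
#' (`sd = gamma / (2 sqrt(2 log 2))`); the alternative PSF form.
#'
#' @inheritParams lorentzianDensity
#' @return Density values (1/um).
#' @export
gaussianDensity <- function(z, gamma) {
    if (!is.finite(gamma) || gamma <= 0)
        stop("gamma must be positive")
    stats::dnorm(z, sd = gamma / (2 * sqrt(2 * log(2))))
}

#' Kernel mass of the Lorentzian PSF by windowed quadrature
#'
#' Integrates the Lorentzian density numerically (midpoint rule) over
#' `[-halfWidthFWHM * gamma, +halfWidthFWHM * gamma]` and adds the
#' closed-form arctangent tail mass
#' `2 * (1/2 - atan(2 W / gamma) / pi)` beyond the window. The total is 1
#' up to quadrature error; used as a self-check of the kernel
#' normalization underlying the forward model.
#'
#' @param gamma FWHM (um).
#' @param halfWidthFWHM Window half-width in units of the FWHM (default
#'   40).
#' @param n Number of midpoint cells (default 100000).
#' @return List with `numeric` (windowed quadrature), `tail` (analytic
#'   tail mass) and `total` (their sum).
#' @export
#' @examples
#' psfKernelMass(1)$total  # 1 within quadrature error
psfKernelMass <- function(gamma, halfWidthFWHM = 40, n = 1e5) {
    if (!is.finite(gamma) || gamma <= 0)
        stop("gamma must be positive")
    W <- halfWidthFWHM * gamma
    width <- 2 * W / n
    mids <- seq(-W + width / 2, W - width / 2, length.out = n)
    numeric <- sum(lorentzianDensity(mids, gamma)) * width
    tail <- 2 * (0.5 - atan(2 * W / gamma) / pi)
    list(numeric = numeric, tail = tail, total = numeric + tail)
}

#' Calibrate the axial PSF on an optically thin sample
#'
#' Jointly fits amplitude, center, constant baseline and FWHM of
#' `amplitude * density(z - center; gamma) + baseline` to the depth
#' profile of an optically thin sample; the fitted FWHM is the objective's
#' diffraction-limited axial resolution. The result is invariant under
#' positive rescaling of the profile intensity. When the fitted FWHM
#' exceeds half the scan span, a warning reports that the thin-sample
#' assumption looks violated (and `thinSampleOK` is `FALSE`).
#'
#' @param profile A [DepthProfile-class] from a thin-sample scan.
#' @param form PSF form, `"lorentzian"` (default) or `"gaussian"`.
#' @return A [PSFCalibration-class].
#' @export
calibratePSF <- function(profile, form = c("lorentzian", "gaussian")) {
    stopifnot(is(profile, "DepthProfile"))
    form <- match.arg(form)
    z <- profile@z
    y <- profile@intensity
    dens <- if (form == "lorentzian") lorentzianDensity else gaussianDensity
    peakIdx <- which.max(y)
    z0 <- z[peakIdx]
    half <- min(y) + (max(y) - min(y)) / 2
    above <- y >= half
    g0 <- max(diff(range(z[above])), 2 * profile@stepSize)
    a0 <- (max(y) - min(y)) / dens(0, g0)
    dat <- data.frame(z = z, y = y)
    fit <- minpack.lm::nlsLM(
        y ~ amp * dens(z - center, gamma) + base,
        data = dat,
        start = list(amp = a0, center = z0, gamma = g0, base = min(y)),
        lower = c(amp = 1e-12, center = min(z), gamma = 1e-4, base = -Inf),
        upper = c(amp = Inf, center = max(z), gamma = Inf, base = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500))
    p <- stats::coef(fit)
    span <- max(z) - min(z)
    ok <- p[["gamma"]] <= span / 2
    if (!ok)
        warning(sprintf(
            "fitted FWHM (%.3g um) exceeds half the scan span (%.3g um): the thin-sample assumption looks violated",
            p[["gamma"]], span))
    new("PSFCalibration",
        psf = PSF(p[["gamma"]], form), center = unname(p[["center"]]),
        amplitude = unname(p[["amp"]]), baseline = unname(p[["base"]]),
        rss = sum(stats::resid(fit)^2), thinSampleOK = ok)
}

#' Diffraction-limited lateral resolution
#'
#' Rayleigh-type criterion for a confocal microscope:
#' `FWHM_lateral = 0.4 lambda / NA`.
#'
#' @param cfg An [OpticsConfig-class].
#' @return Lateral FWHM (um).
#' @export
#' @examples
#' lateralFWHM(OpticsConfig(532, 0.9))  # 0.2364 um
lateralFWHM <- function(cfg) {
    stopifnot(is(cfg, "OpticsConfig"))
    0.4 * (cfg@wavelength / 1000) / cfg@numericalAperture
}

#' Ideal confocal axial resolution
#'
#' For an ideal confocal microscope with infinitely small pinhole:
#' `FWHM_axial = 0.64 lambda / (n - sqrt(n^2 - NA^2))`, with `n` the
#' immersion-medium index. Real systems with a finite pinhole resolve
#' worse; this is the theoretical floor.
#'
#' @param cfg An [OpticsConfig-class] with `nImmersion` set and
#'   `NA <= nImmersion`.
#' @return Axial FWHM (um).
#' @export
#' @examples
#' idealAxialFWHM(OpticsConfig(532, 0.9, nImmersion = 1.0))  # 0.603 um
idealAxialFWHM <- function(cfg) {
    stopifnot(is(cfg, "OpticsConfig"))
    n <- cfg@nImmersion
    na <- cfg@numericalAperture
    if (!is.finite(n))
        stop("nImmersion must be set")
    if (na > n)
        stop("numerical aperture must not exceed the immersion index")
    0.64 * (cfg@wavelength / 1000) / (n - sqrt(n^2 - na^2))
}

#' Refraction-based depth of focus
#'
#' Distance between the marginal- and paraxial-ray foci created by
#' refraction at an index-mismatched interface (air-objective form, valid
#' for `NA < 1`):
#' `dof = (sqrt(NA^2 (n^2 - 1) / (1 - NA^2) + n^2) - n) * z0`,
#' with `n` the sample index and `z0` the nominal focus depth. Linear in
#' `z0` and zero for `n = 1`. Exposed as a diagnostic only: it
#' overestimates the depth of focus because it neglects the confocal
#' aperture, and it is never used inside the fit.
#'
#' @param cfg An [OpticsConfig-class] with `nSample` set and `NA < 1`.
#' @param z0 Nominal focus depth(s) (um), >= 0; vectorized.
#' @return Depth of focus (um).
#' @export
depthOfFocus <- function(cfg, z0) {
    stopifnot(is(cfg, "OpticsConfig"))
    na <- cfg@numericalAperture
    n <- cfg@nSample
    if (!is.finite(n))
        stop("nSample must be set")
    if (na >= 1)
        stop("the refraction-based depth-of-focus formula is only valid for NA < 1 (air objective)")
    if (any(z0 < 0))
        stop("z0 must be non-negative")
    (sqrt(na^2 * (n^2 - 1) / (1 - na^2) + n^2) - n) * z0
}

#' Paraxial depth correction
#'
#' First-order mapping between the mechanical stage displacement `z0` and
#' the true focal depth under refractive index mismatch:
#' `z_focus = delta_n * z0`, with `delta_n` the sample/immersion index
#' ratio. Converts measured optical thickness to geometric thickness.
#'
#' @param z0 Nominal depth(s) (um), >= 0; vectorized.
#' @param deltaN Refractive index ratio sample / immersion, > 0.
#' @return Corrected depth(s) (um).
#' @export
#' @examples
#' paraxialCorrectedDepth(13.5, 1.58)  # 21.33 um
paraxialCorrectedDepth <- function(z0, deltaN) {
    if (any(z0 < 0))
        stop("z0 must be non-negative")
    if (!is.finite(deltaN) || deltaN <= 0)
        stop("deltaN must be positive")
    deltaN * z0
}

#' Write a PSF calibration report
#'
#' Small key-value text report of a thin-sample calibration.
#'
#' @param calibration A [PSFCalibration-class].
#' @param path Output path.
#' @param label Objective label.
#' @param cfg Optional [OpticsConfig-class] whose wavelength / NA are
#'   included.
#' @return `path`, invisibly.
#' @export
exportCalibration <- function(calibration, path, label = "",
                              cfg = NULL) {
    stopifnot(is(calibration, "PSFCalibration"))
    lines <- c(
        paste0("objective: ", label),
        paste0("psf_form: ", calibration@psf@form),
        sprintf("fwhm_um: %.6g", calibration@psf@gamma),
        sprintf("center_um: %.6g", calibration@center),
        sprintf("baseline: %.6g", calibration@baseline),
        sprintf("thin_sample_ok: %s", calibration@thinSampleOK))
    if (!is.null(cfg)) {
        lines <- c(lines,
                   sprintf("wavelength_nm: %.6g", cfg@wavelength),
                   sprintf("numerical_aperture: %.6g",
                           cfg@numericalAperture))
    }
    writeLines(lines, path)
    invisible(path)
}
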