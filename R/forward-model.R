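## The forward model: ideal layer profile with Beer-Lambert decay,
## convolved with an axial PSF whose FWHM grows linearly between the
## interfaces,
##     S(z) = integral rect(y; z1, z2) h exp(-mu (y - z1)) L(z - y; gamma(z)) dy
## (+ optional constant background plateaus outside the layer). The kernel
## FWHM depends on the evaluation point z, not on the integration variable.
##
## Numerics: the layer is split into uniform sub-cells; the decaying ideal
## profile is taken at each cell midpoint while the kernel mass per cell is
## integrated in closed form with the arctangent antiderivative of the
## Lorentzian. Together with the analytic plateau terms the total kernel
## mass is exactly 1, so truncation cannot bias h or mu; the only
## discretization error is the midpoint approximation of exp(-mu y) within
## a cell, which is O(resolution^2 mu^2).

#' Construct a LayerModel
#'
#' @param z1,z2 Interface depths (um), `z1 < z2`.
#' @param gamma1,gamma2 PSF FWHM at the first / second interface (um).
#' @param mu Attenuation coefficient (1/um), >= 0.
#' @param h Ideal-profile amplitude at the first interface.
#' @param topLevel,bottomLevel Optional background plateaus above z1 /
#'   below z2 (normalized units), default 0 (off).
#' @return A validated [LayerModel-class].
#' @export
#' @examples
#' LayerModel(5, 19, gamma1 = 0.9, gamma2 = 3.9, mu = 0.0945, h = 1.2)
LayerModel <- function(z1, z2, gamma1, gamma2, mu = 0, h = 1,
                       topLevel = 0, bottomLevel = 0) {
    new("LayerModel", z1 = as.numeric(z1), z2 = as.numeric(z2),
        gamma1 = as.numeric(gamma1), gamma2 = as.numeric(gamma2),
        mu = as.numeric(mu), h = as.numeric(h),
        topLevel = as.numeric(topLevel),
        bottomLevel = as.numeric(bottomLevel))
}

#' PSF FWHM at a given depth
#'
#' Linear interpolation between `gamma1` at the first and `gamma2` at the
#' second interface; clamped to the boundary values outside `[z1, z2]`
#' (the linear growth is defined between the interfaces only; clamping is
#' the minimal extension and keeps the immersion-side resolution at the
#' calibrated value).
#'
#' @param z Depth(s) (um); vectorized.
#' @param model A [LayerModel-class].
#' @return FWHM value(s) (um).
#' @export
gammaAt <- function(z, model) {
    stopifnot(is(model, "LayerModel"))
    frac <- (z - model@z1) / (model@z2 - model@z1)
    frac <- pmin(pmax(frac, 0), 1)
    model@gamma1 + (model@gamma2 - model@gamma1) * frac
}

#' Ideal (infinite-resolution) composition profile
#'
#' `h * exp(-mu * (z - z1))` inside the layer; `topLevel` above `z1` and
#' `bottomLevel` below `z2` outside (both 0 unless background modeling is
#' enabled). The decay argument is the depth below the first interface, so
#' `h` is the ideal intensity at the first interface.
#'
#' @param z Depth(s) (um); vectorized.
#' @param model A [LayerModel-class].
#' @return Ideal intensity value(s) (normalized units).
#' @export
idealProfile <- function(z, model) {
    stopifnot(is(model, "LayerModel"))
    out <- numeric(length(z))
    inside <- z >= model@z1 & z <= model@z2
    out[inside] <- model@h * exp(-model@mu * (z[inside] - model@z1))
    out[z < model@z1] <- model@topLevel
    out[z > model@z2] <- model@bottomLevel
    out
}

## CDF of the unit-area axial kernel centered at 0: the arctangent
## antiderivative for the Lorentzian, the error function for the Gaussian.
kernelCDF <- function(u, gamma, form = "lorentzian") {
    if (form == "lorentzian") 0.5 + atan(2 * u / gamma) / pi
    else stats::pnorm(u, sd = gamma / (2 * sqrt(2 * log(2))))
}

## Antiderivatives of u * kernel(u) and u^2 * kernel(u) for the
## unit-FWHM kernel (gamma = 1); both scale as gamma and gamma^2 when the
## offsets are expressed in FWHM units. They power the per-cell linear
## and quadratic corrections of the ideal profile, which make the cell
## quadrature exact for locally parabolic integrands.
kernelM1Antideriv <- function(v, form = "lorentzian") {
    if (form == "lorentzian") {
        log(v^2 + 0.25) / (4 * pi)
    } else {
        sigma <- 1 / (2 * sqrt(2 * log(2)))
        -sigma^2 * stats::dnorm(v, 0, sigma)
    }
}

kernelM2Antideriv <- function(v, form = "lorentzian", cdf = NULL) {
    if (form == "lorentzian") {
        if (is.null(cdf)) cdf <- kernelCDF(v, 1)
        v / (2 * pi) - (cdf - 0.5) / 4
    } else {
        sigma <- 1 / (2 * sqrt(2 * log(2)))
        sigma^2 * (stats::pnorm(v / sigma) -
                       (v / sigma) * stats::dnorm(v / sigma))
    }
}

## Per-cell kernel integrals for every (evaluation point, cell) pair:
## `masses` (zeroth moment, exact), `cen1`/`cen2` (first/second moments
## centered on the cell midpoints), and the CDF values at the first and
## last bound (for the analytic plateau terms). `gz` is the kernel FWHM
## per evaluation point.
kernelCellMatrices <- function(zgrid, bounds, mids, gz, form) {
    nb <- length(bounds)
    U <- outer(zgrid, bounds, function(a, b) b - a)
    V <- U / gz
    M <- kernelCDF(V, 1, form)
    G1 <- gz * kernelM1Antideriv(V, form)
    G2 <- gz^2 * (if (form == "lorentzian") kernelM2Antideriv(V, form, M)
                  else kernelM2Antideriv(V, form))
    D <- outer(zgrid, mids, function(a, b) b - a)
    masses <- M[, -1, drop = FALSE] - M[, -nb, drop = FALSE]
    m1 <- G1[, -1, drop = FALSE] - G1[, -nb, drop = FALSE]
    m2 <- G2[, -1, drop = FALSE] - G2[, -nb, drop = FALSE]
    list(masses = masses,
         cen1 = m1 - D * masses,
         cen2 = m2 - 2 * D * m1 + D^2 * masses,
         cdfFirst = M[, 1], cdfLast = M[, nb])
}

## Midpoints and bounds of the layer sub-cells.
layerCells <- function(z1, z2, resolution) {
    t <- z2 - z1
    ncells <- ceiling(t / resolution)
    if (ncells < 32L)
        stop(sprintf(
            "resolution %g um yields %d quadrature cells across the layer; need >= 32 (reduce the resolution)",
            resolution, ncells))
    bounds <- seq(z1, z2, length.out = ncells + 1L)
    list(bounds = bounds, mids = (bounds[-1] + bounds[-length(bounds)]) / 2)
}

#' Evaluate the forward model on a depth grid
#'
#' Convolves the ideal layer profile of `model` with the axial PSF of
#' depth-dependent FWHM `gammaAt(z, model)` and evaluates the result at
#' `zgrid`. See the package vignette for the quadrature scheme (exact
#' arctangent kernel masses per sub-cell; total kernel mass exactly 1).
#'
#' @param model A [LayerModel-class].
#' @param zgrid Evaluation grid (um), ascending, uniformly spaced.
#' @param resolution Sub-cell spacing (um) for the layer quadrature;
#'   default `step/8` where `step` is the `zgrid` spacing; must be
#'   `<= step/4`. An error is raised if fewer than 32 cells span the
#'   layer.
#' @param form Kernel form, `"lorentzian"` (default) or `"gaussian"`.
#' @return A [ModelCurve-class].
#' @export
convolveModel <- function(model, zgrid, resolution = NULL,
                          form = c("lorentzian", "gaussian")) {
    stopifnot(is(model, "LayerModel"))
    form <- match.arg(form)
    zgrid <- as.numeric(zgrid)
    step <- uniformStep(zgrid, "evaluation grid")
    if (is.null(resolution))
        resolution <- step / 8
    if (resolution > step / 4 + 1e-12)
        stop("resolution must be at most a quarter of the grid spacing")
    cells <- layerCells(model@z1, model@z2, resolution)
    sMid <- model@h * exp(-model@mu * (cells$mids - model@z1))
    gz <- gammaAt(zgrid, model)
    K <- kernelCellMatrices(zgrid, cells$bounds, cells$mids, gz, form)
    ## second-order expansion of exp(-mu y) around each cell midpoint
    s <- as.vector(K$masses %*% sMid -
                   K$cen1 %*% (model@mu * sMid) +
                   K$cen2 %*% (model@mu^2 / 2 * sMid)) +
        model@topLevel * K$cdfFirst +
        model@bottomLevel * (1 - K$cdfLast)
    new("ModelCurve", z = zgrid, sModel = s)
}

#' Residual sum of squares between data and model curve
#'
#' @param profile A [DepthProfile-class].
#' @param curve A [ModelCurve-class] evaluated at the profile's z
#'   positions.
#' @return The residual sum of squares (dimensionless).
#' @export
residualSS <- function(profile, curve) {
    stopifnot(is(profile, "DepthProfile"), is(curve, "ModelCurve"))
    if (length(profile@z) != length(curve@z))
        stop("profile and curve must have equal length")
    if (max(abs(profile@z - curve@z)) > 1e-9)
        stop("curve must be evaluated at the profile z positions")
    sum((profile@intensity - curve@sModel)^2)
}

#' Coefficient of determination of a model curve
#'
#' `R^2 = 1 - LSQ / SS_tot`. By default `SS_tot` is the total sum of
#' squares of the experimental data points, `sum(y^2)` (the literal,
#' uncentered definition used with this model); `centered = TRUE` switches
#' to the conventional mean-centered `sum((y - mean(y))^2)`.
#'
#' @inheritParams residualSS
#' @param centered Use the mean-centered total sum of squares (default
#'   `FALSE`).
#' @return R-squared (dimensionless, <= 1).
#' @export
rSquared <- function(profile, curve, centered = FALSE) {
    lsq <- residualSS(profile, curve)
    y <- profile@intensity
    sstot <- if (centered) sum((y - mean(y))^2) else sum(y^2)
    if (sstot == 0)
        stop("total sum of squares is zero; R^2 undefined")
    1 - lsq / sstot
}

#' Write a model curve as two-column text
#'
#' Columns `z_um, model_intensity`; for overlay plotting against the
#' measured profile.
#'
#' @param curve A [ModelCurve-class].
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
writeCurve <- function(curve, path, delim = ",") {
    stopifnot(is(curve, "ModelCurve"))
    writeLines(c(paste(c("z_um", "model_intensity"), collapse = delim),
                 paste(format(curve@z, digits = 17),
                       format(curve@sModel, digits = 17), sep = delim)),
               path)
    invisible(path)
}
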