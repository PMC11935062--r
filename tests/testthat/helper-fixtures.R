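## Shared builders for the test suite. All fixtures are generated in code
## from the package's own synthetic-scan generator; truths are recorded
## alongside.

## Sweep configuration used for the bulk validation studies: FWHM ranges
## bracketed to the magnitudes of the simulated truths (<= 8 um), default
## increments and staging.
testSweep <- function(...) {
    SweepConfig(gamma1Range = c(0.3, 8), gamma2Range = c(0.3, 8), ...)
}

## Single-layer spec with the layer centered in a scan about twice its
## thickness.
singleLayerSpec <- function(gamma1, gamma2, mu, t, stepSize, h = 1.2,
                            noiseSigma = 0, seed = 1L) {
    z1 <- t / 2
    SyntheticSpec(LayerModel(z1, z1 + t, gamma1, gamma2, mu, h),
                  zRange = c(0, 2 * t), stepSize = stepSize,
                  noiseSigma = noiseSigma, seed = seed)
}

## Independent brute-force Riemann-sum oracle for the forward model: a
## plain midpoint product of the decaying ideal profile and the kernel
## density on a uniform fine grid across the layer, plus the analytic
## plateau terms. Shares no code with convolveModel().
bruteConvolve <- function(model, zgrid, res) {
    z1 <- model@z1
    z2 <- model@z2
    ys <- seq(z1, z2, length.out = ceiling((z2 - z1) / res) + 1)
    mids <- (ys[-1] + ys[-length(ys)]) / 2
    w <- ys[2] - ys[1]
    vapply(zgrid, function(z) {
        g <- gammaAt(z, model)
        sum(model@h * exp(-model@mu * (mids - z1)) *
                lorentzianDensity(z - mids, g)) * w +
            model@topLevel * (0.5 + atan(2 * (z1 - z) / g) / pi) +
            model@bottomLevel * (1 - (0.5 + atan(2 * (z2 - z) / g) / pi))
    }, numeric(1))
}

## Thin-layer spec whose scan reads out the PSF directly (for PSF
## calibration tests).
thinLayerSpec <- function(gamma, noiseSigma = 0, seed = 1L) {
    SyntheticSpec(LayerModel(9.99, 10.01, gamma, gamma, 0, 60),
                  zRange = c(0, 20), stepSize = 0.2,
                  noiseSigma = noiseSigma, seed = seed,
                  resolution = 0.0005,
                  bands = list(layer1 = c(520, 12, 1)))
}
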