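test_that("the PSF FWHM interpolates linearly and clamps outside the layer", {
    m <- LayerModel(5, 19, gamma1 = 0.9, gamma2 = 3.9, mu = 0.05, h = 1.2)
    expect_equal(gammaAt(5, m), 0.9)
    expect_equal(gammaAt(19, m), 3.9)
    expect_equal(gammaAt(12, m), (0.9 + 3.9) / 2)
    expect_equal(gammaAt(0, m), 0.9)      # clamped above the layer
    expect_equal(gammaAt(40, m), 3.9)     # clamped below
})

test_that("the ideal profile is a decaying rectangle with plateaus", {
    m <- LayerModel(5, 19, 1, 1, mu = 0.0945, h = 1.2)
    expect_equal(idealProfile(5, m), 1.2)
    expect_equal(idealProfile(19, m), 1.2 * exp(-0.0945 * 14))
    ## bottom/top intensity ratio for a strongly attenuating 14-um layer
    expect_equal(idealProfile(19, m) / idealProfile(5, m),
                 exp(-1.323))
    expect_equal(exp(-1.323), 0.2663, tolerance = 1e-3)
    expect_equal(idealProfile(c(0, 30), m), c(0, 0))

    mFlat <- LayerModel(5, 19, 1, 1, mu = 0, h = 0.8)
    expect_equal(idealProfile(seq(6, 18), mFlat), rep(0.8, 13))

    mBg <- LayerModel(5, 19, 1, 1, mu = 0, h = 1,
                      topLevel = 0.05, bottomLevel = 0.1)
    expect_equal(idealProfile(1, mBg), 0.05)
    expect_equal(idealProfile(25, mBg), 0.1)
})

test_that("a thin layer of unit area converges to the kernel itself", {
    t <- 0.064
    m <- LayerModel(10 - t / 2, 10 + t / 2, 1.5, 1.5, 0, h = 1 / t)
    zg <- seq(0, 20, by = 0.25)
    curve <- convolveModel(m, zg, resolution = t / 40)
    expect_lt(max(abs(intensity(curve) - lorentzianDensity(zg - 10, 1.5))) /
                  lorentzianDensity(0, 1.5), 1e-3)
})

test_that("a symmetric model gives a symmetric curve to machine precision", {
    m <- LayerModel(7, 21, 1.5, 1.5, mu = 0, h = 1)
    zg <- seq(0, 28, by = 0.5)
    s <- intensity(convolveModel(m, zg))
    expect_lt(max(abs(s - rev(s))), 1e-9)
})

test_that("the convolution matches an independent brute-force oracle", {
    set.seed(7)
    errs <- vapply(seq_len(10), function(i) {
        z1 <- runif(1, 4, 8)
        t <- runif(1, 10, 30)
        m <- LayerModel(z1, z1 + t, runif(1, 0.7, 1.8), runif(1, 1.6, 4.3),
                        runif(1, 0, 0.1), runif(1, 1, 2))
        zg <- seq(0, 2 * (z1 + t), by = 0.5)
        cv <- intensity(convolveModel(m, zg))
        oc <- bruteConvolve(m, zg, 0.0625 / 40)
        max(abs(cv - oc)) / max(oc)
    }, numeric(1))
    expect_lt(max(errs), 1e-6)
})

test_that("halving the sub-cell resolution changes the curve below 1e-4", {
    m <- LayerModel(5, 20, 0.8, 2.6, 0.08, 1.5)
    zg <- seq(0, 40, by = 0.5)
    s1 <- intensity(convolveModel(m, zg, 0.0625))
    s2 <- intensity(convolveModel(m, zg, 0.03125))
    expect_lt(max(abs(s1 - s2)) / max(s2), 1e-4)
})

test_that("attenuation only removes modeled signal", {
    zg <- seq(0, 40, by = 0.5)
    mk <- function(mu) LayerModel(5, 20, 0.9, 2.5, mu, 1.2)
    sLow <- intensity(convolveModel(mk(0.01), zg))
    sHigh <- intensity(convolveModel(mk(0.05), zg))
    expect_true(all(sHigh <= sLow + 1e-12))
})

test_that("the layer contribution scales linearly in h", {
    zg <- seq(0, 40, by = 0.5)
    s1 <- intensity(convolveModel(LayerModel(5, 20, 0.9, 2.5, 0.03, 1), zg))
    s2 <- intensity(convolveModel(LayerModel(5, 20, 0.9, 2.5, 0.03, 1.7),
                                  zg))
    expect_equal(s2, 1.7 * s1, tolerance = 1e-12)
})

test_that("too coarse a quadrature or resolution is rejected", {
    m <- LayerModel(5, 6, 1, 1, 0, 1)
    expect_error(convolveModel(m, seq(0, 12, by = 0.5)),
                 ">= 32")
    expect_error(convolveModel(LayerModel(5, 20, 1, 1, 0, 1),
                               seq(0, 40, by = 0.5), resolution = 0.3),
                 "quarter")
})

test_that("residual sum of squares and R^2 follow their definitions", {
    prof <- generateProfile(singleLayerSpec(1.5, 1.5, 0, 16, 0.5))$profile
    z <- zPositions(prof)
    y <- intensity(prof)

    perfect <- new("ModelCurve", z = z, sModel = y)
    expect_equal(residualSS(prof, perfect), 0)
    expect_equal(rSquared(prof, perfect), 1)

    ## one point off by 0.1 contributes exactly 0.01
    off <- y
    off[10] <- off[10] + 0.1
    expect_equal(residualSS(prof, new("ModelCurve", z = z, sModel = off)),
                 0.01)

    ## random pair equals the hand-computed sum
    set.seed(2)
    r <- runif(length(y))
    curve <- new("ModelCurve", z = z, sModel = r)
    expect_equal(residualSS(prof, curve), sum((y - r)^2))

    ## uncentered total sum of squares by default; centered on request
    zero <- new("ModelCurve", z = z, sModel = numeric(length(y)))
    expect_equal(rSquared(prof, zero), 1 - sum(y^2) / sum(y^2))
    expect_equal(rSquared(prof, zero, centered = TRUE),
                 1 - sum(y^2) / sum((y - mean(y))^2))

    expect_error(residualSS(prof, new("ModelCurve", z = z + 1, sModel = y)),
                 "profile z positions")
    expect_error(residualSS(prof, new("ModelCurve", z = z[-1],
                                      sModel = y[-1])), "equal length")
})

test_that("the noiseless generator curve is reproduced at true parameters", {
    gp <- generateProfile(singleLayerSpec(0.9, 3.9, 0.0945, 14, 0.5))
    prof <- gp$profile
    tr <- gp$truth$models[[1]]
    curve <- convolveModel(tr, zPositions(prof))
    ## the data's min-max zero is recovered by the free offset
    curve@sModel <- curve@sModel + mean(intensity(prof) - curve@sModel)
    expect_gt(rSquared(prof, curve), 1 - 1e-6)
})
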