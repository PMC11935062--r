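test_that("zero-noise profiles equal the normalized forward curve exactly", {
    spec <- singleLayerSpec(0.9, 3.9, 0.0945, 14, 0.5)
    gp <- generateProfile(spec)
    s <- intensity(convolveModel(spec@truth[[1]], zPositions(gp$profile),
                                 0.5 / 8))
    expect_equal(intensity(gp$profile), (s - min(s)) / (max(s) - min(s)),
                 tolerance = 1e-12)
    ## truth record maps h to post-normalization units
    expect_equal(gp$truth$models[[1]]@h, 1.2 / gp$truth$scale)
})

test_that("a fixed seed reproduces profiles and scans bitwise", {
    spec <- singleLayerSpec(1.5, 2.5, 0.02, 16, 0.5, noiseSigma = 0.01,
                            seed = 42L)
    expect_identical(generateProfile(spec)$profile@intensity,
                     generateProfile(spec)$profile@intensity)

    hspec <- thinLayerSpec(0.9, noiseSigma = 0.02, seed = 7L)
    expect_identical(intensities(generateHyperspectral(hspec)),
                     intensities(generateHyperspectral(hspec)))
    ## the generator does not disturb the caller's RNG stream
    set.seed(1)
    before <- runif(1)
    set.seed(1)
    invisible(generateProfile(spec))
    expect_identical(runif(1), before)
})

test_that("sum-filtering a one-band scan recovers the profile exactly", {
    spec <- SyntheticSpec(LayerModel(8, 24, 1.5, 2.0, 0.02, 1.2),
                          c(0, 32), 0.5, 0, seed = 1L, labels = "poly",
                          bands = list(poly = c(1000, 20, 1)))
    scan <- generateHyperspectral(spec)
    viaScan <- intensity(sumFilter(scan, c(960, 1040)))
    direct <- intensity(generateProfile(spec)$profile)
    expect_lt(max(abs(viaScan - direct)), 1e-9)
})

test_that("spectrally separated labels recover their own truths", {
    gam <- function(z) 1.4 + 0.05 * (z - 10)
    truth <- list(LayerModel(10, 33, gam(10), gam(33), 0.03, 1.2),
                  LayerModel(33, 58, gam(33), gam(58), 0.0015, 1.0))
    spec <- SyntheticSpec(truth, c(0, 90), 0.666, 0, seed = 2L,
                          labels = c("PET", "Nafion"),
                          bands = list(PET = c(1610, 30, 1),
                                       Nafion = c(730, 15, 1)))
    scan <- generateHyperspectral(spec)
    for (i in 1:2) {
        lab <- spec@labels[i]
        win <- if (lab == "PET") c(1570, 1650) else c(720, 740)
        got <- intensity(sumFilter(scan, win))
        want <- depthPSF:::synthCurve(spec, i)
        want <- (want - min(want)) / (max(want) - min(want))
        ## the synthetic Lorentzian bands have heavy tails, so a few 1e-4
        ## of the other label leaks into each window by construction
        expect_lt(max(abs(got - want)), 2e-3)
    }
})

test_that("an overlapping immersion-medium band biases the fitted amplitude upward", {
    base <- LayerModel(8, 24, 1.5, 2.0, 0.02, 1.2)
    ## a second component fills the space outside the layer (immersion
    ## medium); its band overlaps the sample band in the overlapping case
    medium <- LayerModel(0.01, 7.9, 1.5, 1.5, 0, 0.45)
    mk <- function(mediumCenter) {
        SyntheticSpec(list(base, medium), c(0, 32), 0.5, 0, seed = 2L,
                      labels = c("poly", "medium"),
                      bands = list(poly = c(1000, 20, 1),
                                   medium = c(mediumCenter, 20, 1)))
    }
    sepScan <- generateHyperspectral(mk(1500))
    expect_warning(ovlScan <- generateHyperspectral(mk(1030)), "overlap")
    fitH <- function(scan) {
        prof <- sumFilter(scan, c(960, 1040))
        fit <- fitLayer(prof, setInterfaces(prof, c(8, 24)), testSweep(),
                        refineInterfaces = TRUE)
        layerModel(fit)@h
    }
    expect_gt(fitH(ovlScan), fitH(sepScan))
})

test_that("fixtures are written with a readable ground-truth sidecar", {
    td <- withr::local_tempdir()
    spec <- singleLayerSpec(1.5, 2.5, 0.02, 16, 0.5, noiseSigma = 0.01,
                            seed = 12L)
    paths <- writeSyntheticFixture(spec, td, "fx", "profile")
    expect_true(file.exists(paths[["data"]]))
    back <- loadScan(paths[["data"]], "profile")
    expect_equal(intensity(back),
                 intensity(generateProfile(spec)$profile))
    truth <- readLines(paths[["truth"]])
    expect_true(any(grepl("seed: 12", truth)))
    expect_true(any(grepl("gamma2=2.5", truth)))

    spec@bands <- list(layer1 = c(730, 15, 1))
    hp <- writeSyntheticFixture(spec, td, "fxh", "matrix")
    reScan <- loadScan(hp[["data"]], "matrix")
    expect_s4_class(reScan, "SpectralScan")
})

test_that("Poisson hyperspectral rendering is reproducible and scaled", {
    spec <- SyntheticSpec(LayerModel(8, 24, 1.5, 2.0, 0.02, 1.2),
                          c(0, 32), 0.5, noiseSigma = 0.05, seed = 9L,
                          labels = "poly", noiseModel = "poisson",
                          bands = list(poly = c(1000, 20, 1)))
    s1 <- generateHyperspectral(spec)
    s2 <- generateHyperspectral(spec)
    expect_identical(intensities(s1), intensities(s2))
    ## relative noise at the peak is close to the requested 5%
    clean <- intensities(generateHyperspectral(
        SyntheticSpec(LayerModel(8, 24, 1.5, 2.0, 0.02, 1.2),
                      c(0, 32), 0.5, 0, seed = 9L, labels = "poly",
                      bands = list(poly = c(1000, 20, 1)))))
    hi <- clean > 0.5 * max(clean)
    relSD <- sd((intensities(s1)[hi] - clean[hi]) / clean[hi])
    expect_gt(relSD, 0.02)
    expect_lt(relSD, 0.1)
})
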