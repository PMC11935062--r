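## Brute-force evaluation of the sweep objective for one parameter
## combination, independent of sweepStage: model curve by convolveModel,
## free normalization offset by mean-centering, plain sum of squares.
bruteObjective <- function(y, zgrid, z1, z2, g1, g2, mu, h, resolution) {
    m <- LayerModel(z1, z2, g1, g2, mu, h)
    s <- intensity(convolveModel(m, zgrid, resolution))
    r <- (y - mean(y)) - (s - mean(s))
    sum(r^2)
}

test_that("the sweep optimum equals an exhaustive loop on a frozen grid", {
    gp <- generateProfile(singleLayerSpec(1.2, 2.4, 0.03, 16, 0.5,
                                          noiseSigma = 0.01, seed = 6L))
    prof <- gp$profile
    ifs <- setInterfaces(prof, c(8, 24))
    cfg <- SweepConfig(gamma1Range = c(0.9, 1.5), gamma2Range = c(2.0, 2.8),
                       gammaInc = 0.2, muRange = c(0, 0.06), muInc = 0.02,
                       hRange = c(1.2, 1.6), hInc = 0.1, stages = 1L)
    fit <- fitLayer(prof, ifs, cfg, refineInterfaces = FALSE)

    y <- intensity(prof)
    zg <- zPositions(prof)
    res <- stepSize(prof) / 8
    best <- list(lsq = Inf)
    ## loop order mirrors the documented lexicographic tie-break
    for (g2 in seq(2.0, 2.8, by = 0.2))
        for (g1 in seq(0.9, 1.5, by = 0.2))
            for (mu in seq(0, 0.06, by = 0.02))
                for (h in seq(1.2, 1.6, by = 0.1)) {
                    lsq <- bruteObjective(y, zg, 8, 24, g1, g2, mu, h, res)
                    if (lsq < best$lsq)
                        best <- list(lsq = lsq, g1 = g1, g2 = g2,
                                     mu = mu, h = h)
                }
    m <- layerModel(fit)
    expect_equal(m@gamma1, best$g1)
    expect_equal(m@gamma2, best$g2)
    expect_equal(m@mu, best$mu)
    expect_equal(m@h, best$h)
    expect_equal(fitLSQ(fit), best$lsq, tolerance = 1e-10)
    expect_equal(fit@iterations, 4 * 5 * 4 * 5)
})

test_that("refinement stages never worsen the residual sum of squares", {
    gp <- generateProfile(singleLayerSpec(0.9, 3.0, 0.05, 18, 0.5,
                                          noiseSigma = 0.01, seed = 2L))
    fit <- fitLayer(gp$profile, detectInterfaces(gp$profile, 1L),
                    testSweep())
    expect_true(all(diff(fit@stageLSQ) <= 1e-9 * fit@stageLSQ[1]))
})

test_that("a noiseless scan is recovered within one final increment", {
    gp <- generateProfile(singleLayerSpec(0.9, 3.9, 0.0945, 14, 0.5,
                                          noiseSigma = 0))
    fit <- fitLayer(gp$profile, detectInterfaces(gp$profile, 1L),
                    testSweep())
    tr <- gp$truth$models[[1]]
    m <- layerModel(fit)
    expect_lte(abs(m@gamma1 - 0.9), 0.1)
    expect_lte(abs(m@gamma2 - 3.9), 0.1)
    expect_lte(abs(m@mu - 0.0945), 0.002)
    expect_lte(abs(m@h - tr@h), 0.02)
    expect_lte(abs(opticalThickness(fit) - 14), 0.25)
    expect_gt(fitR2(fit), 0.9999)
})

test_that("a no-decay scan fits with negligible mu and equal FWHMs", {
    gp <- generateProfile(singleLayerSpec(1.5, 1.5, 0, 20, 0.5,
                                          noiseSigma = 0.005, seed = 5L))
    fit <- fitLayer(gp$profile, detectInterfaces(gp$profile, 1L),
                    testSweep())
    m <- layerModel(fit)
    expect_lte(m@mu, 0.002)
    expect_lte(abs(m@gamma2 - m@gamma1), 0.1)
    expect_true("negligible_attenuation" %in% qcFlags(qcEvaluate(fit)))
})

test_that("results are bitwise identical for any worker count", {
    gp <- generateProfile(singleLayerSpec(1.2, 2.2, 0.02, 14, 0.5,
                                          noiseSigma = 0.01, seed = 8L))
    ifs <- setInterfaces(gp$profile, c(7, 21))
    mk <- function(w) SweepConfig(gamma1Range = c(0.8, 2), gamma2Range = c(1.5, 3),
                                  stages = 1L, gammaInc = 0.1, workers = w)
    f1 <- fitLayer(gp$profile, ifs, mk(1L))
    f4 <- fitLayer(gp$profile, ifs, mk(4L))
    expect_identical(descriptors(f1), descriptors(f4))
    expect_identical(fitLSQ(f1), fitLSQ(f4))
    expect_identical(intensity(modelCurve(f1)), intensity(modelCurve(f4)))
})

test_that("quality-control flags trigger at the stated thresholds", {
    gp <- generateProfile(singleLayerSpec(1.5, 1.5, 0, 16, 0.5,
                                          noiseSigma = 0.005, seed = 1L))
    fit <- fitLayer(gp$profile, setInterfaces(gp$profile, c(8, 24)),
                    testSweep(), refineInterfaces = TRUE)

    mk <- function(r2, mu, g1) {
        out <- fit
        out@r2 <- r2
        out@model@mu <- mu
        out@model@gamma1 <- g1
        out
    }
    expect_false("poor_fit" %in% qcFlags(qcEvaluate(mk(0.995, 0.05, 1.5))))
    expect_true("poor_fit" %in% qcFlags(qcEvaluate(mk(0.985, 0.05, 1.5))))
    expect_true("negligible_attenuation" %in%
                    qcFlags(qcEvaluate(mk(0.995, 5e-4, 1.5))))
    expect_false("negligible_attenuation" %in%
                     qcFlags(qcEvaluate(mk(0.995, 2e-3, 1.5))))
    ## sub-resolution first interface versus a calibrated objective
    expect_true("subresolution_gamma1" %in%
                    qcFlags(qcEvaluate(mk(0.995, 0.05, 0.7),
                                       calibratedFWHM = 0.87)))
    expect_false("subresolution_gamma1" %in%
                     qcFlags(qcEvaluate(mk(0.995, 0.05, 0.9),
                                        calibratedFWHM = 0.87)))
})

test_that("an optimum pinned to a sweep boundary is flagged", {
    gp <- generateProfile(singleLayerSpec(1.5, 1.5, 0, 16, 0.5,
                                          noiseSigma = 0.005, seed = 1L))
    cfg <- SweepConfig(gamma1Range = c(0.3, 8), gamma2Range = c(0.3, 8),
                       hRange = c(1, 1.1), hInc = 0.05)  # h truth > 1.1
    fit <- fitLayer(gp$profile, detectInterfaces(gp$profile, 1L), cfg)
    expect_true("range_boundary" %in% qcFlags(fit))
})

test_that("replicate aggregation reports mean, sd and suppression", {
    gp <- generateProfile(singleLayerSpec(1.5, 1.5, 0, 16, 0.5,
                                          noiseSigma = 0.005, seed = 1L))
    base <- fitLayer(gp$profile, setInterfaces(gp$profile, c(8, 24)),
                     testSweep())
    vary <- function(g1, mu) {
        out <- base
        out@model@gamma1 <- g1
        out@model@mu <- mu
        qcEvaluate(out)
    }
    reps <- list(vary(0.8, 0.02), vary(0.9, 0.02), vary(1.0, 0.02))
    s <- aggregateReplicates(reps)
    expect_equal(s$mean[s$descriptor == "fwhm1"], 0.9)
    expect_equal(s$sd[s$descriptor == "fwhm1"], 0.1)
    expect_false(any(s$suppressed))

    same <- aggregateReplicates(list(base, base, base, base))
    expect_true(all(same$sd[!same$suppressed] == 0))

    negl <- list(vary(0.9, 5e-4), vary(1.0, 8e-4), vary(0.95, 2e-4))
    sn <- aggregateReplicates(negl)
    expect_true(sn$suppressed[sn$descriptor == "mu"])
    expect_true(is.na(sn$mean[sn$descriptor == "mu"]))

    expect_error(aggregateReplicates(list(base)), "at least 2")

    td <- withr::local_tempdir()
    exportReplicateSummary(list(sampleA = s, sampleB = sn),
                           file.path(td, "summary.tsv"))
    tab <- readLines(file.path(td, "summary.tsv"))
    expect_length(tab, 3L)
    expect_match(tab[3], "\t-$")   # suppressed attenuation prints as "-"
})

test_that("replicate means stay within two sigmas of the generator truth", {
    fits <- lapply(1:4, function(s) {
        gp <- generateProfile(singleLayerSpec(1.5, 2.5, 0.02, 16, 0.5,
                                              noiseSigma = 0.01, seed = s))
        fitLayer(gp$profile, detectInterfaces(gp$profile, 1L), testSweep())
    })
    s <- aggregateReplicates(fits)
    g1 <- s[s$descriptor == "fwhm1", ]
    expect_lt(abs(g1$mean - 1.5), 2 * max(g1$sd, 0.1))
})

test_that("the paraxial thickness correction uses the index ratio", {
    gp <- generateProfile(singleLayerSpec(1.5, 1.5, 0, 16, 0.5,
                                          noiseSigma = 0.005, seed = 1L))
    fit <- fitLayer(gp$profile, setInterfaces(gp$profile, c(8, 21.5)),
                    testSweep(), refineInterfaces = FALSE)
    ## t = 13.5 um measured in air maps to the nominal PET thickness
    expect_equal(correctedThickness(fit, OpticsConfig(532, 0.9,
                                                      nImmersion = 1.0,
                                                      nSample = 1.58)),
                 21.33)
    expect_equal(correctedThickness(fit, OpticsConfig(532, 1.0,
                                                      nImmersion = 1.33,
                                                      nSample = 1.33)),
                 13.5)
    expect_error(correctedThickness(fit, OpticsConfig(532, 0.9)),
                 "must be set")
})

test_that("fit reports serialize as key-value text plus a curve file", {
    gp <- generateProfile(singleLayerSpec(1.5, 1.5, 0, 16, 0.5,
                                          noiseSigma = 0.005, seed = 1L))
    fit <- fitLayer(gp$profile, setInterfaces(gp$profile, c(8, 24)),
                    testSweep())
    td <- withr::local_tempdir()
    exportFitResult(fit, file.path(td, "report.txt"),
                    file.path(td, "curve.csv"))
    rep <- readLines(file.path(td, "report.txt"))
    expect_true(any(grepl("^fwhm_first_interface_um:", rep)))
    expect_true(any(grepl("^r_squared:", rep)))
    curve <- read.csv(file.path(td, "curve.csv"))
    expect_equal(curve$z_um, zPositions(gp$profile))
})
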