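test_that("all three dialects round-trip z and intensities exactly", {
    spec <- thinLayerSpec(0.9)
    scan <- generateHyperspectral(spec)
    td <- withr::local_tempdir()

    for (dialect in c("matrix", "long")) {
        path <- file.path(td, paste0("scan.", dialect, ".csv"))
        writeScan(scan, path, dialect)
        back <- loadScan(path, dialect)
        expect_identical(intensities(back), intensities(scan))
        expect_equal(zPositions(back), zPositions(scan))
        expect_equal(wavenumbers(back), wavenumbers(scan))
    }

    prof <- generateProfile(spec)$profile
    path <- file.path(td, "prof.csv")
    writeProfile(prof, path)
    back <- loadScan(path, "profile")
    expect_equal(intensity(back), intensity(prof))
    expect_equal(zPositions(back), zPositions(prof))
})

test_that("delimiters are autodetected from the header line", {
    td <- withr::local_tempdir()
    z <- seq(0, 5, by = 0.5)
    y <- c(0, 0, 1, 4, 9, 9, 4, 1, 0, 0, 0)
    for (d in c(",", "\t", ";")) {
        path <- file.path(td, "p.txt")
        writeLines(c(paste("z_um", "intensity", sep = d),
                     paste(z, y, sep = d)), path)
        prof <- loadScan(path, "profile")
        expect_equal(intensity(prof), y / max(y))
    }
})

test_that("unsorted profile z is re-sorted ascending with a warning", {
    td <- withr::local_tempdir()
    z <- seq(0, 5, by = 0.5)
    y <- c(0, 0, 1, 4, 9, 9, 4, 1, 0, 0, 0)
    o <- c(5, 1, 8, 2, 11, 3, 7, 4, 10, 6, 9)
    path <- file.path(td, "p.csv")
    writeLines(c("z_um,intensity", paste(z[o], y[o], sep = ",")), path)
    expect_warning(prof <- loadScan(path, "profile"), "re-sorting")
    expect_equal(zPositions(prof), z)
    expect_equal(intensity(prof), y / max(y))
})

test_that("malformed rows raise a parse error naming the line", {
    td <- withr::local_tempdir()
    path <- file.path(td, "bad.csv")
    writeLines(c("z_um,intensity", "0,0.1", "0.5", "1,0.3"), path)
    expect_error(loadScan(path, "profile"), "line 3")
    writeLines(c("z_um,intensity", "0,0.1", "0.5,abc", "1,0.3"), path)
    expect_error(loadScan(path, "profile"), "line 3.*non-numeric")
})

test_that("sum filter equals a brute-force column-slice oracle and is inclusive", {
    set.seed(42)
    z <- seq(0, 4, by = 0.5)
    w <- seq(700, 800, by = 10)
    m <- matrix(rexp(length(z) * length(w)), length(z), length(w))
    scan <- SpectralScan(z, w, m)

    ## independent two-line oracle
    sel <- w >= 700 & w <= 760
    expected <- rowSums(m[, sel])
    expected <- (expected - min(expected)) / (max(expected) - min(expected))
    expect_equal(intensity(sumFilter(scan, c(700, 760))), expected)

    ## inclusive on both ends: window touching exactly one column
    one <- sumFilter(scan, c(750, 750 + 1e-9), normalize = FALSE)
    expect_equal(one, m[, w == 750])
})

test_that("a single-spike spectrum reduces to normalized spike amplitudes", {
    z <- seq(0, 4, by = 0.5)
    w <- c(700, 730, 760)
    amp <- c(1, 2, 5, 9, 7, 4, 2, 1, 1)
    m <- matrix(0, length(z), 3)
    m[, 2] <- amp
    prof <- sumFilter(SpectralScan(z, w, m), c(700, 760))
    expect_equal(max(intensity(prof)), 1)
    expect_equal(min(intensity(prof)), 0)
    expect_equal(intensity(prof), (amp - 1) / 8)
})

test_that("sum filter is linear in the intensity matrix before normalization", {
    set.seed(11)
    z <- seq(0, 4, by = 0.5)
    w <- seq(700, 800, by = 10)
    A <- matrix(runif(length(z) * length(w)), length(z))
    B <- matrix(runif(length(z) * length(w)), length(z))
    win <- c(710, 780)
    fa <- sumFilter(SpectralScan(z, w, A), win, normalize = FALSE)
    fb <- sumFilter(SpectralScan(z, w, B), win, normalize = FALSE)
    fab <- sumFilter(SpectralScan(z, w, A + B), win, normalize = FALSE)
    expect_equal(fab, fa + fb)
})

test_that("empty window overlap is an error", {
    scan <- SpectralScan(seq(0, 4, by = 0.5), c(700, 730, 760),
                         matrix(1, 9, 3))
    expect_error(sumFilter(scan, c(5000, 6000)), "does not overlap")
    expect_error(sumFilter(scan, c(760, 700)), "w_lo < w_hi")
})

test_that("min-max normalization is idempotent", {
    set.seed(3)
    x <- rnorm(50)
    once <- normalizeMinMax(x)$values
    twice <- normalizeMinMax(once)$values
    expect_identical(once, twice)
    expect_error(normalizeMinMax(rep(1, 10)), "constant")
})

test_that("background plateaus average the first and last n points", {
    y <- c(rep(0.02, 5), 0.3, 0.8, rep(1, 7), 0.8, 0.3, rep(0, 6))
    prof <- DepthProfile(seq_along(y), y)
    prof <- estimateBackgroundPlateaus(prof)
    lv <- backgroundLevels(prof)
    yn <- intensity(prof)
    expect_equal(unname(lv["top"]), mean(yn[1:5]))
    expect_equal(unname(lv["bottom"]), mean(yn[18:22]))

    ## [0...0, 1...1] pattern gives exactly (0, 1)
    prof2 <- DepthProfile(seq_len(10), c(rep(0, 5), rep(1, 5)))
    lv2 <- backgroundLevels(estimateBackgroundPlateaus(prof2))
    expect_equal(unname(lv2), c(0, 1))

    expect_error(estimateBackgroundPlateaus(DepthProfile(1:8, c(0, 1, 2, 3, 3, 2, 1, 0)), n = 5),
                 "at least 2 \\* n")
})

test_that("plateau estimate concentrates on the true mean under noise", {
    ## mean of 5 N(mu, 0.01) samples is within 0.02 of mu essentially
    ## always; check empirically over seeds
    hits <- vapply(seq_len(200), function(s) {
        y <- withr::with_seed(s, {
            base <- c(rep(0.05, 10), seq(0.1, 1, length.out = 10),
                      rep(1, 10))
            base + rnorm(30, 0, 0.01)
        })
        prof <- estimateBackgroundPlateaus(DepthProfile(seq_len(30), y))
        truePlateau <- (0.05 - min(y)) / (max(y) - min(y))
        abs(backgroundLevels(prof)[["top"]] - truePlateau) < 0.02
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})
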