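## Grid-search least-squares optimization of the four model parameters
## (gamma1, gamma2, mu, h) with coarse-to-fine refinement.
##
## Every stage evaluates the full Cartesian grid and keeps the
## minimum-LSQ combination; later stages re-center a 1/shrink-width grid
## (at 1/shrink the increment) on the incumbent, which stays on the new
## grid so refinement can never worsen the LSQ. Ties are broken toward
## the lexicographically smallest (gamma2, gamma1, mu, h). The amplitude h
## enters the model linearly, so for each (gamma1, gamma2, mu) the LSQ of
## the whole h grid is evaluated from two inner products; the exhaustive
## sweep over all four parameters is preserved.

#' Construct a SweepConfig
#'
#' Defaults bracket the parameter magnitudes of typical polymer films
#' scanned with air, water and oil objectives: FWHM 0.3-20 um at a final
#' increment of 0.1 um, attenuation 0-0.3 1/um at 0.002 1/um, amplitude
#' 1-3 at 0.02, two coarse-to-fine stages with a 5x contraction.
#'
#' @param gamma1Range,gamma2Range FWHM sweep ranges (um).
#' @param gammaInc Final FWHM increment (um).
#' @param muRange Attenuation range (1/um), lower bound >= 0.
#' @param muInc Final attenuation increment (1/um).
#' @param hRange Amplitude range.
#' @param hInc Final amplitude increment.
#' @param stages Number of refinement passes.
#' @param shrink Per-stage range/increment contraction factor.
#' @param workers Parallelism degree; results are independent of it.
#' @return A validated [SweepConfig-class].
#' @export
#' @examples
#' SweepConfig(stages = 1L, gammaInc = 0.5)
SweepConfig <- function(gamma1Range = c(0.3, 20), gamma2Range = c(0.3, 20),
                        gammaInc = 0.1,
                        muRange = c(0, 0.3), muInc = 0.002,
                        hRange = c(1, 3), hInc = 0.02,
                        stages = 2L, shrink = 5, workers = 1L) {
    new("SweepConfig",
        gamma1Range = as.numeric(gamma1Range),
        gamma2Range = as.numeric(gamma2Range),
        gammaInc = as.numeric(gammaInc),
        muRange = as.numeric(muRange), muInc = as.numeric(muInc),
        hRange = as.numeric(hRange), hInc = as.numeric(hInc),
        stages = as.integer(stages), shrink = as.numeric(shrink),
        workers = as.integer(workers))
}

## Grid from lo by inc, clipped at hi (always contains lo).
gridSeq <- function(lo, hi, inc) {
    n <- floor((hi - lo) / inc + 1e-9)
    lo + inc * (0:n)
}

## Grid of width `width` centered on `center` with spacing inc, clipped to
## [lo, hi]; always contains `center`.
gridAround <- function(center, width, inc, lo, hi) {
    k <- floor((width / 2) / inc + 1e-9)
    g <- center + inc * (-k:k)
    g <- g[g >= lo - 1e-12 & g <= hi + 1e-12]
    sort(unique(pmin(pmax(g, lo), hi)))
}

## One exhaustive stage over the Cartesian grid. Returns the incumbent
## (indices into the grids, LSQ) with deterministic lexicographic
## tie-breaking, independent of the worker count.
sweepStage <- function(y, zgrid, z1, z2, top, bottom,
                       g1Grid, g2Grid, muGrid, hGrid,
                       resolution, form, workers, freeOffset = FALSE) {
    cells <- layerCells(z1, z2, resolution)
    ## exp(-mu (y - z1)) at all cell midpoints, one column per mu, plus
    ## its first and second derivative factors for the per-cell
    ## linear/quadratic quadrature corrections
    sMu <- exp(-outer(cells$mids - z1, muGrid))
    sMuP <- sweep(sMu, 2L, muGrid, `*`)
    sMuPP <- sweep(sMu, 2L, muGrid^2 / 2, `*`)
    nh <- length(hGrid)
    h2 <- hGrid^2
    frac <- pmin(pmax((zgrid - z1) / (z2 - z1), 0), 1)
    evalBlock <- function(i2) {
        g2 <- g2Grid[i2]
        best <- list(lsq = Inf, i2 = NA, i1 = NA, imu = NA, ih = NA)
        for (i1 in seq_along(g1Grid)) {
            g1 <- g1Grid[i1]
            gz <- g1 + (g2 - g1) * frac
            K <- kernelCellMatrices(zgrid, cells$bounds, cells$mids, gz,
                                    form)
            C <- K$masses %*% sMu - K$cen1 %*% sMuP +
                K$cen2 %*% sMuPP                    # nz x nmu
            r <- y - top * K$cdfFirst - bottom * (1 - K$cdfLast)
            if (freeOffset) {
                ## minimizing over the free normalization offset is
                ## equivalent to mean-centering residual and curve
                C <- C - rep(colMeans(C), each = length(zgrid))
                r <- r - mean(r)
            }
            rr <- sum(r * r)
            a <- as.vector(crossprod(C, r))         # nmu
            b2 <- colSums(C * C)                    # nmu
            lsqMat <- rr - 2 * outer(hGrid, a) + outer(h2, b2)  # nh x nmu
            j <- which.min(lsqMat)                  # first min: smallest
            lsq <- lsqMat[j]                        # (mu, h) lexicographic
            if (lsq < best$lsq) {
                ih <- (j - 1L) %% nh + 1L
                imu <- (j - 1L) %/% nh + 1L
                best <- list(lsq = lsq, i2 = i2, i1 = i1,
                             imu = imu, ih = ih)
            }
        }
        best
    }
    results <- if (workers > 1L) {
        parallel::mclapply(seq_along(g2Grid), evalBlock,
                           mc.cores = workers)
    } else {
        lapply(seq_along(g2Grid), evalBlock)
    }
    best <- list(lsq = Inf, i2 = NA, i1 = NA, imu = NA, ih = NA)
    for (res in results) {      # blocks arrive in gamma2 order: first
        if (res$lsq < best$lsq) # strict improvement wins, so ties keep
            best <- res         # the lexicographically smallest combo
    }
    if (!is.finite(best$lsq))
        stop("empty parameter grid")
    best$evaluated <- length(g1Grid) * length(g2Grid) *
        length(muGrid) * length(hGrid)
    best
}

#' Fit one layer of a depth profile by exhaustive parameter sweep
#'
#' Sweeps the four model parameters (PSF FWHM at the first and second
#' interface, attenuation coefficient, intensity offset) over a Cartesian
#' grid, keeps the combination minimizing the residual sum of squares,
#' then re-centers and contracts the grid for each further stage. The
#' interface positions are fixed inputs taken from `interfaces`.
#'
#' @param profile A normalized [DepthProfile-class].
#' @param interfaces An [InterfaceSet-class] holding exactly the layer's
#'   two positions (from [detectInterfaces()] or [setInterfaces()]).
#' @param sweep A [SweepConfig-class]; see [SweepConfig()] for defaults.
#' @param resolution Convolution sub-cell spacing (um); default
#'   `stepSize(profile) / 8`.
#' @param useBaselines Model uneven background with the profile's plateau
#'   estimates ([estimateBackgroundPlateaus()]; estimated with `n = 5` on
#'   the fly if absent). Default `FALSE`.
#' @param form Kernel form passed to [convolveModel()].
#' @param centered Use the centered total sum of squares in [rSquared()].
#' @param refineInterfaces Refine the interface positions against the full
#'   forward model after the parameter sweep (default `TRUE` for
#'   auto-detected interfaces, `FALSE` for manual ones). With attenuation,
#'   the inflection point of the measured profile sits systematically
#'   inside the true interface (by about `mu * gamma^2 / 4` for a
#'   Lorentzian kernel), so the detected positions are treated as
#'   initializers: each interface is re-located on a fine grid (coarse
#'   to fine, up to +/- 4 um) minimizing the residual sum of squares,
#'   with a small adaptive parameter grid per candidate position so the
#'   correlated (z, gamma, h) ridge cannot stall the search, and the
#'   final sweep stage is re-run at the refined positions.
#' @return A [FitResult-class]. The QC flag `"range_boundary"` is set when
#'   the optimum sits on an edge of the configured sweep range.
#' @export
fitLayer <- function(profile, interfaces, sweep = SweepConfig(),
                     resolution = NULL, useBaselines = FALSE,
                     form = c("lorentzian", "gaussian"),
                     centered = FALSE, refineInterfaces = NULL) {
    stopifnot(is(profile, "DepthProfile"), is(interfaces, "InterfaceSet"))
    form <- match.arg(form)
    if (length(interfaces@positions) != 2L)
        stop("fitLayer needs exactly one layer (two interface positions); use fitStack() for stacks")
    z1 <- interfaces@positions[1]
    z2 <- interfaces@positions[2]
    if (is.null(refineInterfaces))
        refineInterfaces <- !all(interfaces@provenance == "manual")
    if (is.null(resolution))
        resolution <- profile@stepSize / 8
    top <- bottom <- 0
    ## the min-max normalization of the data fixes an arbitrary zero (the
    ## scan's smallest sample, which under noise lies below the true
    ## signal floor); the comparison therefore allows a global additive
    ## constant, solved analytically alongside each grid combination.
    ## With background plateaus enabled they take that role instead.
    freeOffset <- !useBaselines
    if (useBaselines) {
        if (!is.finite(profile@topLevel))
            profile <- estimateBackgroundPlateaus(profile)
        top <- profile@topLevel
        bottom <- profile@bottomLevel
    }
    y <- profile@intensity
    zgrid <- profile@z
    nStages <- sweep@stages
    evaluated <- 0
    stageLSQ <- numeric(nStages)
    opt <- NULL
    stageGrids <- function(s, opt) {
        fac <- sweep@shrink^(nStages - s)
        if (s == 1L) {
            list(g1 = gridSeq(sweep@gamma1Range[1], sweep@gamma1Range[2],
                              sweep@gammaInc * fac),
                 g2 = gridSeq(sweep@gamma2Range[1], sweep@gamma2Range[2],
                              sweep@gammaInc * fac),
                 mu = gridSeq(sweep@muRange[1], sweep@muRange[2],
                              sweep@muInc * fac),
                 h = gridSeq(sweep@hRange[1], sweep@hRange[2],
                             sweep@hInc * fac))
        } else {
            wfac <- sweep@shrink^(s - 1L)
            list(g1 = gridAround(opt$g1, diff(sweep@gamma1Range) / wfac,
                                 sweep@gammaInc * fac,
                                 sweep@gamma1Range[1],
                                 sweep@gamma1Range[2]),
                 g2 = gridAround(opt$g2, diff(sweep@gamma2Range) / wfac,
                                 sweep@gammaInc * fac,
                                 sweep@gamma2Range[1],
                                 sweep@gamma2Range[2]),
                 mu = gridAround(opt$mu, diff(sweep@muRange) / wfac,
                                 sweep@muInc * fac,
                                 sweep@muRange[1], sweep@muRange[2]),
                 h = gridAround(opt$h, diff(sweep@hRange) / wfac,
                                sweep@hInc * fac,
                                sweep@hRange[1], sweep@hRange[2]))
        }
    }
    doStage <- function(g, z1c, z2c) {
        st <- sweepStage(y, zgrid, z1c, z2c, top, bottom,
                         g$g1, g$g2, g$mu, g$h,
                         resolution, form, sweep@workers, freeOffset)
        evaluated <<- evaluated + st$evaluated
        list(g1 = g$g1[st$i1], g2 = g$g2[st$i2],
             mu = g$mu[st$imu], h = g$h[st$ih], lsq = st$lsq)
    }
    for (s in seq_len(nStages)) {
        opt <- doStage(stageGrids(s, opt), z1, z2)
        stageLSQ[s] <- opt$lsq
    }
    if (refineInterfaces) {
        zmin <- zgrid[1]
        zmax <- zgrid[length(zgrid)]
        ## LSQ of a candidate interface pair, minimized over a small
        ## adaptive parameter grid around the incumbent (the four swept
        ## parameters re-adapt jointly with the interfaces; freezing them
        ## stalls the search on the strong correlation ridge between the
        ## interface position, the adjacent FWHM and the amplitude)
        miniLsq <- function(z1c, z2c) {
            g <- list(
                g1 = gridAround(opt$g1, 2 * sweep@gammaInc, sweep@gammaInc,
                                sweep@gamma1Range[1], sweep@gamma1Range[2]),
                g2 = gridAround(opt$g2, 4 * sweep@gammaInc, sweep@gammaInc,
                                sweep@gamma2Range[1], sweep@gamma2Range[2]),
                mu = gridAround(opt$mu, 2 * sweep@muInc, sweep@muInc,
                                sweep@muRange[1], sweep@muRange[2]),
                h = gridAround(opt$h, 2 * sweep@hInc, sweep@hInc,
                               sweep@hRange[1], sweep@hRange[2]))
            evaluated <<- evaluated + length(g$g1) * length(g$g2) *
                length(g$mu) * length(g$h)
            sweepStage(y, zgrid, z1c, z2c, top, bottom,
                       g$g1, g$g2, g$mu, g$h, resolution, form, 1L,
                       freeOffset)$lsq
        }
        zSearch <- function(fixed, current, lo, hi, coarse) {
            sp <- if (coarse) 4 * resolution else resolution
            hw <- if (coarse) 4 else 0.5
            cand <- current + seq(-hw, hw, by = sp)
            cand <- cand[cand >= lo & cand <= hi]
            lsqs <- vapply(cand, fixed, numeric(1))
            cand[which.min(lsqs)]
        }
        for (iter in 1:4) {
            coarse <- iter == 1L
            z2new <- zSearch(function(zc) miniLsq(z1, zc), z2,
                             z1 + 32 * resolution, zmax, coarse)
            z1new <- zSearch(function(zc) miniLsq(zc, z2new), z1,
                             zmin, z2new - 32 * resolution, coarse)
            moved <- abs(z2new - z2) > 1e-12 || abs(z1new - z1) > 1e-12
            z1 <- z1new
            z2 <- z2new
            if (!moved) break
            opt <- doStage(stageGrids(max(nStages, 2L), opt), z1, z2)
            stageLSQ <- c(stageLSQ, opt$lsq)
        }
    }
    model <- LayerModel(z1, z2, gamma1 = opt$g1, gamma2 = opt$g2,
                        mu = opt$mu, h = opt$h,
                        topLevel = top, bottomLevel = bottom)
    curve <- convolveModel(model, zgrid, resolution, form)
    offset <- 0
    if (freeOffset) {
        offset <- mean(y - curve@sModel)
        curve@sModel <- curve@sModel + offset
    }
    flags <- character()
    onEdge <- function(v, rng, inc)
        abs(v - rng[1]) < inc / 2 || abs(v - rng[2]) < inc / 2
    if (onEdge(opt$g1, sweep@gamma1Range, sweep@gammaInc) ||
        onEdge(opt$g2, sweep@gamma2Range, sweep@gammaInc) ||
        onEdge(opt$h, sweep@hRange, sweep@hInc) ||
        abs(opt$mu - sweep@muRange[2]) < sweep@muInc / 2)
        flags <- c(flags, "range_boundary")
    result <- new("FitResult", model = model,
                  r2 = rSquared(profile, curve, centered),
                  lsq = residualSS(profile, curve),
                  curve = curve,
                  decayPerDistance = (opt$g2 - opt$g1) / (z2 - z1),
                  qcFlags = flags, iterations = evaluated,
                  offset = offset,
                  stageLSQ = stageLSQ, config = sweep, profile = profile)
    qcEvaluate(result)
}

#' Evaluate quality-control flags on a fit
#'
#' Adds `"poor_fit"` when the coefficient of determination is below 0.99,
#' `"negligible_attenuation"` when the fitted attenuation coefficient is
#' at or below 1e-3 1/um (no meaningful intensity decay over focus depth;
#' replicate statistics on mu are suppressed in that regime), and
#' `"subresolution_gamma1"` when the FWHM at the first interface falls
#' below a supplied calibrated objective FWHM (paraxial focus compression
#' at strongly mismatched interfaces can produce such apparent
#' super-resolution).
#'
#' @param result A [FitResult-class].
#' @param calibratedFWHM Optional calibrated objective FWHM (um), e.g.
#'   `fwhm(calibratePSF(...))`.
#' @return The result with updated `qcFlags`.
#' @export
qcEvaluate <- function(result, calibratedFWHM = NULL) {
    stopifnot(is(result, "FitResult"))
    flags <- setdiff(result@qcFlags,
                     c("poor_fit", "negligible_attenuation",
                       "subresolution_gamma1"))
    if (result@r2 < 0.99)
        flags <- c(flags, "poor_fit")
    if (result@model@mu <= 1e-3)
        flags <- c(flags, "negligible_attenuation")
    if (!is.null(calibratedFWHM) && result@model@gamma1 < calibratedFWHM)
        flags <- c(flags, "subresolution_gamma1")
    result@qcFlags <- flags
    result
}

#' Replicate statistics over independent fits
#'
#' Arithmetic mean and standard deviation (over replicates, `n - 1`
#' denominator) of every fit descriptor across independent through-plane
#' scans of the same sample/objective configuration. When every replicate
#' carries the `negligible_attenuation` flag, statistics on the
#' attenuation coefficient are suppressed (reported as `NA` with
#' `suppressed = TRUE` and printed as "-"), since a decay at or below
#' 1e-3 1/um is not meaningfully quantifiable.
#'
#' @param results List of [FitResult-class] (>= 2).
#' @return A `data.frame` with columns `descriptor`, `mean`, `sd`,
#'   `suppressed`.
#' @export
aggregateReplicates <- function(results) {
    if (length(results) < 2L)
        stop("need at least 2 replicate fits; report a single fit directly")
    stopifnot(all(vapply(results, is, logical(1), "FitResult")))
    mat <- vapply(results, descriptors,
                  numeric(length(descriptors(results[[1]]))))
    out <- data.frame(descriptor = rownames(mat),
                      mean = rowMeans(mat),
                      sd = apply(mat, 1, stats::sd),
                      suppressed = FALSE,
                      row.names = NULL)
    allNegligible <- all(vapply(results, function(r)
        "negligible_attenuation" %in% r@qcFlags, logical(1)))
    if (allNegligible) {
        i <- out$descriptor == "mu"
        out$mean[i] <- NA_real_
        out$sd[i] <- NA_real_
        out$suppressed[i] <- TRUE
    }
    out
}

#' Geometric thickness from the fitted optical thickness
#'
#' Applies the paraxial correction to the optical thickness of a fitted
#' layer: `t * nSample / nImmersion`.
#'
#' @param result A [FitResult-class].
#' @param cfg An [OpticsConfig-class] with both refractive indices set.
#' @return Corrected thickness (um).
#' @export
correctedThickness <- function(result, cfg) {
    stopifnot(is(result, "FitResult"), is(cfg, "OpticsConfig"))
    if (!is.finite(cfg@nSample) || !is.finite(cfg@nImmersion))
        stop("both nSample and nImmersion must be set")
    opticalThickness(result) * cfg@nSample / cfg@nImmersion
}

#' Export a fit result as a key-value report (plus optional curve file)
#'
#' @param result A [FitResult-class].
#' @param path Report path.
#' @param curvePath Optional path for the overlay model curve
#'   ([writeCurve()]).
#' @return `path`, invisibly.
#' @export
exportFitResult <- function(result, path, curvePath = NULL) {
    stopifnot(is(result, "FitResult"))
    d <- descriptors(result)
    m <- result@model
    lines <- c(
        sprintf("z1_um: %.6g", m@z1),
        sprintf("z2_um: %.6g", m@z2),
        sprintf("optical_thickness_um: %.6g", d[["t"]]),
        sprintf("fwhm_first_interface_um: %.6g", d[["fwhm1"]]),
        sprintf("fwhm_second_interface_um: %.6g", d[["fwhm2"]]),
        sprintf("resolution_decay_per_distance: %.6g",
                d[["decayPerDistance"]]),
        sprintf("attenuation_coefficient_per_um: %.6g", d[["mu"]]),
        sprintf("intensity_offset_h: %.6g", d[["h"]]),
        sprintf("r_squared: %.8g", d[["r2"]]),
        sprintf("lsq: %.8g", result@lsq),
        sprintf("grid_points_evaluated: %g", result@iterations),
        paste0("qc_flags: ",
               if (length(result@qcFlags))
                   paste(result@qcFlags, collapse = ",") else "none"))
    writeLines(lines, path)
    if (!is.null(curvePath))
        writeCurve(result@curve, curvePath)
    invisible(path)
}

#' Export a replicate summary table
#'
#' Delimited table with one row per sample: FWHM at the first and second
#' interface, resolution decay per distance and attenuation coefficient
#' (mean +/- sd); suppressed attenuation statistics print as "-".
#'
#' @param summaries Named list of data frames from
#'   [aggregateReplicates()].
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
exportReplicateSummary <- function(summaries, path, delim = "\t") {
    fmt <- function(s, key) {
        i <- s$descriptor == key
        if (s$suppressed[i]) "-"
        else sprintf("%.3g +/- %.3g", s$mean[i], s$sd[i])
    }
    header <- paste(c("sample", "fwhm_first_interface_um",
                      "fwhm_second_interface_um",
                      "resolution_decay_per_distance",
                      "attenuation_coefficient_per_um"), collapse = delim)
    rows <- vapply(names(summaries), function(nm) {
        s <- summaries[[nm]]
        paste(c(nm, fmt(s, "fwhm1"), fmt(s, "fwhm2"),
                fmt(s, "decayPerDistance"), fmt(s, "mu")),
              collapse = delim)
    }, character(1))
    writeLines(c(header, rows), path)
    invisible(path)
}
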