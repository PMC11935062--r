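## Reading, integrating and normalizing confocal through-plane scan data.
##
## Three text dialects are supported (delimiter autodetected from the
## header among comma/tab/semicolon):
##   long    columns z_um, wavenumber_cm1, intensity (one row per pair)
##   matrix  first row: label then z (um); first column: wavenumber (1/cm);
##           body: counts (rows = wavenumbers, columns = z positions)
##   profile columns z_um, intensity (already band-integrated)

#' Construct a SpectralScan
#'
#' @param z Axial focus positions (um), strictly ascending, uniform.
#' @param wavenumbers Spectral axis (1/cm); re-ordered ascending if needed.
#' @param intensities Matrix of counts, `length(z)` x `length(wavenumbers)`.
#' @param meta Optional free-text label (objective, immersion medium).
#' @return A validated [SpectralScan-class].
#' @export
#' @examples
#' SpectralScan(z = seq(0, 2, by = 0.5), wavenumbers = c(700, 730, 760),
#'              intensities = matrix(1, 5, 3))
SpectralScan <- function(z, wavenumbers, intensities, meta = "") {
    intensities <- as.matrix(intensities)
    o <- order(wavenumbers)
    new("SpectralScan", z = as.numeric(z),
        wavenumbers = as.numeric(wavenumbers)[o],
        intensities = intensities[, o, drop = FALSE],
        stepSize = uniformStep(as.numeric(z)),
        meta = as.character(meta))
}

#' Construct a DepthProfile
#'
#' The intensity vector is always min-max normalized (idempotently) and the
#' pre-normalization extrema recorded in `rawMin`/`rawMax`.
#'
#' @param z Focus depths (um), strictly ascending, uniform spacing.
#' @param intensity Intensity values (counts or already normalized).
#' @param topLevel,bottomLevel Optional background plateau values
#'   (normalized units); usually left `NA` and filled in later by
#'   [estimateBackgroundPlateaus()].
#' @return A validated [DepthProfile-class].
#' @export
#' @examples
#' DepthProfile(z = seq(0, 7), intensity = c(0, 0, 1, 5, 5, 1, 0, 0))
DepthProfile <- function(z, intensity, topLevel = NA_real_,
                         bottomLevel = NA_real_) {
    nm <- normalizeMinMax(as.numeric(intensity))
    new("DepthProfile", z = as.numeric(z), intensity = nm$values,
        stepSize = uniformStep(as.numeric(z)),
        rawMin = nm$min, rawMax = nm$max,
        topLevel = topLevel, bottomLevel = bottomLevel)
}

#' Load a through-plane scan from a delimited text file
#'
#' @param path Path to the file.
#' @param dialect One of `"long"`, `"matrix"` (both return a
#'   [SpectralScan-class]) or `"profile"` (returns a [DepthProfile-class],
#'   min-max normalized on load). See the package vignette for the column
#'   layouts. The delimiter (comma, tab or semicolon) is autodetected from
#'   the header line.
#' @param meta Optional free-text label attached to the scan.
#' @return A [SpectralScan-class] or [DepthProfile-class]; z sorted
#'   ascending (with a warning if the file was unsorted).
#' @export
loadScan <- function(path, dialect = c("long", "matrix", "profile"),
                     meta = "") {
    dialect <- match.arg(dialect)
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2L)
        stop("file too short: ", path)
    delim <- detectDelimiter(lines[1])
    switch(dialect,
        profile = {
            body <- parseNumericRows(lines[-1], delim, 2L, 2L)
            z <- body[, 1]
            if (is.unsorted(z, strictly = TRUE)) {
                warning("profile z positions were not sorted; re-sorting ascending")
                o <- order(z)
                body <- body[o, , drop = FALSE]
                z <- body[, 1]
            }
            DepthProfile(z = z, intensity = body[, 2])
        },
        long = {
            body <- parseNumericRows(lines[-1], delim, 3L, 2L)
            z <- sort(unique(body[, 1]))
            w <- sort(unique(body[, 2]))
            if (nrow(body) != length(z) * length(w))
                stop("long-format file is not a complete z x wavenumber grid")
            mat <- matrix(NA_real_, length(z), length(w))
            iz <- match(body[, 1], z)
            iw <- match(body[, 2], w)
            mat[cbind(iz, iw)] <- body[, 3]
            if (anyNA(mat))
                stop("long-format file has duplicated or missing (z, wavenumber) pairs")
            SpectralScan(z = z, wavenumbers = w, intensities = mat,
                         meta = meta)
        },
        matrix = {
            header <- strsplit(lines[1], delim, fixed = TRUE)[[1]]
            z <- suppressWarnings(as.numeric(header[-1]))
            if (anyNA(z))
                stop("parse error at line 1: matrix header must be a label followed by numeric z positions")
            body <- parseNumericRows(lines[-1], delim, length(z) + 1L, 2L)
            w <- body[, 1]
            mat <- t(body[, -1, drop = FALSE])   # rows become z positions
            if (is.unsorted(z, strictly = TRUE)) {
                warning("matrix z positions were not sorted; re-sorting ascending")
                o <- order(z)
                z <- z[o]
                mat <- mat[o, , drop = FALSE]
            }
            SpectralScan(z = z, wavenumbers = w, intensities = mat,
                         meta = meta)
        })
}

#' Write a SpectralScan to a delimited text file
#'
#' @param scan A [SpectralScan-class].
#' @param path Output path.
#' @param dialect `"matrix"` or `"long"`.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
writeScan <- function(scan, path, dialect = c("matrix", "long"),
                      delim = ",") {
    stopifnot(is(scan, "SpectralScan"))
    dialect <- match.arg(dialect)
    z <- scan@z
    w <- scan@wavenumbers
    m <- scan@intensities
    if (dialect == "matrix") {
        header <- paste(c("wavenumber_cm1", format(z, digits = 17)),
                        collapse = delim)
        rows <- vapply(seq_along(w), function(i)
            paste(c(format(w[i], digits = 17),
                    format(m[, i], digits = 17)), collapse = delim),
            character(1))
        writeLines(c(header, rows), path)
    } else {
        header <- paste(c("z_um", "wavenumber_cm1", "intensity"),
                        collapse = delim)
        grid <- expand.grid(iw = seq_along(w), iz = seq_along(z))
        rows <- paste(format(z[grid$iz], digits = 17),
                      format(w[grid$iw], digits = 17),
                      format(m[cbind(grid$iz, grid$iw)], digits = 17),
                      sep = delim)
        writeLines(c(header, rows), path)
    }
    invisible(path)
}

#' Write a DepthProfile to a two-column text file
#'
#' @param profile A [DepthProfile-class] (normalized intensities are
#'   written).
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
writeProfile <- function(profile, path, delim = ",") {
    stopifnot(is(profile, "DepthProfile"))
    header <- paste(c("z_um", "intensity"), collapse = delim)
    rows <- paste(format(profile@z, digits = 17),
                  format(profile@intensity, digits = 17), sep = delim)
    writeLines(c(header, rows), path)
    invisible(path)
}

#' Integrate a wavenumber window into a depth profile (sum filter)
#'
#' Sums the counts of every spectral column with `w_lo <= w <= w_hi`
#' (inclusive on both ends) at each focus position, then min-max
#' normalizes the integrated intensity. The sum filter is linear in the
#' intensity matrix before normalization.
#'
#' @param scan A [SpectralScan-class].
#' @param window Numeric length-2, the wavenumber window (1/cm).
#' @param normalize Normalize after integration (default `TRUE`; `FALSE`
#'   returns the raw integrated counts as a numeric vector).
#' @return A [DepthProfile-class] (or raw numeric vector).
#' @export
sumFilter <- function(scan, window, normalize = TRUE) {
    stopifnot(is(scan, "SpectralScan"))
    if (length(window) != 2L || !all(is.finite(window)) ||
        window[1] >= window[2])
        stop("window must be [w_lo, w_hi] with w_lo < w_hi")
    sel <- scan@wavenumbers >= window[1] & scan@wavenumbers <= window[2]
    if (!any(sel))
        stop(sprintf(
            "sum-filter window [%g, %g] does not overlap the wavenumber axis [%g, %g]",
            window[1], window[2], min(scan@wavenumbers),
            max(scan@wavenumbers)))
    integrated <- rowSums(scan@intensities[, sel, drop = FALSE])
    if (!normalize) return(integrated)
    DepthProfile(z = scan@z, intensity = integrated)
}

#' Estimate background plateaus from the scan ends
#'
#' Averages the first `n` and last `n` normalized intensities of the
#' through-plane profile; used as the nonzero ideal-profile baselines when
#' background modeling is enabled in [fitLayer()].
#'
#' @param profile A [DepthProfile-class] with at least `2 * n` points.
#' @param n Number of points averaged at each end (default 5).
#' @return The profile with `topLevel` and `bottomLevel` filled in
#'   (retrieve with [backgroundLevels()]).
#' @export
estimateBackgroundPlateaus <- function(profile, n = 5L) {
    stopifnot(is(profile, "DepthProfile"))
    n <- as.integer(n)
    if (n < 1L)
        stop("n must be >= 1")
    m <- length(profile@intensity)
    if (m < 2L * n)
        stop(sprintf("profile has %d points; need at least 2 * n = %d",
                     m, 2L * n))
    profile@topLevel <- mean(profile@intensity[seq_len(n)])
    profile@bottomLevel <- mean(profile@intensity[seq(m - n + 1L, m)])
    profile
}

#' Extract a slice of a depth profile
#'
#' Internal-style convenience used when fitting edges or lobes: returns the
#' (un-renormalized) z / intensity values between two depths.
#'
#' @param profile A [DepthProfile-class].
#' @param zmin,zmax Depth bounds (um), inclusive.
#' @return List with `z` and `intensity` vectors.
#' @export
profileSlice <- function(profile, zmin, zmax) {
    sel <- profile@z >= zmin & profile@z <= zmax
    list(z = profile@z[sel], intensity = profile@intensity[sel])
}
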