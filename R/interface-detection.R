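## Locating material interfaces in a depth profile.
##
## An interface shows up as an intensity swap: a steep rising or falling
## flank whose inflection point (zero of the second derivative) marks the
## transition. Each candidate flank is fitted with a four-parameter
## sigmoid; the fitted inflection d is the interface estimate. When the
## automatic test fails (noise, extreme decay) interfaces can be set
## manually.

sigmoidError <- function(msg) {
    stop(errorCondition(paste0(msg, "; consider setting interfaces manually",
                               " with setInterfaces()"),
                        class = c("depthPSF_sigmoid_error", "error")))
}

#' Fit a sigmoid to one edge of a depth profile
#'
#' Least-squares fit of `f(z) = a + b / (1 + exp(-s c (z - d)))` with
#' `s = +1` for a rising and `s = -1` for a falling edge; `d` is the
#' inflection point. Starting values: `a` = segment minimum, `b` = segment
#' range, `d` = steepest-gradient point, `c` = 4 / segment span. Up to
#' three bounded restarts with `d` shifted by one or two grid steps are
#' attempted before the failure condition (class
#' `depthPSF_sigmoid_error`) is signalled, which directs the caller to the
#' manual workflow.
#'
#' @param z,intensity Numeric vectors: the edge segment (>= 6 points)
#'   spanning one monotone-in-trend flank, e.g. from [profileSlice()].
#' @param edge `"rising"` or `"falling"`.
#' @return A [SigmoidFit-class]. `d` is invariant under affine intensity
#'   rescaling of the segment (`a` and `b` absorb it).
#' @export
fitSigmoid <- function(z, intensity, edge = c("rising", "falling")) {
    edge <- match.arg(edge)
    z <- as.numeric(z)
    y <- as.numeric(intensity)
    if (length(z) != length(y))
        stop("z and intensity must have equal length")
    if (length(z) < 6L)
        stop("an edge segment needs at least 6 points")
    s <- if (edge == "rising") 1 else -1
    span <- max(z) - min(z)
    rng <- max(y) - min(y)
    if (rng < 1e-8)
        sigmoidError("flat segment: no edge amplitude to fit")
    dz <- diff(z)
    grad <- diff(y) / dz
    d0 <- z[which.max(s * grad)] + dz[1] / 2
    step <- mean(dz)
    a0 <- min(y)
    b0 <- rng
    ## steepness from the observed maximum slope (a sigmoid's peak slope
    ## is b c / 4); the flat 4/span fallback alone under-bends long
    ## segments and lets the optimizer drift into shallow local optima
    cSlope <- 4 * max(s * grad) / b0
    ## bounded Levenberg-Marquardt on the residuals with the analytic
    ## Jacobian of the logistic edge
    sigmoidAt <- function(p) {
        e <- pmin(pmax(s * p[3] * (z - p[4]), -700), 700)
        1 / (1 + exp(-e))
    }
    residFn <- function(p) y - (p[1] + p[2] * sigmoidAt(p))
    jacFn <- function(p) {
        g <- sigmoidAt(p)
        gg <- p[2] * g * (1 - g)
        -cbind(1, g, gg * s * (z - p[4]), -gg * s * p[3])
    }
    fitOnce <- function(cStart, dStart) {
        tryCatch({
            fit <- minpack.lm::nls.lm(
                par = c(a0, b0, cStart, dStart),
                fn = residFn, jac = jacFn,
                lower = c(-Inf, 1e-8, 1e-6, min(z)),
                upper = c(Inf, Inf, Inf, max(z)),
                control = minpack.lm::nls.lm.control(maxiter = 200))
            p <- stats::setNames(fit$par, c("a", "b", "c", "d"))
            list(p = p, rss = sum(fit$fvec^2))
        }, error = function(e) NULL)
    }
    best <- NULL
    for (dStart in c(d0, d0 + step, d0 - step, d0 + 2 * step)) {
        dStart <- min(max(dStart, min(z)), max(z))
        for (cStart in unique(c(cSlope, 4 / span))) {
            res <- fitOnce(cStart, dStart)
            if (!is.null(res) && is.finite(res$p[["d"]]) &&
                res$p[["d"]] >= min(z) && res$p[["d"]] <= max(z) &&
                res$p[["b"]] > 1e-4 && res$p[["c"]] > 0 &&
                (is.null(best) || res$rss < best$rss))
                best <- res
        }
        ## stop restarting once a clean fit exists (residuals far below
        ## the edge amplitude)
        if (!is.null(best) && best$rss < (0.02 * best$p[["b"]])^2 *
                length(y))
            break
    }
    if (is.null(best))
        sigmoidError("sigmoid fit did not converge on this segment")
    new("SigmoidFit",
        a = unname(best$p[["a"]]), b = unname(best$p[["b"]]),
        c = unname(best$p[["c"]]), d = unname(best$p[["d"]]),
        rss = best$rss, edge = edge)
}

## Intensity lobes of a smoothed profile: maximal runs above `thr`, runs
## separated by fewer than 3 points merged. Returns start/end indices and
## the peak index/value per lobe.
profileLobes <- function(sm, thr) {
    above <- sm > thr
    if (!any(above)) return(NULL)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values], ends[r$values])
    if (nrow(runs) > 1L) {           # merge runs split by short dips
        merged <- runs[1, , drop = FALSE]
        for (k in seq(2L, nrow(runs))) {
            if (runs[k, 1] - merged[nrow(merged), 2] <= 3L)
                merged[nrow(merged), 2] <- runs[k, 2]
            else merged <- rbind(merged, runs[k, ])
        }
        runs <- merged
    }
    peakIdx <- apply(runs, 1, function(se)
        se[1] + which.max(sm[se[1]:se[2]]) - 1L)
    list(runs = runs, peakIdx = peakIdx, peakVal = sm[peakIdx])
}

#' Detect material interfaces by sigmoid inflection points
#'
#' An interface is an intensity swap: the profile's transition between the
#' background level and a material lobe, mathematically the inflection
#' point where the second derivative of the profile crosses zero. The
#' detector smooths the profile (3-point moving average), thresholds it to
#' find its `nLayers` intensity lobes (the dominant ones are kept if more
#' separate), anchors one rising segment at each lobe entry and one
#' falling segment at each lobe exit -- each segment spanning from the
#' adjacent background plateau to just past the edge shoulder -- and fits
#' a sigmoid per segment ([fitSigmoid()]). The fitted inflection points
#' `d`, in depth order, are the interface positions. The segments are
#' bounded on purpose: under strong attenuation the exponential intensity
#' decay inside a layer would otherwise masquerade as a huge falling edge
#' and displace the faint second-interface inflection.
#'
#' @param profile A normalized [DepthProfile-class].
#' @param nLayers Number of traversed lobes of this signal (>= 1); each
#'   contributes a rising and a falling edge.
#' @return An [InterfaceSet-class] with provenance `"auto"`. Fewer lobes
#'   than `nLayers`, a failed sigmoid, or an insignificant edge amplitude
#'   raise an error (class `depthPSF_sigmoid_error`) directing to
#'   [setInterfaces()].
#' @export
detectInterfaces <- function(profile, nLayers = 1L) {
    stopifnot(is(profile, "DepthProfile"))
    nLayers <- as.integer(nLayers)
    if (nLayers < 1L)
        stop("nLayers must be >= 1")
    z <- profile@z
    y <- profile@intensity
    n <- length(y)
    sm <- movingAverage3(y)
    nEnd <- min(5L, floor(n / 4))
    bg <- min(mean(sm[seq_len(nEnd)]), mean(sm[seq(n - nEnd + 1L, n)]))
    thr <- bg + 0.12 * (max(sm) - bg)
    lob <- profileLobes(sm, thr)
    if (is.null(lob))
        sigmoidError("no intensity lobe rises above the background")
    if (nrow(lob$runs) < nLayers)
        sigmoidError(sprintf(
            "found %d intensity lobe(s) but expected %d layer(s)",
            nrow(lob$runs), nLayers))
    keep <- sort(order(-lob$peakVal)[seq_len(nLayers)])
    runs <- lob$runs[keep, , drop = FALSE]
    peakIdx <- lob$peakIdx[keep]
    ## outer anchors: profile ends, or the minimum between adjacent lobes
    splits <- integer(0)
    if (nLayers > 1L) {
        splits <- vapply(seq_len(nLayers - 1L), function(k) {
            lo <- runs[k, 2]
            hi <- runs[k + 1L, 1]
            lo + which.min(sm[lo:hi]) - 1L
        }, integer(1))
    }
    leftOut <- c(1L, splits)
    rightOut <- c(splits, n)
    step <- profile@stepSize
    widenTo6 <- function(seg) {
        while (seg[2] - seg[1] + 1L < 6L) {
            if (seg[1] > 1L) seg[1] <- seg[1] - 1L
            if (seg[2] < n) seg[2] <- seg[2] + 1L
            if (seg[1] == 1L && seg[2] == n) break
        }
        seg
    }
    fits <- vector("list", 2L * nLayers)
    for (k in seq_len(nLayers)) {
        s <- runs[k, 1]; e <- runs[k, 2]; p <- peakIdx[k]
        vstop <- bg + 0.3 * (sm[p] - bg)   # just past the edge shoulder
        pad <- max(3L, round(0.15 * (e - s)))
        iRise <- s
        while (iRise < p && sm[iRise] < vstop) iRise <- iRise + 1L
        riseSeg <- c(leftOut[k], min(iRise + pad, p))
        iFall <- e
        while (iFall > p && sm[iFall] < vstop) iFall <- iFall - 1L
        fallSeg <- c(max(iFall - pad, p), rightOut[k])
        for (segEdge in list(list(riseSeg, "rising", 2L * k - 1L),
                             list(fallSeg, "falling", 2L * k))) {
            idx0 <- widenTo6(segEdge[[1]])
            edge <- segEdge[[2]]
            fit <- fitSigmoid(z[idx0[1]:idx0[2]], y[idx0[1]:idx0[2]],
                              edge)
            ## refine on a window sized by the fitted steepness, centered
            ## on the inflection: under strong attenuation the first-pass
            ## segment contains a stretch of the exponential decay ramp,
            ## which drags the inflection inward; a local window balances
            ## edge and ramp and removes most of that bias
            for (it in 1:2) {
                w <- 4 / fit@c + 3 * step
                lo <- which.min(abs(z - (fit@d - w)))
                hi <- which.min(abs(z - (fit@d + w)))
                seg <- if (edge == "rising")
                    c(max(leftOut[k], lo), min(p, hi))
                else c(max(p, lo), min(rightOut[k], hi))
                seg <- widenTo6(seg)
                ref <- tryCatch(
                    fitSigmoid(z[seg[1]:seg[2]], y[seg[1]:seg[2]], edge),
                    error = function(e) NULL)
                if (is.null(ref)) break
                ## the decay ramp can only drag the inflection inward
                ## (toward the peak); a refinement step racing that way is
                ## the ramp taking over the local window, not the edge
                inward <- if (edge == "rising") ref@d - fit@d
                          else fit@d - ref@d
                if (inward > 2 * step) break
                conv <- abs(ref@d - fit@d) < step / 4
                fit <- ref
                if (conv) break
            }
            fits[[segEdge[[3]]]] <- fit
        }
    }
    d <- vapply(fits, function(f) f@d, numeric(1))
    b <- vapply(fits, function(f) f@b, numeric(1))
    if (any(b < 0.025))
        sigmoidError("an edge amplitude is insignificant (< 0.025 of the normalized range)")
    if (any(diff(d) <= 0))
        sigmoidError("fitted inflection points are not in increasing depth order")
    new("InterfaceSet", positions = d,
        provenance = rep("auto", 2L * nLayers), nLayers = nLayers,
        zRange = range(z))
}

#' Set interface positions manually
#'
#' Bypasses the automatic second-derivative test; used when noise or
#' extreme resolution decay corrupts the automatic detection.
#'
#' @param profile A [DepthProfile-class].
#' @param positions Strictly increasing interface depths (um) inside the
#'   scan range; two per traversed layer.
#' @return An [InterfaceSet-class] with provenance `"manual"`.
#' @export
setInterfaces <- function(profile, positions) {
    stopifnot(is(profile, "DepthProfile"))
    positions <- as.numeric(positions)
    if (length(positions) < 2L || length(positions) %% 2L != 0L)
        stop("need an even number (2 per layer) of interface positions")
    if (any(diff(positions) <= 0))
        stop("interface positions must be strictly increasing")
    zr <- range(profile@z)
    if (min(positions) < zr[1] || max(positions) > zr[2])
        stop("interface positions must lie within the scan range")
    new("InterfaceSet", positions = positions,
        provenance = rep("manual", length(positions)),
        nLayers = as.integer(length(positions) / 2L), zRange = zr)
}

#' Export / import interface positions as a two-column text file
#'
#' Columns `layer_index, z_um`; supports the manual workflow of recording
#' interface positions from visual inspection and reusing them.
#'
#' @param interfaces An [InterfaceSet-class].
#' @param path File path.
#' @return `exportInterfaces`: `path` invisibly. `importInterfaces`: an
#'   [InterfaceSet-class] with provenance `"manual"`.
#' @export
exportInterfaces <- function(interfaces, path) {
    stopifnot(is(interfaces, "InterfaceSet"))
    p <- interfaces@positions
    layer <- rep(seq_len(interfaces@nLayers), each = 2L)
    writeLines(c("layer_index,z_um",
                 paste(layer, format(p, digits = 17), sep = ",")), path)
    invisible(path)
}

#' @rdname exportInterfaces
#' @param profile The [DepthProfile-class] the positions belong to (for
#'   range validation).
#' @export
importInterfaces <- function(path, profile) {
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    body <- parseNumericRows(lines[-1], detectDelimiter(lines[1]), 2L, 2L)
    setInterfaces(profile, body[, 2])
}
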