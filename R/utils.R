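## Internal helpers.

#' Min-max normalize a numeric vector
#'
#' Maps the smallest value to 0 and the largest to 1. Idempotent: applying
#' it twice equals applying it once.
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @return List with `values` (normalized vector), `min` and `max` (the
#'   pre-normalization extrema).
#' @export
#' @examples
#' normalizeMinMax(c(2, 4, 6))$values
normalizeMinMax <- function(x) {
    if (!all(is.finite(x)))
        stop("cannot normalize non-finite intensities")
    lo <- min(x)
    hi <- max(x)
    if (hi <= lo)
        stop("cannot min-max normalize a constant profile")
    list(values = (x - lo) / (hi - lo), min = lo, max = hi)
}

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG state (restores .Random.seed, or removes it if it did not exist).
withSeed <- function(seed, expr) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(as.integer(seed))
    expr
}

## Detect the column delimiter of a header line: the candidate that splits
## it into the most fields wins (comma, tab, semicolon).
detectDelimiter <- function(headerLine) {
    cands <- c(",", "\t", ";")
    counts <- vapply(cands, function(d)
        length(strsplit(headerLine, d, fixed = TRUE)[[1]]), integer(1))
    if (max(counts) < 2L)
        stop("cannot detect delimiter (comma/tab/semicolon) in header: ",
             headerLine)
    cands[which.max(counts)]
}

## Split delimited lines into a numeric matrix, reporting the 1-based file
## line number of the first malformed row.
parseNumericRows <- function(lines, delim, ncolExpected, firstLineNo) {
    parts <- strsplit(lines, delim, fixed = TRUE)
    n <- lengths(parts)
    if (any(n != ncolExpected)) {
        bad <- which(n != ncolExpected)[1]
        stop(sprintf("parse error at line %d: expected %d fields, found %d",
                     firstLineNo + bad - 1L, ncolExpected, n[bad]))
    }
    vals <- suppressWarnings(as.numeric(unlist(parts, use.names = FALSE)))
    if (anyNA(vals)) {
        bad <- which(vapply(parts, function(p)
            anyNA(suppressWarnings(as.numeric(p))), logical(1)))[1]
        stop(sprintf("parse error at line %d: non-numeric field",
                     firstLineNo + bad - 1L))
    }
    matrix(vals, nrow = length(parts), ncol = ncolExpected, byrow = TRUE)
}

## Uniform step size of an ascending grid; errors if spacing is not
## uniform within 1% relative tolerance.
uniformStep <- function(z, what = "z") {
    dz <- diff(z)
    if (any(dz <= 0))
        stop(what, " positions must be strictly increasing")
    if (length(dz) > 1L && (max(dz) - min(dz)) / mean(dz) > 0.01)
        stop(what, " spacing must be uniform within 1% relative tolerance")
    mean(dz)
}

## 3-point centered moving average with copied endpoints.
movingAverage3 <- function(x) {
    n <- length(x)
    if (n < 3L) return(x)
    out <- x
    out[2:(n - 1L)] <- (x[1:(n - 2L)] + x[2:(n - 1L)] + x[3:n]) / 3
    out
}
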