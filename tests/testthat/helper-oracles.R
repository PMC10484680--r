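# Independent brute-force oracles the implementation is checked against.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
})

# Enumerates every maximal qualifying bin interval: endpoints above
# threshold, every internal sub-threshold stretch spanning <= maxGap
# bases, not contained in a larger qualifying interval; then drops
# intervals whose span is <= minRun bases. Returns a two-column matrix of
# bin start/end indices.
peakOracle <- function(values, binSize, threshold, maxGap, minRun) {
    n <- length(values)
    above <- values > threshold
    qual <- list()
    for (i in seq_len(n)) {
        for (j in i:n) {
            if (!above[i] || !above[j]) next
            ok <- TRUE
            if (j > i) {
                r <- rle(above[i:j])
                gaps <- r$lengths[!r$values]
                if (length(gaps) > 0L && any(gaps * binSize > maxGap))
                    ok <- FALSE
            }
            if (ok) qual[[length(qual) + 1L]] <- c(i, j)
        }
    }
    if (length(qual) == 0L)
        return(matrix(integer(0), ncol = 2))
    qm <- do.call(rbind, qual)
    maximal <- vapply(seq_len(nrow(qm)), function(k) {
        !any(qm[, 1] <= qm[k, 1] & qm[, 2] >= qm[k, 2] &
             (qm[, 1] < qm[k, 1] | qm[, 2] > qm[k, 2]))
    }, logical(1))
    qm <- qm[maximal, , drop = FALSE]
    span <- (qm[, 2] - qm[, 1] + 1L) * binSize
    qm[span > minRun, , drop = FALSE]
}

peaksToBins <- function(peaks, binSize) {
    if (length(peaks) == 0L)
        return(matrix(integer(0), ncol = 2))
    m <- cbind((start(peaks) - 1L) %/% binSize + 1L,
               end(peaks) %/% binSize)
    storage.mode(m) <- "integer"
    m
}

# Quadratic interval-overlap oracle: every pair with >= 1 base overlap.
overlapOracle <- function(a, b) {
    out <- NULL
    for (i in seq_along(a)) {
        for (j in seq_along(b)) {
            if (as.character(seqnames(a))[i] != as.character(seqnames(b))[j])
                next
            ov <- min(end(a)[i], end(b)[j]) - max(start(a)[i], start(b)[j]) + 1L
            if (ov >= 1L)
                out <- rbind(out, c(i, j, ov))
        }
    }
    if (is.null(out)) matrix(integer(0), ncol = 3) else out
}

# Literal BH step-up definition: adj_(i) = min_{j >= i} n * p_(j) / j.
bhOracle <- function(p) {
    n <- length(p)
    o <- order(p)
    ps <- p[o]
    adj <- numeric(n)
    for (i in seq_len(n))
        adj[i] <- min(1, min(n * ps[i:n] / (i:n)))
    adj[order(o)]
}

randomGRanges <- function(n, chroms = c("chr1", "chr2"), maxPos = 10000L,
                          maxWidth = 500L) {
    starts <- sample(maxPos, n, replace = TRUE)
    GRanges(sample(chroms, n, replace = TRUE),
            IRanges(starts, width = sample(maxWidth, n, replace = TRUE)))
}
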