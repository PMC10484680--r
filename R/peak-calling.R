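#' Threshold/max-gap/min-run peak calling on a fixed-bin track
#'
#' Calls peaks the way interactive genome-browser thresholding does: bins
#' whose value strictly exceeds \code{valueThreshold} are signal; runs of
#' signal bins separated by sub-threshold stretches spanning at most
#' \code{maxGap} bases are bridged into one peak; peaks whose total span is
#' not strictly greater than \code{minRun} bases are discarded. Flanking
#' sub-threshold bins are never part of a peak. Defaults are the SUMO-2/3
#' ChIP-seq settings (threshold 32, max gap 100, min run 100); CTCF
#' CUT&RUN profiles use threshold 360 with max gap and min run of 50.
#'
#' Gap and run lengths are measured in bases, not bins, so parameters are
#' independent of the track's bin size. A bin whose value equals the
#' threshold exactly is below threshold (strict exceedance).
#'
#' @param track a [SignalTrack-class].
#' @param valueThreshold signal threshold in track units (strict \code{>}).
#' @param maxGap largest internal sub-threshold stretch, in bases, that is
#'   still bridged (inclusive).
#' @param minRun peaks must span strictly more than this many bases.
#' @return `GRanges` of peaks sorted by start, with metadata columns
#'   \code{maxValue} and \code{meanValue} (mean over all bins in the peak
#'   span, bridged gap bins included).
#' @examples
#' st <- SignalTrack("chr1", c(40, 40, 0, 0, 40, 40), binSize = 50)
#' callPeaks(st, valueThreshold = 32, maxGap = 100, minRun = 100)
#' @export
callPeaks <- function(track, valueThreshold = 32, maxGap = 100,
                      minRun = 100) {
    stopifnot(is(track, "SignalTrack"))
    v <- trackValues(track)
    if (length(v) == 0L)
        stop("cannot call peaks on an empty track")
    stopifnot(valueThreshold >= 0, maxGap >= 0, minRun >= 0)
    bs <- binSize(track)
    if (maxGap > 0 && bs > maxGap)
        message("bin size (", bs, ") exceeds maxGap (", maxGap,
                "): gap bridging is impossible at this resolution")

    above <- v > valueThreshold
    if (!any(above))
        return(GRanges())
    r <- rle(above)
    nrun <- length(r$lengths)
    runEnd <- cumsum(r$lengths)
    runStart <- runEnd - r$lengths + 1L
    sigRuns <- which(r$values)

    # group consecutive signal runs whose separating gap is <= maxGap bases
    grp <- integer(length(sigRuns))
    g <- 1L
    grp[1L] <- 1L
    if (length(sigRuns) > 1L) {
        for (i in 2L:length(sigRuns)) {
            gapBins <- runStart[sigRuns[i]] - runEnd[sigRuns[i - 1L]] - 1L
            if (gapBins * bs > maxGap)
                g <- g + 1L
            grp[i] <- g
        }
    }

    starts <- ends <- integer(0)
    maxv <- meanv <- numeric(0)
    for (k in unique(grp)) {
        members <- sigRuns[grp == k]
        b1 <- runStart[members[1L]]
        b2 <- runEnd[members[length(members)]]
        span <- (b2 - b1 + 1L) * bs
        if (span <= minRun)
            next
        starts <- c(starts, b1)
        ends <- c(ends, b2)
        maxv <- c(maxv, max(v[b1:b2]))
        meanv <- c(meanv, mean(v[b1:b2]))
    }
    if (length(starts) == 0L)
        return(GRanges())
    o <- trackOrigin(track)
    GRanges(trackChrom(track),
            IRanges(start = o + (starts - 1L) * bs + 1L,
                    end = o + ends * bs),
            maxValue = maxv, meanValue = meanv)
}

#' Summarize a peak set
#'
#' @param peaks `GRanges` from [callPeaks()].
#' @return list with \code{count}, \code{meanIntensity} (mean of per-peak
#'   \code{meanValue}; \code{NA} when there are no peaks) and
#'   \code{undefined} flagging the empty case.
#' @export
peakSummary <- function(peaks) {
    if (length(peaks) == 0L)
        return(list(count = 0L, meanIntensity = NA_real_, undefined = TRUE))
    list(count = length(peaks),
         meanIntensity = mean(mcols(peaks)$meanValue),
         undefined = FALSE)
}
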