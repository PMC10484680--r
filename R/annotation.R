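#' Define promoter intervals upstream of TSSs
#'
#' Promoters are the 2 kb immediately upstream of each transcription start
#' site. In 0-based half-open coordinates a plus-strand gene with TSS t
#' yields \code{[t - upstream, t)} and a minus-strand gene \code{[t,
#' t + upstream)}. Promoters are kept for every annotated gene regardless
#' of chromatin marks; overlap with an H3K4me3 peak (the promoter-proxy
#' mark) is recorded in the \code{h3k4me3Supported} flag. Promoters running
#' off the chromosome start (or past a known chromosome end) are clipped
#' and flagged.
#'
#' @param genes `GRanges` of genes with strand and a \code{gene_id}
#'   metadata column; the TSS is the 5' end of each range.
#' @param h3k4me3Peaks optional `GRanges` of H3K4me3 peaks.
#' @param upstream promoter extent in bases upstream of the TSS.
#' @return `GRanges` of promoters with \code{gene_id},
#'   \code{h3k4me3Supported} and \code{clipped} metadata columns.
#' @examples
#' g <- GenomicRanges::GRanges("chr1:5001-6000:+", gene_id = "g1")
#' definePromoters(g)  # 1-based 3001-5000, i.e. [3000, 5000) half-open
#' @export
definePromoters <- function(genes, h3k4me3Peaks = NULL, upstream = 2000) {
    stopifnot(is(genes, "GRanges"), upstream > 0)
    if (!"gene_id" %in% colnames(mcols(genes)))
        stop("'genes' must carry a 'gene_id' metadata column")
    str <- as.character(strand(genes))
    if (any(str == "*"))
        stop("every gene needs a known strand to orient its promoter")
    # 1-based inclusive coordinates of [t - up, t) / [t, t + up)
    pstart <- ifelse(str == "+", start(genes) - upstream, end(genes))
    pend <- ifelse(str == "+", start(genes) - 1L, end(genes) + upstream - 1L)
    clipped <- pstart < 1L
    pstart <- pmax(pstart, 1L)
    sl <- GenomeInfoDb::seqlengths(genes)
    if (any(!is.na(sl))) {
        lim <- sl[as.character(seqnames(genes))]
        over <- !is.na(lim) & pend > lim
        clipped <- clipped | over
        pend <- ifelse(over, lim, pend)
    }
    if (any(pend < pstart))
        stop("promoter collapsed to zero length; TSS at chromosome edge")
    prom <- GRanges(seqnames(genes), IRanges(pstart, pend),
                    strand = strand(genes))
    GenomeInfoDb::seqlevels(prom) <- GenomeInfoDb::seqlevels(genes)
    GenomeInfoDb::seqlengths(prom) <- sl
    mcols(prom)$gene_id <- mcols(genes)$gene_id
    mcols(prom)$clipped <- clipped
    mcols(prom)$h3k4me3Supported <- if (is.null(h3k4me3Peaks))
        NA else GenomicRanges::countOverlaps(prom, h3k4me3Peaks) > 0L
    prom
}

#' Candidate enhancers: H3K4me1 regions outside promoters
#'
#' H3K4me1 peaks that do not correspond to any annotated promoter are
#' candidate enhancers. A peak overlapping a promoter by one base or more
#' is excluded entirely (peaks are treated as atomic, not trimmed).
#'
#' @param h3k4me1Peaks `GRanges` of H3K4me1 peaks.
#' @param promoters `GRanges` of promoters.
#' @return the subset of \code{h3k4me1Peaks} with no promoter overlap.
#' @export
defineEnhancers <- function(h3k4me1Peaks, promoters) {
    stopifnot(is(h3k4me1Peaks, "GRanges"), is(promoters, "GRanges"))
    keep <- GenomicRanges::countOverlaps(h3k4me1Peaks, promoters,
                                         ignore.strand = TRUE) == 0L
    h3k4me1Peaks[keep]
}

#' Infer element activity from H3K27ac
#'
#' A regulatory element is called active when it overlaps at least one
#' H3K27ac peak by at least one base (half-open adjacency does not count).
#'
#' @param elements `GRanges` of promoters or candidate enhancers.
#' @param h3k27acPeaks `GRanges` of H3K27ac peaks.
#' @return \code{elements} with a logical \code{active} metadata column.
#' @export
classifyActivity <- function(elements, h3k27acPeaks) {
    stopifnot(is(elements, "GRanges"), is(h3k27acPeaks, "GRanges"))
    mcols(elements)$active <-
        GenomicRanges::countOverlaps(elements, h3k27acPeaks,
                                     ignore.strand = TRUE) > 0L
    elements
}

# mean binned signal in the window [anchor - flank, anchor + flank),
# strand-oriented; NULL when the window exits the track
.windowSignal <- function(track, pos0, strandChar, flank, bin) {
    v <- trackValues(track)
    bs <- binSize(track)
    o <- trackOrigin(track)
    lo <- pos0 - flank            # 0-based inclusive
    hi <- pos0 + flank - 1L       # 0-based inclusive
    if (lo < o || hi >= o + length(v) * bs)
        return(NULL)
    bases <- lo:hi
    idx <- (bases - o) %/% bs + 1L
    w <- v[idx]
    if (strandChar == "-")
        w <- rev(w)
    colMeans(matrix(w, nrow = bin))
}

#' Metaprofile of a signal track around anchor positions
#'
#' Averages a track in strand-oriented windows of \code{2 * flank} bases
#' centred on anchors (typically TSSs), binned at \code{bin} bases. Anchors
#' whose window leaves the covered part of the chromosome are dropped and
#' counted.
#'
#' @param tracks named list of [SignalTrack-class] keyed by chromosome (a
#'   single \code{SignalTrack} is accepted).
#' @param anchors `GRanges` of single-base anchor positions with strand.
#' @param flank half-window size in bases; must be divisible by \code{bin}.
#' @param bin profile bin width in bases.
#' @return list with \code{profile} (numeric vector of length
#'   \code{2*flank/bin}), \code{positions} (bin centres relative to the
#'   anchor), \code{anchorsUsed} and \code{anchorsDropped}.
#' @export
metaprofile <- function(tracks, anchors, flank = 2000, bin = 50) {
    if (is(tracks, "SignalTrack"))
        tracks <- stats::setNames(list(tracks), trackChrom(tracks))
    stopifnot(flank > 0, bin > 0, flank %% bin == 0)
    nb <- 2L * flank %/% bin
    acc <- numeric(nb)
    used <- dropped <- 0L
    for (i in seq_along(anchors)) {
        chr <- as.character(seqnames(anchors))[i]
        tr <- tracks[[chr]]
        if (is.null(tr)) {
            dropped <- dropped + 1L
            next
        }
        w <- .windowSignal(tr, start(anchors)[i] - 1L,
                           as.character(strand(anchors))[i], flank, bin)
        if (is.null(w)) {
            dropped <- dropped + 1L
        } else {
            acc <- acc + w
            used <- used + 1L
        }
    }
    if (used == 0L)
        stop("no usable anchors: every window exits the track ",
             "(", dropped, " dropped)")
    list(profile = acc / used,
         positions = seq(-flank + bin / 2, flank - bin / 2, by = bin),
         anchorsUsed = used, anchorsDropped = dropped)
}

#' Signal heatmap matrix over regions, ranked by one track
#'
#' Builds the matrix behind ranked signal heatmaps: one row per region,
#' columns the binned window signal of each track around the region
#' centre, rows ordered by decreasing mean signal of \code{rankBy}
#' (stable sort, so ties preserve input order).
#'
#' @param trackSets named list; each element is a track set as accepted by
#'   [metaprofile()].
#' @param regions non-empty `GRanges`; windows are centred on region
#'   midpoints (strand-oriented).
#' @param rankBy name of the element of \code{trackSets} used for ranking.
#' @param flank,bin window geometry, as in [metaprofile()].
#' @return list with \code{matrix} (rows = retained regions in ranked
#'   order, columns \code{<track>.<bin>}), \code{order} (indices into
#'   \code{regions}), and \code{dropped} (regions whose window left the
#'   track).
#' @export
heatmapMatrix <- function(trackSets, regions, rankBy, flank = 2000,
                          bin = 50) {
    stopifnot(length(regions) > 0L, rankBy %in% names(trackSets))
    trackSets <- lapply(trackSets, function(ts) {
        if (is(ts, "SignalTrack"))
            stats::setNames(list(ts), trackChrom(ts)) else ts
    })
    nb <- 2L * flank %/% bin
    mid <- (start(regions) + end(regions)) %/% 2L
    rows <- list()
    keptIdx <- integer(0)
    for (i in seq_along(regions)) {
        chr <- as.character(seqnames(regions))[i]
        str <- as.character(strand(regions))[i]
        row <- unlist(lapply(names(trackSets), function(nm) {
            tr <- trackSets[[nm]][[chr]]
            if (is.null(tr)) return(NULL)
            .windowSignal(tr, mid[i] - 1L, str, flank, bin)
        }))
        if (is.null(row) || length(row) != nb * length(trackSets))
            next
        rows[[length(rows) + 1L]] <- row
        keptIdx <- c(keptIdx, i)
    }
    if (length(rows) == 0L)
        stop("no region window fits inside the tracks")
    m <- do.call(rbind, rows)
    colnames(m) <- as.vector(vapply(names(trackSets), function(nm)
        sprintf("%s.%d", nm, seq_len(nb)), character(nb)))
    rankCols <- grep(paste0("^", rankBy, "\\."), colnames(m))
    o <- order(-rowMeans(m[, rankCols, drop = FALSE]))
    list(matrix = m[o, , drop = FALSE],
         order = keptIdx[o],
         dropped = setdiff(seq_along(regions), keptIdx))
}
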