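#' Normalized per-fragment contact scores for one 4C replicate
#'
#' Identifies the viewpoint fragment, flags it and its
#' \code{exclusionWindow} neighbours on each side as viewpoint-proximal
#' (undigested / self-ligation artifacts), and scales the remaining raw
#' counts to reads per million included reads. Excluded fragments carry
#' no score. Blind fragments (no internal second-enzyme site) are kept in
#' the normalization universe by default; set \code{includeBlind = FALSE}
#' to exclude them as well.
#'
#' @param counts integer per-fragment counts (from [assignToFragments()]).
#' @param map a [FragmentMap-class].
#' @param viewpoint `GRanges` locating the viewpoint (any overlap with a
#'   fragment identifies it).
#' @param exclusionWindow fragments masked on each side of the viewpoint.
#' @param includeBlind keep blind fragments in the normalization universe.
#' @param replicate,condition labels stored in the profile.
#' @return a [ViewpointProfile-class].
#' @export
normalizeProfile <- function(counts, map, viewpoint, exclusionWindow = 2L,
                             includeBlind = TRUE, replicate = "rep1",
                             condition = "mock") {
    stopifnot(is(map, "FragmentMap"), is(viewpoint, "GRanges"))
    fr <- fragments(map)
    if (length(counts) != length(fr))
        stop("counts length does not match the fragment map")
    hits <- GenomicRanges::findOverlaps(viewpoint, fr, ignore.strand = TRUE)
    if (length(hits) == 0L)
        stop("viewpoint does not overlap any restriction fragment")
    vp <- S4Vectors::subjectHits(hits)[1L]
    vpChr <- as.character(seqnames(fr))[vp]
    sameChr <- as.character(seqnames(fr)) == vpChr
    excluded <- sameChr &
        abs(mcols(fr)$fragId - mcols(fr)$fragId[vp]) <= exclusionWindow
    if (!includeBlind)
        excluded <- excluded | mcols(fr)$blind
    total <- sum(counts[!excluded])
    if (total == 0L)
        stop("no reads on included fragments; cannot normalize")
    score <- counts / total * 1e6
    score[excluded] <- NA_real_
    new("ViewpointProfile",
        fragments = fr,
        counts = as.integer(counts),
        score = score,
        excluded = excluded,
        viewpointIndex = as.integer(vp),
        replicate = as.character(replicate),
        condition = as.character(condition))
}

#' Binned signal track from a viewpoint profile
#'
#' Spreads each fragment's normalized score uniformly over its bases and
#' averages per \code{bin}-base bin (the per-10-bp representation used to
#' display 4C interaction frequencies). Excluded fragments contribute
#' zero.
#'
#' @param profile a [ViewpointProfile-class].
#' @param bin bin width in bases.
#' @return named list of [SignalTrack-class], one per chromosome.
#' @export
binnedTrack <- function(profile, bin = 10L) {
    stopifnot(is(profile, "ViewpointProfile"), bin > 0)
    fr <- profile@fragments
    sc <- profile@score
    sc[is.na(sc)] <- 0
    cov <- GenomicRanges::coverage(fr, weight = sc)
    out <- list()
    for (chr in names(cov)) {
        rl <- cov[[chr]]
        len <- length(rl)
        if (len == 0L) {
            out[[chr]] <- SignalTrack(chr, numeric(0), binSize = bin)
            next
        }
        starts <- seq.int(1L, len, by = bin)
        v <- IRanges::viewMeans(IRanges::Views(
            rl, start = starts, end = pmin(starts + bin - 1L, len)))
        out[[chr]] <- SignalTrack(chr, as.numeric(v), binSize = bin)
    }
    out
}

#' Write a viewpoint profile as TSV
#'
#' @param profile a [ViewpointProfile-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeProfileTsv <- function(profile, path) {
    fr <- profile@fragments
    df <- data.frame(
        chrom = as.character(seqnames(fr)),
        start = start(fr) - 1L,  # 0-based half-open on disk
        end = end(fr),
        fragId = mcols(fr)$fragId,
        blind = mcols(fr)$blind,
        excluded = profile@excluded,
        count = profile@counts,
        score = profile@score,
        condition = profile@condition,
        replicate = profile@replicate)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
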