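# Default viewpoint amplification (capture) sequence used by the 4C assay.
FOURC_CAPTURE <- "CGTGACGCACGGAAACGTC"

#' Trim-capture filtering of 4C reads
#'
#' Only reads containing the capture (viewpoint amplification) sequence
#' are kept. Retained reads are trimmed so that only the sequence
#' downstream of the first-enzyme cut site remains: everything up to and
#' including the first \code{site1} occurrence after the capture is
#' removed, leaving the ligated partner sequence. Retained reads whose
#' remainder is empty (no junction site or nothing beyond it) are dropped
#' and counted separately.
#'
#' @param reads `DNAStringSet` (or character vector) of raw reads.
#' @param capture capture sequence (at least 8 bases).
#' @param site1 first-enzyme recognition sequence at the ligation
#'   junction.
#' @return list with \code{trimmed} (`DNAStringSet`), \code{kept},
#'   \code{dropped} (no capture), \code{emptyAfterTrim}, and
#'   \code{keptIndex} (indices of trimmed reads in the input). The
#'   identity \code{kept + dropped + emptyAfterTrim == length(reads)}
#'   always holds.
#' @export
trimCapture <- function(reads, capture = FOURC_CAPTURE, site1 = "CATG") {
    if (is.character(reads))
        reads <- Biostrings::DNAStringSet(reads)
    stopifnot(is(reads, "DNAStringSet"))
    if (nchar(capture) < 8L)
        stop("capture sequence must be at least 8 bases")
    n <- length(reads)
    if (n == 0L)
        return(list(trimmed = Biostrings::DNAStringSet(), kept = 0L,
                    dropped = 0L, emptyAfterTrim = 0L,
                    keptIndex = integer(0)))
    capHits <- Biostrings::vmatchPattern(capture, reads)
    capEndL <- Biostrings::endIndex(capHits)
    capEnd <- vapply(capEndL, function(e)
        if (length(e) == 0L) NA_integer_ else e[1L], integer(1))
    hasCapture <- !is.na(capEnd)
    siteHits <- Biostrings::vmatchPattern(site1, reads)
    siteStartL <- Biostrings::startIndex(siteHits)
    wid <- Biostrings::width(reads)
    siteLen <- nchar(site1)
    from <- rep(NA_integer_, n)
    for (i in which(hasCapture)) {
        st <- siteStartL[[i]]
        ok <- st > capEnd[i]
        if (any(ok))
            from[i] <- st[which(ok)[1L]] + siteLen
    }
    usable <- hasCapture & !is.na(from) & from <= wid
    trimmed <- Biostrings::subseq(reads[usable], start = from[usable])
    if (!is.null(names(reads)))
        names(trimmed) <- names(reads)[usable]
    list(trimmed = trimmed,
         kept = sum(usable),
         dropped = sum(!hasCapture),
         emptyAfterTrim = sum(hasCapture & !usable),
         keptIndex = which(usable))
}

#' Exact-match placement of trimmed 4C reads
#'
#' Places each read by exact match of its 5' \code{k} bases against the
#' (forward strand of the) genome, the placement contract that replaces a
#' short-read aligner on synthetic genomes with unique fragment-start
#' k-mers. Reads matching at several positions are ambiguous; reads
#' shorter than \code{k} or with no match are unplaced. Both groups are
#' counted and excluded.
#'
#' @param reads trimmed `DNAStringSet`.
#' @param genome `DNAStringSet` of chromosomes.
#' @param k prefix length used for placement.
#' @param maxAmbiguousFraction abort threshold: when more than this
#'   fraction of reads is ambiguous the genome is too repetitive for
#'   \code{k} and the function stops with guidance to increase \code{k}.
#' @return list with \code{placements} (`GRanges` of single-base start
#'   positions, metadata column \code{readIndex}), \code{nPlaced},
#'   \code{nUnplaced}, \code{nAmbiguous}.
#' @export
mapReads <- function(reads, genome, k = 20L,
                     maxAmbiguousFraction = 0.5) {
    if (is.character(reads))
        reads <- Biostrings::DNAStringSet(reads)
    if (is.character(genome))
        genome <- Biostrings::DNAStringSet(genome)
    stopifnot(is(reads, "DNAStringSet"), is(genome, "DNAStringSet"),
              k >= 8L)
    n <- length(reads)
    wid <- Biostrings::width(reads)
    longEnough <- wid >= k
    idx <- which(longEnough)
    hitChr <- rep(NA_character_, n)
    hitPos <- rep(NA_integer_, n)
    nHits <- integer(n)
    if (length(idx) > 0L) {
        prefixes <- Biostrings::subseq(reads[idx], 1L, k)
        pd <- Biostrings::PDict(prefixes)
        for (chr in names(genome)) {
            m <- Biostrings::matchPDict(pd, genome[[chr]])
            cnt <- S4Vectors::elementNROWS(m)
            starts <- Biostrings::startIndex(m)
            first <- vapply(starts, function(s)
                if (length(s) > 0L) s[1L] else NA_integer_, integer(1))
            take <- cnt > 0L & nHits[idx] == 0L
            hitChr[idx[take]] <- chr
            hitPos[idx[take]] <- first[take]
            nHits[idx] <- nHits[idx] + cnt
        }
    }
    placed <- nHits == 1L
    ambiguous <- nHits > 1L
    if (n > 0L && sum(ambiguous) / n > maxAmbiguousFraction)
        stop("genome too repetitive for k = ", k, ": ",
             sum(ambiguous), "/", n, " reads are ambiguous; ",
             "increase k for unique placement")
    pl <- GRanges(hitChr[placed], IRanges(hitPos[placed], width = 1L))
    GenomeInfoDb::seqlevels(pl) <- names(genome)
    GenomeInfoDb::seqlengths(pl) <-
        stats::setNames(Biostrings::width(genome), names(genome))
    mcols(pl)$readIndex <- which(placed)
    list(placements = pl,
         nPlaced = sum(placed),
         nUnplaced = sum(!placed & !ambiguous),
         nAmbiguous = sum(ambiguous))
}

#' Assign read placements to restriction fragments
#'
#' Each placement increments exactly one fragment: the fragment containing
#' its start base. Because fragments tile the chromosome half-open
#' boundaries resolve to the downstream fragment automatically.
#'
#' @param placements `GRanges` of single-base placements
#'   (from [mapReads()]).
#' @param map a [FragmentMap-class].
#' @return integer vector of per-fragment counts (length = number of
#'   fragments); the sum equals the number of placements.
#' @export
assignToFragments <- function(placements, map) {
    stopifnot(is(placements, "GRanges"), is(map, "FragmentMap"))
    fr <- fragments(map)
    hits <- GenomicRanges::findOverlaps(placements, fr,
                                        ignore.strand = TRUE)
    if (length(unique(S4Vectors::queryHits(hits))) < length(placements))
        stop("some placements fall outside the fragment map")
    counts <- tabulate(S4Vectors::subjectHits(hits), nbins = length(fr))
    stopifnot(sum(counts) == length(placements))
    names(counts) <- sprintf("frag%05d", mcols(fr)$fragId)
    counts
}
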