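#' In-silico restriction digest of a genome
#'
#' Extrapolates the restriction fragment map from a genome sequence using
#' the recognition sequence of the first restriction enzyme: the genome is
#' cut at every occurrence of \code{site1} (overlapping occurrences
#' included; every position is scanned) and fragments are the intervals
#' between consecutive cut positions plus the chromosome ends. The default
#' chemistry is NlaIII-style \code{CATG} cutting after the site (3' side)
#' and DpnII-style \code{GATC} cutting before the site; both sites and cut
#' offsets are configurable. A fragment is flagged \code{blind} when no
#' \code{site2} occurrence lies fully inside it.
#'
#' @param genome `DNAStringSet` (or named character vector) of chromosome
#'   sequences.
#' @param site1 first-enzyme recognition sequence (fragments the genome).
#' @param site2 second-enzyme recognition sequence (blind-fragment flag).
#' @param cutOffset1 bases after the start of a \code{site1} match at
#'   which the cut falls; the default \code{nchar(site1)} cuts after the
#'   site. Use 0 for a 5'-side cutter.
#' @return a [FragmentMap-class].
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "TTCATGAAACATGTT"))
#' fragments(digestGenome(g))  # 1-6, 7-13, 14-15
#' @export
digestGenome <- function(genome, site1 = "CATG", site2 = "GATC",
                         cutOffset1 = nchar(site1)) {
    if (is.character(genome))
        genome <- Biostrings::DNAStringSet(genome)
    stopifnot(is(genome, "DNAStringSet"), !is.null(names(genome)))
    for (s in c(site1, site2))
        if (!nzchar(s) || grepl("[^ACGT]", s))
            stop("enzyme sites must be non-empty, non-degenerate A/C/G/T ",
                 "sequences, got '", s, "'")
    stopifnot(cutOffset1 >= 0, cutOffset1 <= nchar(site1))

    grs <- list()
    sl <- stats::setNames(Biostrings::width(genome), names(genome))
    for (chr in names(genome)) {
        seqc <- genome[[chr]]
        len <- length(seqc)
        m1 <- Biostrings::matchPattern(site1, seqc)
        # 1-based start of the fragment downstream of each cut
        cuts <- Biostrings::start(m1) + cutOffset1
        cuts <- sort(unique(cuts[cuts > 1L & cuts <= len]))
        starts <- c(1L, cuts)
        ends <- c(cuts - 1L, len)
        fr <- GRanges(chr, IRanges(starts, ends))
        m2 <- Biostrings::matchPattern(site2, seqc)
        if (length(m2) > 0L) {
            g2 <- GRanges(chr, IRanges(Biostrings::start(m2),
                                       Biostrings::end(m2)))
            # a fragment is sighted only by fully-contained site2 occurrences
            contained <- GenomicRanges::findOverlaps(g2, fr, type = "within")
            blind <- rep(TRUE, length(fr))
            blind[unique(S4Vectors::subjectHits(contained))] <- FALSE
        } else {
            blind <- rep(TRUE, length(fr))
        }
        mcols(fr)$blind <- blind
        grs[[chr]] <- fr
    }
    all <- suppressWarnings(do.call(c, unname(grs)))
    GenomeInfoDb::seqlevels(all) <- names(genome)
    GenomeInfoDb::seqlengths(all) <- sl
    mcols(all)$fragId <- seq_along(all)
    new("FragmentMap", fragments = all, site1 = site1, site2 = site2)
}

#' Extract fragment sequences from a genome
#'
#' Mostly a testing aid: concatenating the returned sequences per
#' chromosome must reconstruct the genome exactly.
#'
#' @param map a [FragmentMap-class].
#' @param genome the `DNAStringSet` the map was derived from.
#' @return `DNAStringSet` of fragment sequences in map order.
#' @export
fragmentSequences <- function(map, genome) {
    stopifnot(is(map, "FragmentMap"))
    if (is.character(genome))
        genome <- Biostrings::DNAStringSet(genome)
    fr <- fragments(map)
    out <- Biostrings::DNAStringSet(vapply(seq_along(fr), function(i) {
        as.character(Biostrings::subseq(
            genome[[as.character(seqnames(fr))[i]]],
            start(fr)[i], end(fr)[i]))
    }, character(1)))
    names(out) <- sprintf("frag%05d", mcols(fr)$fragId)
    out
}

#' Write a fragment map as BED with flags in the name field
#'
#' @param map a [FragmentMap-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFragmentMapBed <- function(map, path) {
    fr <- fragments(map)
    out <- granges(fr)
    mcols(out)$name <- sprintf("frag%05d|%s", mcols(fr)$fragId,
                               ifelse(mcols(fr)$blind, "blind", "cut"))
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}
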