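#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

#' SignalTrack: fixed-bin coverage along one chromosome
#'
#' A \code{SignalTrack} holds one non-negative numeric value per fixed-width
#' bin along a single chromosome, the substrate of threshold peak calling,
#' metaprofiles and heatmap matrices. Bins start at \code{origin} (a 0-based
#' base offset, usually 0) and are \code{binSize} bases wide.
#'
#' @slot chromosome single chromosome name.
#' @slot binSize bin width in bases (> 0).
#' @slot origin 0-based base offset of the first bin.
#' @slot values one non-negative finite value per bin.
#'
#' @examples
#' st <- SignalTrack("chr1", c(0, 40, 40, 0), binSize = 50)
#' trackValues(st)
#' @export
setClass("SignalTrack",
    representation(
        chromosome = "character",
        binSize    = "integer",
        origin     = "integer",
        values     = "numeric"
    )
)

setValidity("SignalTrack", function(object) {
    msg <- NULL
    if (length(object@chromosome) != 1L || is.na(object@chromosome) ||
        !nzchar(object@chromosome))
        msg <- c(msg, "'chromosome' must be a single non-empty name")
    if (length(object@binSize) != 1L || is.na(object@binSize) ||
        object@binSize <= 0L)
        msg <- c(msg, "'binSize' must be a single positive integer")
    if (length(object@origin) != 1L || is.na(object@origin) ||
        object@origin < 0L)
        msg <- c(msg, "'origin' must be a single non-negative integer")
    if (anyNA(object@values) || any(!is.finite(object@values)))
        msg <- c(msg, "'values' must be finite and non-missing")
    else if (any(object@values < 0))
        msg <- c(msg, "'values' must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' @param chromosome chromosome name.
#' @param values numeric vector, one value per bin.
#' @param binSize bin width in bases.
#' @param origin 0-based offset of the first bin.
#' @rdname SignalTrack-class
#' @export
SignalTrack <- function(chromosome, values, binSize = 50L, origin = 0L) {
    new("SignalTrack",
        chromosome = as.character(chromosome),
        binSize = as.integer(binSize),
        origin = as.integer(origin),
        values = as.numeric(values))
}

#' FragmentMap: in-silico restriction digest of a genome
#'
#' Ordered tiling of every chromosome into restriction fragments delimited
#' by the first-enzyme recognition site (NlaIII-style \code{CATG} by
#' default). Fragments carry a \code{blind} flag: \code{TRUE} when no
#' second-enzyme site (DpnII-style \code{GATC}) lies fully inside the
#' fragment. The fragment map is the coordinate system of all 4C-seq
#' quantification.
#'
#' @slot fragments \code{GRanges} tiling each chromosome without gaps or
#'   overlaps, with metadata columns \code{fragId} (1-based index in genome
#'   order) and \code{blind}.
#' @slot site1 first (fragmenting) enzyme recognition sequence.
#' @slot site2 second enzyme recognition sequence (blind-fragment flag).
#'
#' @seealso [digestGenome()]
#' @export
setClass("FragmentMap",
    representation(
        fragments = "GRanges",
        site1     = "character",
        site2     = "character"
    )
)

setValidity("FragmentMap", function(object) {
    msg <- NULL
    fr <- object@fragments
    if (!all(c("fragId", "blind") %in% colnames(mcols(fr))))
        msg <- c(msg, "fragments need 'fragId' and 'blind' metadata columns")
    for (site in c(object@site1, object@site2)) {
        if (length(site) != 1L || !nzchar(site) ||
            grepl("[^ACGT]", site))
            msg <- c(msg, "enzyme sites must be non-empty A/C/G/T strings")
    }
    sl <- GenomeInfoDb::seqlengths(fr)
    for (chr in GenomeInfoDb::seqlevels(fr)) {
        f <- fr[as.character(seqnames(fr)) == chr]
        if (length(f) == 0L) next
        o <- order(start(f))
        f <- f[o]
        if (start(f)[1L] != 1L)
            msg <- c(msg, sprintf("fragments on %s do not start at base 1", chr))
        if (length(f) > 1L &&
            !all(start(f)[-1L] == end(f)[-length(f)] + 1L))
            msg <- c(msg, sprintf("fragments on %s have gaps or overlaps", chr))
        if (!is.na(sl[chr]) && end(f)[length(f)] != sl[chr])
            msg <- c(msg, sprintf("fragments on %s do not reach chromosome end", chr))
    }
    if (is.null(msg)) TRUE else msg
})

#' ViewpointProfile: per-fragment 4C-seq contact profile for one replicate
#'
#' Stores raw read counts per restriction fragment together with normalized
#' contact scores (reads per million included reads). The viewpoint fragment
#' and its \code{exclusionWindow} neighbours are flagged \code{excluded} and
#' carry no score; scores over included fragments sum to 1e6.
#'
#' @slot fragments fragment `GRanges` (as in the [FragmentMap-class]).
#' @slot counts raw read count per fragment (non-negative integers).
#' @slot score normalized score per fragment; \code{NA} on excluded fragments.
#' @slot excluded logical flag per fragment (viewpoint-proximal or blind
#'   when blind fragments are excluded from the normalization universe).
#' @slot viewpointIndex index of the viewpoint fragment.
#' @slot replicate replicate identifier.
#' @slot condition condition label.
#'
#' @seealso [normalizeProfile()], [callInteractions()]
#' @export
setClass("ViewpointProfile",
    representation(
        fragments      = "GRanges",
        counts         = "integer",
        score          = "numeric",
        excluded       = "logical",
        viewpointIndex = "integer",
        replicate      = "character",
        condition      = "character"
    )
)

setValidity("ViewpointProfile", function(object) {
    msg <- NULL
    n <- length(object@fragments)
    if (length(object@counts) != n || length(object@score) != n ||
        length(object@excluded) != n)
        msg <- c(msg, "counts, score and excluded must match fragment count")
    if (any(object@counts < 0L, na.rm = TRUE))
        msg <- c(msg, "counts must be non-negative")
    if (length(object@viewpointIndex) != 1L ||
        object@viewpointIndex < 1L || object@viewpointIndex > n)
        msg <- c(msg, "viewpointIndex out of range")
    inc <- !object@excluded
    if (any(!is.na(object@score[object@excluded])))
        msg <- c(msg, "excluded fragments must carry NA scores")
    if (sum(inc) > 0L) {
        tot <- sum(object@score[inc])
        if (is.na(tot) || abs(tot - 1e6) > 1)
            msg <- c(msg, "included scores must sum to 1e6 (+/- 1)")
    }
    if (is.null(msg)) TRUE else msg
})
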