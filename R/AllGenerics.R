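# Accessor generics and show methods for the package's S4 containers.

#' @rdname SignalTrack-class
#' @param x,object a \code{SignalTrack}, \code{FragmentMap} or
#'   \code{ViewpointProfile}.
#' @export
setGeneric("trackChrom", function(x) standardGeneric("trackChrom"))

#' @rdname SignalTrack-class
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' @rdname SignalTrack-class
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname SignalTrack-class
#' @export
setGeneric("trackOrigin", function(x) standardGeneric("trackOrigin"))

#' @rdname SignalTrack-class
#' @export
setGeneric("binRanges", function(x) standardGeneric("binRanges"))

#' @rdname FragmentMap-class
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' @rdname FragmentMap-class
#' @export
setGeneric("enzymeSites", function(x) standardGeneric("enzymeSites"))

#' @rdname ViewpointProfile-class
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))

#' @rdname ViewpointProfile-class
#' @export
setGeneric("profileScores", function(x) standardGeneric("profileScores"))

#' @rdname ViewpointProfile-class
#' @export
setGeneric("excludedFragments", function(x) standardGeneric("excludedFragments"))

#' @rdname ViewpointProfile-class
#' @export
setGeneric("viewpointIndex", function(x) standardGeneric("viewpointIndex"))

#' @rdname ViewpointProfile-class
#' @export
setGeneric("profileCondition", function(x) standardGeneric("profileCondition"))

#' @rdname ViewpointProfile-class
#' @export
setGeneric("profileReplicate", function(x) standardGeneric("profileReplicate"))

#' @rdname SignalTrack-class
#' @export
setMethod("trackChrom", "SignalTrack", function(x) x@chromosome)

#' @rdname SignalTrack-class
#' @export
setMethod("trackValues", "SignalTrack", function(x) x@values)

#' @rdname SignalTrack-class
#' @export
setMethod("binSize", "SignalTrack", function(x) x@binSize)

#' @rdname SignalTrack-class
#' @export
setMethod("trackOrigin", "SignalTrack", function(x) x@origin)

#' @rdname SignalTrack-class
#' @export
setMethod("length", "SignalTrack", function(x) length(x@values))

#' @describeIn SignalTrack-class bins as a 1-based \code{GRanges} with a
#'   \code{score} column.
#' @export
setMethod("binRanges", "SignalTrack", function(x) {
    n <- length(x@values)
    if (n == 0L)
        return(GRanges())
    GRanges(x@chromosome,
            IRanges(start = x@origin + (seq_len(n) - 1L) * x@binSize + 1L,
                    width = x@binSize),
            score = x@values)
})

setMethod("show", "SignalTrack", function(object) {
    n <- length(object@values)
    cat("SignalTrack on", object@chromosome,
        sprintf("(%d bins x %d bp, origin %d)\n",
                n, object@binSize, object@origin))
    if (n > 0L)
        cat(sprintf("  values: min %.3g, mean %.3g, max %.3g\n",
                    min(object@values), mean(object@values),
                    max(object@values)))
})

#' @rdname FragmentMap-class
#' @export
setMethod("fragments", "FragmentMap", function(x) x@fragments)

#' @describeIn FragmentMap-class the two recognition sequences as a named
#'   character vector.
#' @export
setMethod("enzymeSites", "FragmentMap",
          function(x) c(site1 = x@site1, site2 = x@site2))

#' @rdname FragmentMap-class
#' @export
setMethod("length", "FragmentMap", function(x) length(x@fragments))

setMethod("show", "FragmentMap", function(object) {
    fr <- object@fragments
    cat(sprintf("FragmentMap: %d fragments on %d sequence(s) [%s / %s]\n",
                length(fr), length(GenomeInfoDb::seqlevels(fr)),
                object@site1, object@site2))
    if (length(fr) > 0L)
        cat(sprintf("  widths: min %d, median %d, max %d; blind: %d\n",
                    min(width(fr)), as.integer(stats::median(width(fr))),
                    max(width(fr)), sum(mcols(fr)$blind)))
})

#' @rdname ViewpointProfile-class
#' @export
setMethod("profileCounts", "ViewpointProfile", function(x) x@counts)

#' @rdname ViewpointProfile-class
#' @export
setMethod("profileScores", "ViewpointProfile", function(x) x@score)

#' @rdname ViewpointProfile-class
#' @export
setMethod("excludedFragments", "ViewpointProfile", function(x) x@excluded)

#' @rdname ViewpointProfile-class
#' @export
setMethod("viewpointIndex", "ViewpointProfile", function(x) x@viewpointIndex)

#' @rdname ViewpointProfile-class
#' @export
setMethod("profileCondition", "ViewpointProfile", function(x) x@condition)

#' @rdname ViewpointProfile-class
#' @export
setMethod("profileReplicate", "ViewpointProfile", function(x) x@replicate)

#' @rdname ViewpointProfile-class
#' @export
setMethod("length", "ViewpointProfile", function(x) length(x@fragments))

setMethod("show", "ViewpointProfile", function(object) {
    inc <- !object@excluded
    cat(sprintf(
        "ViewpointProfile [%s / %s]: %d fragments, %d excluded\n",
        object@condition, object@replicate,
        length(object@fragments), sum(object@excluded)))
    cat(sprintf("  reads included: %d; viewpoint fragment #%d\n",
                sum(object@counts[inc]), object@viewpointIndex))
})
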