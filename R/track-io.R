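#' Read fixed-step wiggle tracks
#'
#' Parses a fixed-step wiggle file into one [SignalTrack-class] per
#' declaration block. Parsing is delegated to
#' \code{rtracklayer::import(format = "wig")}; a light pre-scan gives
#' line-numbered messages for malformed declarations and rejects
#' variable-step input without a \code{span}, which cannot describe a
#' fixed-bin track.
#'
#' @param path path to a wiggle file.
#' @return named list of \code{SignalTrack}, one per chromosome.
#' @seealso [writeWiggle()]
#' @examples
#' tf <- tempfile(fileext = ".wig")
#' writeWiggle(SignalTrack("chr1", c(1, 2, 3), binSize = 50), tf)
#' readWiggle(tf)
#' @export
readWiggle <- function(path) {
    lines <- readLines(path)
    decl <- grep("^(fixedStep|variableStep)", lines)
    if (length(decl) == 0L)
        stop("no fixedStep/variableStep declaration found in '", path, "'")
    for (i in decl) {
        ln <- lines[[i]]
        if (startsWith(ln, "variableStep") && !grepl("span=", ln))
            stop("line ", i, ": variableStep without span cannot be read ",
                 "as a fixed-bin track")
        if (startsWith(ln, "fixedStep") &&
            (!grepl("chrom=", ln) || !grepl("start=", ln) ||
             !grepl("step=", ln)))
            stop("line ", i, ": malformed fixedStep declaration: ", ln)
    }
    body <- setdiff(seq_along(lines), c(decl, grep("^(track|#)", lines)))
    bad <- body[is.na(suppressWarnings(as.numeric(lines[body]))) &
                nzchar(trimws(lines[body]))]
    if (length(bad) > 0L)
        stop("line ", bad[1L], ": not a numeric wiggle value: ",
             lines[bad[1L]])
    gr <- rtracklayer::import(path, format = "wig")
    out <- list()
    for (chr in as.character(unique(seqnames(gr)))) {
        g <- gr[as.character(seqnames(gr)) == chr]
        g <- g[order(start(g))]
        w <- unique(width(g))
        if (length(w) != 1L)
            stop("track on ", chr, " has unequal spans; not a fixed-bin track")
        if (length(g) > 1L && !all(diff(start(g)) == w))
            stop("track on ", chr, " is not contiguous fixed-step")
        out[[chr]] <- SignalTrack(chr, as.numeric(g$score), binSize = w,
                                  origin = start(g)[1L] - 1L)
    }
    out
}

#' Write SignalTracks as fixed-step wiggle
#'
#' @param tracks a \code{SignalTrack} or list of them.
#' @param path output path.
#' @param name track name written in the \code{track} line.
#' @return \code{path}, invisibly.
#' @export
writeWiggle <- function(tracks, path, name = "track") {
    if (is(tracks, "SignalTrack"))
        tracks <- list(tracks)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("track type=wiggle_0 name=\"%s\"", name), con)
    for (tr in tracks) {
        writeLines(sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                           trackChrom(tr), trackOrigin(tr) + 1L,
                           binSize(tr), binSize(tr)), con)
        writeLines(format(trackValues(tr), trim = TRUE, scientific = FALSE,
                          digits = 10), con)
    }
    invisible(path)
}

#' Write peaks as BED6
#'
#' Peaks are written 0-based half-open with \code{name} = peak index and
#' \code{score} = \code{maxValue} clipped to 1000, the usual BED convention.
#'
#' @param peaks `GRanges` from [callPeaks()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePeaksBed <- function(peaks, path) {
    out <- granges(peaks)
    if (length(peaks) > 0L) {
        mx <- if ("maxValue" %in% colnames(mcols(peaks)))
            mcols(peaks)$maxValue else rep(0, length(peaks))
        mcols(out)$name <- sprintf("peak_%d", seq_along(peaks))
        mcols(out)$score <- pmin(round(mx), 1000)
    }
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

#' Read a BED file of intervals
#'
#' Thin wrapper around \code{rtracklayer::import} returning a 1-based
#' `GRanges`.
#'
#' @param path BED file path.
#' @return `GRanges`.
#' @export
readBed <- function(path) {
    rtracklayer::import(path, format = "BED")
}
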