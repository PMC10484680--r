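#' All overlapping interval pairs with overlap lengths
#'
#' Reports every pair (x in \code{a}, y in \code{b}) overlapping by at
#' least one base, with the overlap length \code{min(ends) - max(starts)}
#' (half-open arithmetic; adjacency is not overlap). Intervals on
#' chromosomes absent from the other set yield no pairs and trigger a
#' warning.
#'
#' @param a,b `GRanges`.
#' @return `DataFrame` with columns \code{query}, \code{subject} (indices
#'   into \code{a} and \code{b}) and \code{overlap} (bases).
#' @export
intersectPairs <- function(a, b) {
    stopifnot(is(a, "GRanges"), is(b, "GRanges"))
    onlyA <- setdiff(unique(as.character(seqnames(a))),
                     unique(as.character(seqnames(b))))
    onlyB <- setdiff(unique(as.character(seqnames(b))),
                     unique(as.character(seqnames(a))))
    if (length(onlyA) || length(onlyB))
        warning("chromosomes present in only one set are skipped: ",
                paste(c(onlyA, onlyB), collapse = ", "))
    hits <- GenomicRanges::findOverlaps(a, b, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- pmin(end(a)[qh], end(b)[sh]) - pmax(start(a)[qh], start(b)[sh]) + 1L
    DataFrame(query = qh, subject = sh, overlap = ov)
}

#' Fraction of intervals in one set bound by another
#'
#' @param a non-empty `GRanges` (e.g. SUMO-2/3 peaks).
#' @param b `GRanges` (e.g. CTCF peaks).
#' @return proportion of \code{a} overlapping at least one interval of
#'   \code{b} by at least one base.
#' @export
fractionBound <- function(a, b) {
    stopifnot(is(a, "GRanges"), is(b, "GRanges"))
    if (length(a) == 0L)
        stop("'a' must be non-empty")
    mean(GenomicRanges::countOverlaps(a, b, ignore.strand = TRUE) > 0L)
}

#' Genes whose promoters carry every requested feature
#'
#' A gene qualifies when, for every supplied peak set, at least one of its
#' promoters overlaps at least one peak of that set. Genes with multiple
#' annotated TSSs contribute multiple promoters and qualify if any
#' promoter does. With no peak sets the conjunction is vacuous: all genes
#' are returned with a warning.
#'
#' @param promoters `GRanges` with a \code{gene_id} metadata column.
#' @param ... one or more `GRanges` peak sets (e.g. SUMO-2/3 and CTCF).
#' @return character vector of qualifying gene ids.
#' @export
genesWithPromoterFeature <- function(promoters, ...) {
    stopifnot(is(promoters, "GRanges"))
    if (!"gene_id" %in% colnames(mcols(promoters)))
        stop("'promoters' must carry a 'gene_id' metadata column")
    sets <- list(...)
    ids <- as.character(mcols(promoters)$gene_id)
    if (length(sets) == 0L) {
        warning("no peak sets supplied; vacuous conjunction returns all genes")
        return(unique(ids))
    }
    qual <- Reduce(intersect, lapply(sets, function(pk) {
        hit <- GenomicRanges::countOverlaps(promoters, pk,
                                            ignore.strand = TRUE) > 0L
        unique(ids[hit])
    }))
    sort(qual)
}

#' Cross gene lists with inclusion-exclusion accounting
#'
#' Folds a list of gene sets by intersection or union, reporting at each
#' pairwise step the set sizes |A|, |B|, the intersection and the union,
#' and asserting the inclusion-exclusion identity
#' |A u B| = |A| + |B| - |A n B|.
#'
#' @param sets named list of character vectors (duplicates are removed).
#' @param mode \code{"intersection"} or \code{"union"}.
#' @return list with \code{result} (character vector) and \code{report}
#'   (data.frame, one row per fold step).
#' @examples
#' crossGeneLists(list(s23 = paste0("p", 1:31),
#'                     s1 = paste0("p", c(1:8, 32:34))), mode = "union")
#' @export
crossGeneLists <- function(sets, mode = c("intersection", "union")) {
    mode <- match.arg(mode)
    stopifnot(length(sets) >= 1L)
    sets <- lapply(sets, function(s) unique(as.character(s)))
    nms <- if (is.null(names(sets))) paste0("set", seq_along(sets))
           else names(sets)
    acc <- sets[[1L]]
    accName <- nms[1L]
    report <- NULL
    for (i in seq_along(sets)[-1L]) {
        b <- sets[[i]]
        nAB <- length(intersect(acc, b))
        uAB <- length(union(acc, b))
        stopifnot(uAB == length(acc) + length(b) - nAB)
        report <- rbind(report, data.frame(
            stepA = accName, stepB = nms[i],
            sizeA = length(acc), sizeB = length(b),
            intersection = nAB, union = uAB))
        acc <- if (mode == "intersection") intersect(acc, b)
               else union(acc, b)
        accName <- sprintf("(%s %s %s)", accName,
                           if (mode == "intersection") "n" else "u", nms[i])
    }
    list(result = sort(acc), report = report)
}

#' Genes whose drug response is modulated by a second treatment
#'
#' Identifies genes whose fold change under a drug is altered at least
#' \code{factor}-fold by a co-treatment (e.g. DNR-responsive genes blunted
#' by the SUMOylation inhibitor ML-792). Two readings are offered:
#' \describe{
#'   \item{\code{contrast}}{\code{log2fcA} is the direct
#'     combination-vs-drug contrast; a gene is modulated when
#'     \code{|log2fcA| >= log2(factor)}.}
#'   \item{\code{ratio}}{\code{log2fcA} and \code{log2fcB} are the
#'     combination-vs-mock and drug-vs-mock contrasts; a gene is modulated
#'     when the ratio of its fold changes differs by \code{factor} or
#'     more, i.e. \code{|log2fcA - log2fcB| >= log2(factor)}.}
#' }
#' The direct-contrast reading is the default; the fold-change-ratio
#' reading is exposed as a mode.
#'
#' @param log2fcA named numeric vector of log2 fold changes (see modes).
#' @param log2fcB named numeric vector, required for \code{mode="ratio"}.
#' @param factor minimal linear modulation (>= 1).
#' @param mode \code{"contrast"} or \code{"ratio"}.
#' @return character vector of modulated gene names.
#' @export
modulatedGenes <- function(log2fcA, log2fcB = NULL, factor = 2,
                           mode = c("contrast", "ratio")) {
    mode <- match.arg(mode)
    stopifnot(factor >= 1, !is.null(names(log2fcA)))
    if (mode == "contrast") {
        hit <- abs(log2fcA) >= log2(factor)
        return(sort(names(log2fcA)[hit & !is.na(hit)]))
    }
    stopifnot(!is.null(log2fcB), !is.null(names(log2fcB)))
    common <- intersect(names(log2fcA), names(log2fcB))
    d <- log2fcA[common] - log2fcB[common]
    sort(common[abs(d) >= log2(factor) & !is.na(d)])
}

#' Write a gene list as one-id-per-line text
#' @param genes character vector.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneList <- function(genes, path) {
    writeLines(as.character(genes), path)
    invisible(path)
}
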