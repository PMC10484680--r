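# Fragment-level one-sided exceedance p-values for a single replicate.
# Background: running-median smoothing of the normalized scores followed by
# an isotonic fit constrained to be non-increasing in distance (in fragment
# index units) from the viewpoint. Residuals are ranked within
# distance strata against an outlier-cleaned reference so that genuine
# multi-fragment interactions do not suppress each other's ranks.
.fragmentPValues <- function(profile, smoothingWindow = 21L,
                             strataSize = 50L, madK = 3,
                             minTestDistance = NULL) {
    fr <- profile@fragments
    inc <- which(!profile@excluded)
    score <- profile@score[inc]
    vpChr <- as.character(seqnames(fr))[profile@viewpointIndex]
    sameChr <- as.character(seqnames(fr))[inc] == vpChr
    d <- ifelse(sameChr,
                abs(mcols(fr)$fragId[inc] -
                    mcols(fr)$fragId[profile@viewpointIndex]),
                NA_real_)

    # smooth each viewpoint arm separately, ordered by distance: the
    # running median of a monotonically decaying arm is unbiased at every
    # position, whereas smoothing across the viewpoint peak in position
    # space would systematically underestimate the near-viewpoint decay
    vpId <- mcols(fr)$fragId[profile@viewpointIndex]
    side <- sign(mcols(fr)$fragId[inc] - vpId)
    sm <- score
    armSmooth <- function(ii) {
        if (length(ii) < 3L) return()
        o <- ii[order(d[ii])]
        k <- min(smoothingWindow, length(o))
        if (k %% 2L == 0L) k <- k - 1L
        if (k >= 3L)
            sm[o] <<- stats::runmed(score[o], k, endrule = "median")
    }
    armSmooth(which(!is.na(d) & side < 0))
    armSmooth(which(!is.na(d) & side > 0))

    bg <- numeric(length(score))
    cis <- which(!is.na(d))
    if (length(cis) > 1L) {
        o <- order(d[cis])
        iso <- stats::isoreg(d[cis][o], -sm[cis][o])
        bg[cis[o]] <- -iso$yf
    } else if (length(cis) == 1L) {
        bg[cis] <- sm[cis]
    }
    trans <- which(is.na(d))
    if (length(trans) > 0L)
        bg[trans] <- stats::median(sm[trans])
    # variance-stabilized residuals: for count-derived scores the
    # square-root scale has near-constant variance, so near-viewpoint
    # fragments (large means) do not dominate their stratum's ranks
    resid <- sqrt(score) - sqrt(pmax(bg, 0))

    # distance strata: equal-count chunks along increasing distance; trans
    # fragments form their own stratum
    stratum <- integer(length(score))
    if (length(cis) > 0L) {
        o <- order(d[cis])
        nStrata <- max(1L, floor(length(cis) / strataSize))
        bounds <- floor(seq(0L, length(cis), length.out = nStrata + 1L))
        sid <- rep(seq_len(nStrata), times = diff(bounds))
        stratum[cis[o]] <- sid
    }
    if (length(trans) > 0L)
        stratum[trans] <- max(stratum) + 1L

    p <- rep(NA_real_, length(score))
    for (s in unique(stratum)) {
        ii <- which(stratum == s)
        r <- resid[ii]
        med <- stats::median(r)
        scale <- stats::mad(r)
        if (scale == 0) scale <- stats::sd(r)
        if (is.na(scale) || scale == 0) {
            refMask <- rep(TRUE, length(r))
        } else {
            refMask <- r <= med + madK * scale
        }
        nRef <- sum(refMask)
        for (j in seq_along(r)) {
            self <- refMask[j]
            cnt <- sum(r[refMask] >= r[j]) - as.integer(self)
            p[ii[j]] <- (1 + cnt) / (1 + nRef - as.integer(self))
        }
    }
    # fragments closer to the viewpoint than the smoothing half-window
    # have end-rule-extrapolated backgrounds (the running median cannot be
    # centred there); they are background for ranking but not testable
    if (is.null(minTestDistance) && length(cis) > 0L)
        minTestDistance <- min(d[cis]) + (smoothingWindow - 1L) %/% 2L
    if (!is.null(minTestDistance))
        p[!is.na(d) & d < minTestDistance] <- NA_real_

    full <- rep(NA_real_, length(fr))
    full[inc] <- p
    full
}

#' Replicate-consistent 4C interaction calling
#'
#' For each replicate, a monotonically non-increasing background in
#' distance to the viewpoint is fitted by isotonic regression to
#' running-median-smoothed normalized scores; fragment-level one-sided
#' exceedance p-values are computed by rank against same-distance-stratum
#' background residuals (the reference set is cleaned of gross outliers
#' with a median + \code{madK} * MAD rule so adjacent interacting
#' fragments do not mask each other). Fragments significant at
#' \code{alpha} in \emph{all} replicates are merged into interaction
#' regions, bridging up to \code{mergeGap} intervening fragments, and
#' labelled with roman numerals. Regions supported by fewer than
#' \code{minFragments} significant fragments are dropped: an isolated
#' single-fragment signal that repeats across replicates is more often a
#' shared amplification artifact than a genuine contact, which spreads
#' over neighbouring fragments.
#'
#' @param profiles list of [ViewpointProfile-class] replicates (>= 2) on
#'   the same fragment map.
#' @param alpha fragment-level significance threshold per replicate.
#' @param smoothingWindow running-median window, in fragments.
#' @param mergeGap maximal number of non-significant fragments bridged
#'   when merging.
#' @param minFragments minimal number of significant fragments a region
#'   needs to be reported.
#' @param strataSize target number of fragments per distance stratum.
#' @param madK outlier-cleaning multiplier for the rank reference set.
#' @param minTestDistance fragments closer to the viewpoint (in fragment
#'   index distance) are background only, never called: their smoothed
#'   background is end-rule extrapolated rather than interpolated.
#'   Default: nearest included distance plus the smoothing half-window.
#' @return `GRanges` of interaction regions with metadata columns
#'   \code{label}, \code{nFragments} and \code{pMax} (the largest
#'   per-replicate minimum p inside the region). Fragment-level p-values
#'   are attached as a matrix in \code{metadata()$fragmentP}.
#' @export
callInteractions <- function(profiles, alpha = 0.05,
                             smoothingWindow = 21L, mergeGap = 1L,
                             strataSize = 50L, madK = 3,
                             minTestDistance = NULL, minFragments = 2L) {
    stopifnot(is.list(profiles), length(profiles) >= 2L)
    fr <- profiles[[1L]]@fragments
    for (p in profiles) {
        stopifnot(is(p, "ViewpointProfile"))
        if (length(p@fragments) != length(fr) ||
            !identical(start(p@fragments), start(fr)) ||
            !identical(as.character(seqnames(p@fragments)),
                       as.character(seqnames(fr))))
            stop("replicates are not on the same fragment map")
    }
    pMat <- vapply(profiles, .fragmentPValues,
                   numeric(length(fr)),
                   smoothingWindow = smoothingWindow,
                   strataSize = strataSize, madK = madK,
                   minTestDistance = minTestDistance)
    sig <- rowSums(pMat < alpha) == length(profiles)
    sig[is.na(sig)] <- FALSE

    regions <- GRanges()
    sigIdx <- which(sig)
    if (length(sigIdx) > 0L) {
        chrs <- as.character(seqnames(fr))[sigIdx]
        startsL <- endsL <- integer(0)
        chrL <- character(0)
        for (chr in unique(chrs)) {
            ii <- sigIdx[chrs == chr]
            brk <- c(0L, which(diff(ii) > mergeGap + 1L), length(ii))
            for (b in seq_len(length(brk) - 1L)) {
                memb <- ii[(brk[b] + 1L):brk[b + 1L]]
                startsL <- c(startsL, start(fr)[memb[1L]])
                endsL <- c(endsL, end(fr)[memb[length(memb)]])
                chrL <- c(chrL, chr)
            }
        }
        regions <- GRanges(chrL, IRanges(startsL, endsL))
        ov <- GenomicRanges::findOverlaps(regions, fr)
        nFrag <- integer(length(regions))
        pMax <- numeric(length(regions))
        for (r in seq_along(regions)) {
            memb <- S4Vectors::subjectHits(ov)[
                S4Vectors::queryHits(ov) == r]
            memb <- memb[sig[memb]]
            nFrag[r] <- length(memb)
            pMax[r] <- max(apply(pMat[memb, , drop = FALSE], 2L, min))
        }
        keep <- nFrag >= minFragments
        regions <- regions[keep]
        nFrag <- nFrag[keep]
        pMax <- pMax[keep]
        o <- order(as.character(seqnames(regions)), start(regions))
        regions <- regions[o]
        mcols(regions)$label <-
            as.character(utils::as.roman(seq_along(regions)))
        mcols(regions)$nFragments <- nFrag[o]
        mcols(regions)$pMax <- pMax[o]
    }
    metadata(regions)$fragmentP <- pMat
    regions
}

#' Differential contact testing between conditions
#'
#' Sums raw fragment counts per interaction region and replicate, and
#' tests for condition differences with the package's size-factor
#' normalized negative-binomial stage. Sequencing depth is taken from
#' each profile's total included reads, so region counts are compared on
#' a common per-library scale. Regions with all-zero counts are excluded
#' and reported.
#'
#' @param regions `GRanges` of interaction regions (e.g. from
#'   [callInteractions()] run per condition and merged).
#' @param profiles list of [ViewpointProfile-class] spanning two
#'   conditions, >= 2 replicates each.
#' @param contrast character of length 2: (reference, treatment)
#'   condition labels; the log2 fold change is treatment over reference.
#' @return list with \code{results} (data.frame: label, log2FoldChange,
#'   pvalue, padj) and \code{excluded} (labels of all-zero regions).
#' @export
differentialContacts <- function(regions, profiles, contrast) {
    stopifnot(length(contrast) == 2L, length(regions) > 0L)
    conds <- vapply(profiles, profileCondition, character(1))
    use <- conds %in% contrast
    profiles <- profiles[use]
    conds <- factor(conds[use], levels = contrast)
    if (any(table(conds) < 2L))
        stop("need at least 2 replicates per condition")
    fr <- profiles[[1L]]@fragments
    ov <- GenomicRanges::findOverlaps(regions, fr)
    counts <- matrix(0L, nrow = length(regions), ncol = length(profiles))
    for (j in seq_along(profiles)) {
        cj <- profiles[[j]]@counts
        for (r in seq_along(regions)) {
            memb <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == r]
            counts[r, j] <- sum(cj[memb])
        }
    }
    labels <- if ("label" %in% colnames(mcols(regions)))
        as.character(mcols(regions)$label)
    else as.character(seq_along(regions))
    rownames(counts) <- labels
    colnames(counts) <- vapply(profiles, function(p)
        paste(profileCondition(p), profileReplicate(p), sep = "_"),
        character(1))
    allZero <- rowSums(counts) == 0L
    depth <- vapply(profiles, function(p)
        sum(p@counts[!p@excluded]), numeric(1))
    sf <- depth / exp(mean(log(depth)))
    res <- nbTest(counts[!allZero, , drop = FALSE], conds,
                  sizeFactors = sf)
    res$padj <- bhAdjust(res$pvalue)
    res$label <- labels[!allZero]
    list(results = res[, c("label", "baseMean", "log2FoldChange",
                           "pvalue", "padj")],
         excluded = labels[allZero])
}
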