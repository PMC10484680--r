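# Synthetic 4C-seq, SILAC and RNA-seq count generators (continued from
# simulate.R) plus the one-call simulateAll() driver.

#' Plant the viewpoint capture sequence into a genome
#'
#' Overwrites the bases immediately upstream of the end-of-fragment
#' first-enzyme site of a central restriction fragment with the capture
#' (amplification) sequence, so the viewpoint fragment carries the
#' capture at its boundary as the assay requires. The genome is
#' re-digested afterwards by the caller; the capture contains neither
#' enzyme site, so the viewpoint cut itself is preserved.
#'
#' @param genome `DNAStringSet`.
#' @param capture capture sequence.
#' @param site1 first-enzyme site.
#' @return list with \code{genome} (modified), \code{viewpoint}
#'   (single-base `GRanges` at the viewpoint cut) and
#'   \code{viewpointChrom}.
#' @export
plantCaptureSite <- function(genome, capture = FOURC_CAPTURE,
                             site1 = "CATG") {
    stopifnot(is(genome, "DNAStringSet"))
    map <- digestGenome(genome, site1 = site1)
    fr <- fragments(map)
    chr <- names(genome)[1L]
    frc <- fr[as.character(seqnames(fr)) == chr]
    chromLen <- Biostrings::width(genome)[[1L]]
    mid <- chromLen %/% 2L
    need <- nchar(capture) + nchar(site1) + 5L
    cand <- frc[width(frc) >= need & end(frc) < chromLen]
    if (length(cand) == 0L)
        stop("no fragment long enough to host the capture sequence")
    vpFrag <- cand[which.min(abs((start(cand) + end(cand)) / 2 - mid))]
    # fragment ends with site1; write the capture right before it
    capEnd <- end(vpFrag) - nchar(site1)
    capStart <- capEnd - nchar(capture) + 1L
    seqs <- as.character(genome)
    substr(seqs[[chr]], capStart, capEnd) <- capture
    newGenome <- Biostrings::DNAStringSet(seqs)
    vp <- GRanges(chr, IRanges(end(vpFrag), width = 1L))
    GenomeInfoDb::seqlengths(vp) <-
        stats::setNames(Biostrings::width(newGenome), names(newGenome))
    list(genome = newGenome, viewpoint = vp, viewpointChrom = chr)
}

# per-fragment enrichment folds from the planted-interaction table
.interactionFolds <- function(planted, map, vpIndex, condition) {
    fr <- fragments(map)
    fold <- rep(1, length(fr))
    col <- if (tolower(condition) %in% c("dnr", "treated"))
        "foldDnr" else "foldMock"
    regions <- GRanges()
    for (i in seq_len(nrow(planted))) {
        i1 <- vpIndex + planted$offsetFragments[i]
        i2 <- i1 + planted$nFragments[i] - 1L
        if (i1 < 1L || i2 > length(fr))
            stop("planted interaction ", i, " falls outside the genome")
        fold[i1:i2] <- planted[[col]][i]
        reg <- GRanges(seqnames(fr)[i1],
                       IRanges(start(fr)[i1], end(fr)[i2]))
        mcols(reg)$fold <- planted[[col]][i]
        regions <- c(regions, reg)
    }
    list(fold = fold, regions = regions)
}

#' Sample per-fragment 4C contact counts
#'
#' Draws fragment counts from the model underlying the read simulator: a
#' multinomial over fragments with weights \code{fold / max(d, 1)} where
#' \code{d} is the fragment-index distance to the viewpoint (power-law
#' contact decay with exponent -1) times the planted enrichment fold.
#' Trans-chromosomal fragments receive a small constant weight. The
#' viewpoint fragment itself and fragments whose downstream sequence is
#' too short to yield a mappable read get weight zero.
#'
#' @param map a [FragmentMap-class].
#' @param vpIndex viewpoint fragment index.
#' @param nReads reads to distribute.
#' @param fold per-fragment enrichment folds (default all 1).
#' @param readLength partner-sequence length a read carries.
#' @param transWeight relative total weight of each trans chromosome.
#' @return integer vector of per-fragment counts summing to
#'   \code{nReads}.
#' @export
sample4CFragmentCounts <- function(map, vpIndex, nReads,
                                   fold = NULL, readLength = 40L,
                                   transWeight = 0.01) {
    fr <- fragments(map)
    n <- length(fr)
    if (is.null(fold))
        fold <- rep(1, n)
    stopifnot(length(fold) == n, vpIndex >= 1L, vpIndex <= n)
    chrs <- as.character(seqnames(fr))
    vpChr <- chrs[vpIndex]
    sl <- GenomeInfoDb::seqlengths(fr)
    w <- numeric(n)
    cis <- chrs == vpChr
    d <- abs(mcols(fr)$fragId - mcols(fr)$fragId[vpIndex])
    w[cis] <- 1 / pmax(d[cis], 1)
    if (any(!cis)) {
        for (chr in unique(chrs[!cis])) {
            ii <- which(chrs == chr)
            w[ii] <- transWeight / length(ii)
        }
    }
    w <- w * fold
    w[vpIndex] <- 0
    reachable <- start(fr) + readLength - 1L <= sl[chrs]
    w[!reachable] <- 0
    counts <- as.integer(stats::rmultinom(1L, nReads, w))
    names(counts) <- sprintf("frag%05d", mcols(fr)$fragId)
    counts
}

#' Simulate a 4C-seq read set with planted interactions
#'
#' Emits FASTQ-writable reads for one replicate of one condition. Each
#' capture-bearing read is \code{capture + site1 + } the genomic sequence
#' immediately downstream of a sampled partner fragment's cut site;
#' partner fragments are drawn from the distance-decay law times the
#' planted enrichment folds ([sample4CFragmentCounts()]). A configurable
#' fraction of decoy reads is random sequence lacking the capture. The
#' returned truth tally is the simulator's own bookkeeping against which
#' the trim/map/assign stages are scored.
#'
#' @param config a [simulationConfig()].
#' @param genome `DNAStringSet` with the capture planted
#'   ([plantCaptureSite()]).
#' @param viewpoint single-base `GRanges` at the viewpoint cut.
#' @param condition,replicate labels (also seed the per-replicate RNG
#'   stream).
#' @param capture,site1 assay sequences.
#' @param readLength partner-sequence bases carried by each read.
#' @return list with \code{reads} (`DNAStringSet`) and \code{truth}
#'   (list: fragmentCounts, nCapture, nDecoy, vpIndex, plantedRegions).
#' @export
make4CReads <- function(config, genome, viewpoint,
                        condition = "mock", replicate = "rep1",
                        capture = FOURC_CAPTURE, site1 = "CATG",
                        readLength = 40L) {
    stopifnot(inherits(config, "SimulationConfig"))
    map <- digestGenome(genome, site1 = site1)
    hits <- GenomicRanges::findOverlaps(viewpoint, fragments(map))
    if (length(hits) == 0L)
        stop("viewpoint does not overlap any restriction fragment")
    vpIndex <- S4Vectors::subjectHits(hits)[1L]
    vpFrag <- fragments(map)[vpIndex]
    vpSeq <- as.character(Biostrings::subseq(
        genome[[as.character(seqnames(vpFrag))]],
        start(vpFrag), end(vpFrag)))
    if (!grepl(capture, vpSeq, fixed = TRUE))
        stop("viewpoint fragment does not contain the capture sequence; ",
             "plant it with plantCaptureSite()")
    streamOffset <- sum(utf8ToInt(paste(condition, replicate))) %% 997L
    .withSeed(config$seed + .SEED_OFFSETS[["fourc"]] + streamOffset, {
        pl <- .interactionFolds(config$plantedInteractions, map, vpIndex,
                                condition)
        nDecoy <- stats::rbinom(1L, config$n4cReads, config$decoyFraction)
        nCapture <- config$n4cReads - nDecoy
        counts <- sample4CFragmentCounts(map, vpIndex, nCapture,
                                         fold = pl$fold,
                                         readLength = readLength)
        fr <- fragments(map)
        hot <- which(counts > 0L)
        fragSeq <- rep(NA_character_, length(counts))
        for (chr in unique(as.character(seqnames(fr))[hot])) {
            ii <- hot[as.character(seqnames(fr))[hot] == chr]
            fragSeq[ii] <- as.character(Biostrings::extractAt(
                genome[[chr]],
                IRanges(start(fr)[ii], start(fr)[ii] + readLength - 1L)))
        }
        partnerSeq <- rep(fragSeq, counts)
        capReads <- paste0(capture, site1, partnerSeq)
        decoyLen <- nchar(capture) + nchar(site1) + readLength
        decoyMat <- matrix(sample(c("A", "C", "G", "T"),
                                  nDecoy * decoyLen, replace = TRUE),
                           nrow = nDecoy)
        decoys <- apply(decoyMat, 1L, paste, collapse = "")
        if (nDecoy == 0L) decoys <- character(0)
        allReads <- sample(c(capReads, decoys))
        reads <- Biostrings::DNAStringSet(allReads)
        names(reads) <- sprintf("%s_%s_read%06d", condition, replicate,
                                seq_along(reads))
        list(reads = reads,
             truth = list(fragmentCounts = counts,
                          nCapture = nCapture,
                          nDecoy = nDecoy,
                          vpIndex = vpIndex,
                          plantedRegions = pl$regions))
    })
}

#' Write reads as FASTQ (constant quality)
#' @param reads `DNAStringSet`.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFastq <- function(reads, path) {
    quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
    Biostrings::writeXStringSet(reads, path, format = "fastq",
                                qualities = quals)
    invisible(path)
}

#' Read FASTQ sequences
#' @param path FASTQ file.
#' @return `DNAStringSet`.
#' @export
readFastq <- function(path) {
    Biostrings::readDNAStringSet(path, format = "fastq")
}

#' Simulate a SILAC SUMOylome ratio table with planted hit sets
#'
#' Builds a per-protein table of SUMO-1 and SUMO-2/3 log2 ratios over a
#' SUMOylated-universe of \code{nSilacProteins} proteins. Planted up/down
#' proteins draw |log2 ratio| above the cutoff (margin 0.15 plus an
#' exponential tail); unchanged proteins are centred at 0 and truncated
#' inside (-0.45, 0.45) so planted sets are exactly recoverable. A small
#' set of non-universe contaminant proteins with large ratios is added;
#' they must never be classified. Input-abundance log2 ratios are near 0
#' except for two deliberately confounded hits.
#'
#' @param config a [simulationConfig()].
#' @param cutoff classification cutoff the table is built around.
#' @param nContaminants non-universe proteins appended.
#' @return list with \code{table} (data.frame for [classifyRatios()]) and
#'   \code{truth} (planted id sets per paralog and direction).
#' @export
makeSilacTable <- function(config, cutoff = 0.5, nContaminants = 20L) {
    stopifnot(inherits(config, "SimulationConfig"))
    .withSeed(config$seed + .SEED_OFFSETS[["silac"]], {
        sc <- config$silacCounts
        n <- config$nSilacProteins
        ids <- sprintf("P%04d", seq_len(n + nContaminants))
        uni <- c(rep(TRUE, n), rep(FALSE, nContaminants))

        pool <- seq_len(n)
        take <- function(k) {
            picked <- sort(sample(pool, k))
            pool <<- setdiff(pool, picked)
            picked
        }
        upCommon <- take(sc[["nCommonUp"]])
        upS23only <- take(sc[["nUpS23"]] - sc[["nCommonUp"]])
        upS1only <- take(sc[["nUpS1"]] - sc[["nCommonUp"]])
        downCommon <- take(sc[["nCommonDown"]])
        downS23only <- take(sc[["nDownS23"]] - sc[["nCommonDown"]])
        downS1only <- take(sc[["nDownS1"]] - sc[["nCommonDown"]])

        nAll <- n + nContaminants
        drawHit <- function(k, sign)
            sign * (cutoff + 0.15 + stats::rexp(k, rate = 2))
        background <- function(k)
            pmax(pmin(stats::rnorm(k, 0, 0.15), 0.45), -0.45)

        r23 <- background(nAll)
        r1 <- background(nAll)
        upS23 <- c(upCommon, upS23only)
        upS1 <- c(upCommon, upS1only)
        downS23 <- c(downCommon, downS23only)
        downS1 <- c(downCommon, downS1only)
        r23[upS23] <- drawHit(length(upS23), +1)
        r23[downS23] <- drawHit(length(downS23), -1)
        r1[upS1] <- drawHit(length(upS1), +1)
        r1[downS1] <- drawHit(length(downS1), -1)
        # contaminants: outside the universe, some with large ratios
        ci <- n + seq_len(nContaminants)
        r23[ci] <- stats::rnorm(nContaminants, 0, 1)
        r1[ci] <- stats::rnorm(nContaminants, 0, 1)

        abund <- stats::rnorm(nAll, 0, 0.1)
        confounded <- c(downS23[1L], upS23[1L])
        abund[confounded] <- c(-1, 1)

        tab <- data.frame(protein = ids,
                          log2RatioSumo1 = r1,
                          log2RatioSumo23 = r23,
                          inSumoylatedUniverse = uni,
                          inputAbundanceRatio = abund)
        list(table = tab,
             truth = list(upS23 = ids[upS23], upS1 = ids[upS1],
                          downS23 = ids[downS23], downS1 = ids[downS1],
                          abundanceConfounded = ids[confounded]))
    })
}

#' Simulate an RNA-seq count matrix with planted differential genes
#'
#' Negative-binomial counts over lognormal baseline means with uneven
#' library depths. With the default two conditions, \code{nUp}/\code{nDown}
#' genes change by \code{2^log2fc} in the treated condition. With the
#' four-condition design \code{mock, DNR, ML792, ML792_DNR}, planted genes
#' respond to DNR, are untouched by ML-792 alone, and half of them are
#' blunted 4-fold in the combination — the planted ground truth for the
#' SUMO-dependence crossing logic.
#'
#' @param config a [simulationConfig()].
#' @param nGenes genes in the matrix (expression universe; the genome's
#'   genes are its first ids when \code{geneIds} is supplied).
#' @param nPerGroup replicates per condition.
#' @param conditions condition labels.
#' @param geneIds optional gene identifiers (length \code{nGenes}).
#' @return list with \code{counts} (matrix), \code{conditions} (factor)
#'   and \code{truth} (planted up/down ids, and modulated ids for the
#'   four-condition design).
#' @export
makeCounts <- function(config, nGenes = 500L, nPerGroup = 3L,
                       conditions = c("mock", "DNR"), geneIds = NULL) {
    stopifnot(inherits(config, "SimulationConfig"), nPerGroup >= 2L)
    .withSeed(config$seed + .SEED_OFFSETS[["counts"]], {
        dc <- config$deCounts
        nUp <- as.integer(dc[["nUp"]])
        nDown <- as.integer(dc[["nDown"]])
        lfc <- dc[["log2fc"]]
        disp <- dc[["dispersion"]]
        stopifnot(nUp + nDown <= nGenes)
        if (is.null(geneIds))
            geneIds <- sprintf("gene%03d", seq_len(nGenes))
        stopifnot(length(geneIds) == nGenes)

        mu0 <- exp(stats::rnorm(nGenes, log(100), 1))
        upIdx <- seq_len(nUp)
        downIdx <- nUp + seq_len(nDown)
        shuffle <- sample(nGenes)
        upIdx <- shuffle[upIdx]
        downIdx <- shuffle[downIdx]

        fourWay <- length(conditions) == 4L &&
            all(c("mock", "DNR", "ML792", "ML792_DNR") %in% conditions)
        lfcMat <- matrix(0, nrow = nGenes, ncol = length(conditions),
                         dimnames = list(geneIds, conditions))
        modulated <- character(0)
        if (length(conditions) >= 2L && !fourWay) {
            lfcMat[upIdx, 2L] <- lfc
            lfcMat[downIdx, 2L] <- -lfc
        } else if (fourWay) {
            lfcMat[upIdx, "DNR"] <- lfc
            lfcMat[downIdx, "DNR"] <- -lfc
            responsive <- c(upIdx, downIdx)
            blunted <- sort(sample(responsive,
                                   floor(length(responsive) / 2)))
            intact <- setdiff(responsive, blunted)
            lfcMat[blunted, "ML792_DNR"] <- lfcMat[blunted, "DNR"] - 2 *
                sign(lfcMat[blunted, "DNR"])
            lfcMat[intact, "ML792_DNR"] <- lfcMat[intact, "DNR"]
            modulated <- geneIds[blunted]
        }

        samples <- paste(rep(conditions, each = nPerGroup),
                         paste0("rep", seq_len(nPerGroup)), sep = "_")
        depth <- stats::runif(length(samples), 0.7, 1.4)
        counts <- matrix(0L, nrow = nGenes, ncol = length(samples),
                         dimnames = list(geneIds, samples))
        for (j in seq_along(samples)) {
            cond <- rep(conditions, each = nPerGroup)[j]
            mu <- mu0 * 2^lfcMat[, cond] * depth[j]
            counts[, j] <- stats::rnbinom(nGenes, mu = mu, size = 1 / disp)
        }
        list(counts = counts,
             conditions = factor(rep(conditions, each = nPerGroup),
                                 levels = conditions),
             truth = list(up = sort(geneIds[upIdx]),
                          down = sort(geneIds[downIdx]),
                          modulated = modulated))
    })
}
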