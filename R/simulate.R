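# Synthetic-data generators with planted ground truth. Every generator is
# a pure function of (config, seed): RNG state is set locally from the
# config seed plus a fixed per-stage offset, so outputs are byte-identical
# across calls and stages can be regenerated independently.

.withSeed <- function(seed, expr) {
    hasOld <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (hasOld)
        old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (hasOld) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

.SEED_OFFSETS <- c(genome = 0L, genes = 101L, tracks = 202L,
                   fourc = 303L, silac = 404L, counts = 505L)

#' Simulation configuration with planted ground truth
#'
#' Bundles and validates every tunable of the synthetic-data module. The
#' defaults define the study conditions the generators emulate: a
#' single-TAD-scale chromosome, boxcar-shaped SUMO-2/3 promoter peaks
#' depleted under DNR, a viewpoint-anchored 4C contact decay with planted
#' interacting regions, the published SILAC per-paralog set sizes
#' (31/11/8 up, 83/32/19 down over a 894-protein SUMOylated universe) and
#' NB counts with planted differential genes.
#'
#' @param seed integer master seed; all generators derive their RNG state
#'   from it.
#' @param nChromosomes number of chromosomes.
#' @param chromLength chromosome length in bases (>= 10000).
#' @param nGenes genes placed on the genome.
#' @param promoterSumoHeight planted SUMO-2/3 peak height, track units.
#' @param dnrDepletionFactor factor in (0, 1] scaling planted SUMO signal
#'   in the DNR condition (1 = no depletion).
#' @param n4cReads 4C reads per replicate.
#' @param plantedInteractions data.frame describing planted 4C
#'   interactions (columns \code{offsetFragments}, \code{nFragments},
#'   \code{foldMock}, \code{foldDnr}); \code{NULL} for the default three
#'   regions (stable, DNR-lost, DNR-gained).
#' @param silacCounts named integer vector: nUpS23, nUpS1, nCommonUp,
#'   nDownS23, nDownS1, nCommonDown.
#' @param deCounts named vector: nUp, nDown, log2fc, dispersion.
#' @param binSize track bin size in bases.
#' @param backgroundMean Poisson mean of track background noise.
#' @param nEnhancers planted enhancer elements.
#' @param ctcfFraction fraction of SUMO peaks co-bound by CTCF.
#' @param activeFraction fraction of elements in the active state.
#' @param nSilacProteins size of the SUMOylated universe.
#' @param decoyFraction fraction of 4C reads lacking the capture.
#' @return validated configuration (class \code{SimulationConfig}).
#' @export
simulationConfig <- function(seed = 1L,
                             nChromosomes = 1L,
                             chromLength = 200000L,
                             nGenes = 25L,
                             promoterSumoHeight = 64,
                             dnrDepletionFactor = 0.5,
                             n4cReads = 30000L,
                             plantedInteractions = NULL,
                             silacCounts = c(nUpS23 = 31L, nUpS1 = 11L,
                                             nCommonUp = 8L,
                                             nDownS23 = 83L, nDownS1 = 32L,
                                             nCommonDown = 19L),
                             deCounts = c(nUp = 25, nDown = 25,
                                          log2fc = 2, dispersion = 0.05),
                             binSize = 50L,
                             backgroundMean = 2,
                             nEnhancers = 8L,
                             ctcfFraction = 1 / 3,
                             activeFraction = 0.7,
                             nSilacProteins = 894L,
                             decoyFraction = 0.2) {
    if (chromLength <= 0L)
        stop("chromosome length must be positive")
    if (chromLength < 10000L)
        stop("chromosome length must be at least 10000 bases")
    stopifnot(nChromosomes >= 1L, nGenes >= 1L,
              dnrDepletionFactor > 0, dnrDepletionFactor <= 1,
              n4cReads >= 1L, binSize > 0L, backgroundMean >= 0,
              ctcfFraction >= 0, ctcfFraction <= 1,
              activeFraction >= 0, activeFraction <= 1,
              decoyFraction >= 0, decoyFraction < 1)
    need <- c("nUpS23", "nUpS1", "nCommonUp",
              "nDownS23", "nDownS1", "nCommonDown")
    if (!all(need %in% names(silacCounts)))
        stop("silacCounts needs: ", paste(need, collapse = ", "))
    sc <- silacCounts
    if (sc["nCommonUp"] > min(sc["nUpS23"], sc["nUpS1"]) ||
        sc["nCommonDown"] > min(sc["nDownS23"], sc["nDownS1"]))
        stop("common set sizes cannot exceed either per-paralog set size")
    tot <- sc["nUpS23"] + sc["nUpS1"] - sc["nCommonUp"] +
           sc["nDownS23"] + sc["nDownS1"] - sc["nCommonDown"]
    if (tot > nSilacProteins)
        stop("planted SILAC sets exceed the protein universe")
    if (is.null(plantedInteractions))
        plantedInteractions <- data.frame(
            offsetFragments = c(40L, -60L, 120L),
            nFragments = 5L,
            foldMock = c(8, 8, 2),
            foldDnr = c(8, 2, 8))
    stopifnot(all(c("offsetFragments", "nFragments", "foldMock",
                    "foldDnr") %in% colnames(plantedInteractions)))
    cfg <- list(seed = as.integer(seed),
                nChromosomes = as.integer(nChromosomes),
                chromLength = as.integer(chromLength),
                nGenes = as.integer(nGenes),
                promoterSumoHeight = promoterSumoHeight,
                dnrDepletionFactor = dnrDepletionFactor,
                n4cReads = as.integer(n4cReads),
                plantedInteractions = plantedInteractions,
                silacCounts = sc,
                deCounts = deCounts,
                binSize = as.integer(binSize),
                backgroundMean = backgroundMean,
                nEnhancers = as.integer(nEnhancers),
                ctcfFraction = ctcfFraction,
                activeFraction = activeFraction,
                nSilacProteins = as.integer(nSilacProteins),
                decoyFraction = decoyFraction)
    class(cfg) <- c("SimulationConfig", "list")
    cfg
}

#' @export
print.SimulationConfig <- function(x, ...) {
    cat("SimulationConfig (seed", x$seed, ")\n")
    cat(sprintf("  genome: %d x %d bp, %d genes, %d enhancers\n",
                x$nChromosomes, x$chromLength, x$nGenes, x$nEnhancers))
    cat(sprintf("  tracks: bin %d, background %.2g, SUMO height %.3g, DNR factor %.2g\n",
                x$binSize, x$backgroundMean, x$promoterSumoHeight,
                x$dnrDepletionFactor))
    cat(sprintf("  4C: %d reads/replicate, %d planted regions, decoys %.2g\n",
                x$n4cReads, nrow(x$plantedInteractions), x$decoyFraction))
    invisible(x)
}

#' Generate a random genome
#'
#' Uniform-base random chromosome sequences; restriction sites therefore
#' occur at the base-composition-expected rate (1/256 per position for a
#' 4-mer). Deterministic given the config seed.
#'
#' @param config a [simulationConfig()].
#' @return named `DNAStringSet`.
#' @export
makeGenome <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    .withSeed(config$seed + .SEED_OFFSETS[["genome"]], {
        seqs <- vapply(seq_len(config$nChromosomes), function(i)
            paste(sample(c("A", "C", "G", "T"), config$chromLength,
                         replace = TRUE), collapse = ""),
            character(1))
        names(seqs) <- paste0("chr", seq_len(config$nChromosomes))
        Biostrings::DNAStringSet(seqs)
    })
}

#' Generate a gene annotation
#'
#' Places genes in evenly spaced slots with jittered TSS positions and
#' random strands, keeping each 2 kb promoter inside the chromosome.
#' Overlapping placements are resolved by rejection-resampling with a
#' bounded number of retries.
#'
#' @param config a [simulationConfig()].
#' @param genome `DNAStringSet` from [makeGenome()].
#' @param maxRetries retries per gene before giving up.
#' @return `GRanges` of genes with \code{gene_id} and \code{active}.
#' @export
makeGenes <- function(config, genome, maxRetries = 50L) {
    stopifnot(inherits(config, "SimulationConfig"))
    .withSeed(config$seed + .SEED_OFFSETS[["genes"]], {
        len <- config$chromLength
        margin <- 2500L
        perChrom <- diff(floor(seq(0, config$nGenes,
                                   length.out = config$nChromosomes + 1L)))
        grl <- list()
        geneWidth <- 1000L
        for (ci in seq_len(config$nChromosomes)) {
            nG <- perChrom[ci]
            if (nG == 0L) next
            slots <- floor(seq(margin, len - margin - geneWidth,
                               length.out = nG + 1L))
            placed <- GRanges()
            for (g in seq_len(nG)) {
                ok <- FALSE
                for (try in seq_len(maxRetries)) {
                    lo <- slots[g]
                    hi <- max(lo + 1L, slots[g + 1L] - geneWidth)
                    tss <- sample(seq.int(lo, hi), 1L)
                    str <- sample(c("+", "-"), 1L)
                    cand <- GRanges(names(genome)[ci],
                                    IRanges(tss, width = geneWidth),
                                    strand = str)
                    if (str == "-")
                        cand <- GRanges(names(genome)[ci],
                                        IRanges(tss - geneWidth + 1L, tss),
                                        strand = str)
                    pad <- cand
                    start(pad) <- max(1L, start(pad) - 2100L)
                    end(pad) <- min(len, end(pad) + 2100L)
                    if (length(placed) == 0L ||
                        !any(GenomicRanges::countOverlaps(pad, placed) > 0L)) {
                        placed <- c(placed, cand)
                        ok <- TRUE
                        break
                    }
                }
                if (!ok)
                    stop("could not place gene ", g, " on chromosome ",
                         ci, " after ", maxRetries, " retries")
            }
            grl[[ci]] <- placed
        }
        genes <- suppressWarnings(do.call(c, grl))
        GenomeInfoDb::seqlevels(genes) <- names(genome)
        GenomeInfoDb::seqlengths(genes) <-
            stats::setNames(Biostrings::width(genome), names(genome))
        genes <- sort(genes, ignore.strand = TRUE)
        mcols(genes)$gene_id <- sprintf("gene%03d", seq_along(genes))
        mcols(genes)$active <-
            stats::runif(length(genes)) < config$activeFraction
        genes
    })
}

# add a boxcar of the given height over [from, to] (1-based bases) to a
# per-chromosome bin-value list
.addBoxcar <- function(values, binSize, from, to, height) {
    b1 <- max(1L, (from - 1L) %/% binSize + 1L)
    b2 <- min(length(values), (to - 1L) %/% binSize + 1L)
    if (b1 <= b2)
        values[b1:b2] <- values[b1:b2] + height
    values
}

#' Generate condition-labelled signal tracks with planted peaks
#'
#' Builds the mock/DNR SUMO-2/3 tracks plus CTCF and histone-mark tracks
#' over Poisson background noise. SUMO boxcar peaks are centred about
#' 100 bp upstream of every TSS and at planted enhancer centres; the DNR
#' SUMO track shares the same background and planted peaks scaled by
#' \code{dnrDepletionFactor}, so a factor of 1 gives identical tracks.
#' H3K4me3 marks active promoters, H3K4me1 all enhancers, H3K27ac active
#' elements; CTCF is co-placed with a configurable fraction of SUMO
#' peaks. Planted element placements that cannot avoid collisions within
#' a bounded number of retries raise an error.
#'
#' @param config a [simulationConfig()].
#' @param genome `DNAStringSet`.
#' @param genes `GRanges` from [makeGenes()].
#' @param maxRetries retries when placing enhancers.
#' @return list with \code{tracks} (named list of track sets, one
#'   [SignalTrack-class] per chromosome each) and \code{truth} (planted
#'   intervals: \code{sumoPeaks}, \code{enhancers}, \code{ctcfSites}).
#' @export
makeTracks <- function(config, genome, genes, maxRetries = 200L) {
    stopifnot(inherits(config, "SimulationConfig"))
    .withSeed(config$seed + .SEED_OFFSETS[["tracks"]], {
        bs <- config$binSize
        chroms <- names(genome)
        lens <- stats::setNames(Biostrings::width(genome), chroms)
        nbins <- ceiling(lens / bs)
        halfPeak <- 200L

        # planted SUMO peaks ~100 bp upstream of each TSS
        str <- as.character(strand(genes))
        tss <- ifelse(str == "+", start(genes), end(genes))
        center <- ifelse(str == "+", tss - 100L, tss + 100L)
        sumoPeaks <- GRanges(seqnames(genes),
                             IRanges(pmax(1L, center - halfPeak),
                                     pmin(lens[as.character(seqnames(genes))],
                                          center + halfPeak - 1L)))
        mcols(sumoPeaks)$elementType <- "promoter"
        mcols(sumoPeaks)$gene_id <- mcols(genes)$gene_id
        mcols(sumoPeaks)$active <- mcols(genes)$active

        # planted enhancers outside promoters (rejection-resampled); the
        # 700 bp margin keeps planted peaks beyond max-gap bridging range
        promZone <- GRanges(seqnames(genes),
                            IRanges(pmax(1L, pmin(tss - 2000L, tss)),
                                    pmax(tss + 2000L, tss)))
        avoid <- c(granges(sumoPeaks) + 700L, promZone + 700L)
        enh <- GRanges()
        perChrom <- diff(floor(seq(0, config$nEnhancers,
                                   length.out = length(chroms) + 1L)))
        for (ci in seq_along(chroms)) {
            for (e in seq_len(perChrom[ci])) {
                ok <- FALSE
                for (try in seq_len(maxRetries)) {
                    c0 <- sample(seq.int(2500L, lens[ci] - 2500L), 1L)
                    cand <- GRanges(chroms[ci],
                                    IRanges(c0 - halfPeak, c0 + halfPeak - 1L))
                    if (!any(GenomicRanges::countOverlaps(cand, avoid) > 0L) &&
                        (length(enh) == 0L ||
                         !any(GenomicRanges::countOverlaps(cand, enh + 600L) > 0L))) {
                        enh <- c(enh, cand)
                        ok <- TRUE
                        break
                    }
                }
                if (!ok)
                    stop("could not place enhancer ", e, " on ", chroms[ci],
                         " after ", maxRetries, " retries")
            }
        }
        if (length(enh) > 0L) {
            mcols(enh)$elementType <- "enhancer"
            mcols(enh)$gene_id <- NA_character_
            mcols(enh)$active <-
                stats::runif(length(enh)) < config$activeFraction
        }

        # CTCF co-placed with a fraction of SUMO peaks (promoter + enhancer)
        allSumo <- c(sumoPeaks, enh)
        nCtcf <- round(config$ctcfFraction * length(allSumo))
        ctcfIdx <- if (nCtcf > 0L)
            sort(sample(seq_along(allSumo), nCtcf)) else integer(0)
        ctcfSites <- granges(allSumo)[ctcfIdx]

        h <- config$promoterSumoHeight
        emptyVals <- lapply(nbins, function(n) numeric(n))
        addAll <- function(values, gr, height) {
            for (i in seq_along(gr)) {
                chr <- as.character(seqnames(gr))[i]
                values[[chr]] <- .addBoxcar(values[[chr]], bs,
                                            start(gr)[i], end(gr)[i], height)
            }
            values
        }
        background <- function() lapply(nbins, function(n)
            as.numeric(stats::rpois(n, config$backgroundMean)))

        active <- mcols(allSumo)$active
        sumoSignal <- addAll(emptyVals, allSumo, h)
        bgShared <- background()
        mock <- Map(`+`, bgShared, sumoSignal)
        dnr <- Map(`+`, bgShared,
                   lapply(sumoSignal, `*`, config$dnrDepletionFactor))

        k4me3 <- addAll(background(), sumoPeaks[mcols(sumoPeaks)$active], h)
        k4me1 <- addAll(background(), enh, h)
        k27 <- addAll(background(), allSumo[active], h)
        ctcf <- addAll(background(), ctcfSites, 400)

        toTracks <- function(values) {
            out <- lapply(names(values), function(chr)
                SignalTrack(chr, values[[chr]], binSize = bs))
            names(out) <- names(values)
            out
        }
        list(tracks = list(sumo_mock = toTracks(mock),
                           sumo_dnr = toTracks(dnr),
                           ctcf = toTracks(ctcf),
                           h3k4me1 = toTracks(k4me1),
                           h3k4me3 = toTracks(k4me3),
                           h3k27ac = toTracks(k27)),
             truth = list(sumoPeaks = allSumo,
                          enhancers = enh,
                          ctcfSites = ctcfSites))
    })
}
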