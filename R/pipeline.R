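# End-to-end orchestration: simulate -> peak calling -> annotation ->
# interval crossing -> 4C -> SILAC -> differential expression -> gene-list
# crossing, with truth scoring and a machine-readable report.

.defaultRunConfig <- function() {
    list(seed = 1L,
         simulation = list(),
         peaks = list(sumo = list(threshold = 32, maxGap = 100, minRun = 100),
                      ctcf = list(threshold = 360, maxGap = 50, minRun = 50),
                      marks = list(threshold = 32, maxGap = 100,
                                   minRun = 100)),
         fourc = list(alpha = 0.05, smoothingWindow = 21L,
                      exclusionWindow = 2L, k = 20L, mergeGap = 1L,
                      strataSize = 50L, replicates = 3L),
         silac = list(cutoff = 0.5),
         de = list(fcLinear = 2, fdr = 0.05),
         cross = list(modulationFactor = 2, modulationMode = "contrast"))
}

.mergeConfig <- function(user, defaults, path = "") {
    for (key in names(user)) {
        full <- if (nzchar(path)) paste(path, key, sep = ".") else key
        if (!key %in% names(defaults))
            stop("unknown config key: '", full, "'")
        if (is.list(defaults[[key]]) && is.list(user[[key]]) &&
            key != "simulation")
            defaults[[key]] <- .mergeConfig(user[[key]], defaults[[key]],
                                            full)
        else
            defaults[[key]] <- user[[key]]
    }
    defaults
}

#' Load and validate a pipeline run configuration
#'
#' Accepts a YAML file path or a nested list with per-stage parameter
#' blocks (\code{seed}, \code{simulation}, \code{peaks}, \code{fourc},
#' \code{silac}, \code{de}, \code{cross}); unknown keys are rejected.
#' Unspecified values take the stage defaults. The \code{simulation}
#' block is passed to [simulationConfig()].
#'
#' @param config path to a YAML file, a list, or \code{NULL} for
#'   defaults.
#' @return validated nested configuration list.
#' @export
loadRunConfig <- function(config = NULL) {
    if (is.character(config))
        config <- yaml::read_yaml(config)
    if (is.null(config))
        config <- list()
    stopifnot(is.list(config))
    .mergeConfig(config, .defaultRunConfig())
}

.score <- function(truthGr, calledGr) {
    if (length(truthGr) == 0L)
        return(list(sensitivity = NA_real_, precision = NA_real_))
    sens <- mean(GenomicRanges::countOverlaps(truthGr, calledGr) > 0L)
    prec <- if (length(calledGr) == 0L) NA_real_
            else mean(GenomicRanges::countOverlaps(calledGr, truthGr) > 0L)
    list(sensitivity = sens, precision = prec)
}

.setScore <- function(truth, called) {
    list(sensitivity = if (length(truth) == 0L) NA_real_
                       else length(intersect(truth, called)) / length(truth),
         precision = if (length(called) == 0L) NA_real_
                     else length(intersect(truth, called)) / length(called))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the requested stages in dependency order, writing stage
#' outputs under \code{outdir} and a machine-readable \code{report.json}
#' that includes sensitivity/precision per stage against the simulation
#' truth manifest. A stage failure halts downstream stages; partial
#' outputs are retained and the failed stage is labelled in the report.
#' All analysis inputs are read back from the files the simulation stage
#' wrote, so identical config and seed give byte-identical outputs.
#'
#' @param config run configuration ([loadRunConfig()] input).
#' @param outdir output directory.
#' @param stages stages to run, in order.
#' @return (invisibly) the report list.
#' @export
runPipeline <- function(config = NULL, outdir = tempfile("sumopipe_run"),
                        stages = c("simulate", "peakcall", "annotate",
                                   "intersect", "fourc", "silac", "de",
                                   "cross")) {
    cfg <- loadRunConfig(config)
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    report <- list(seed = cfg$seed,
                   packageVersion =
                       as.character(utils::packageVersion("sumopipe")),
                   stages = list())
    env <- new.env(parent = emptyenv())
    halted <- FALSE

    runStage <- function(name, fun) {
        if (halted || !name %in% stages) {
            if (!halted && !name %in% stages) return(invisible(NULL))
            report$stages[[name]] <<- list(status = "skipped")
            return(invisible(NULL))
        }
        res <- tryCatch({
            out <- fun()
            c(list(status = "ok"), out)
        }, error = function(e) {
            halted <<- TRUE
            list(status = "failed", error = conditionMessage(e))
        })
        report$stages[[name]] <<- res
        invisible(NULL)
    }

    runStage("simulate", function() {
        simCfg <- do.call(simulationConfig,
                          c(list(seed = cfg$seed), cfg$simulation))
        env$simCfg <- simCfg
        env$sim <- simulateAll(simCfg, outdir,
                               fourcReplicates = cfg$fourc$replicates)
        list(nGenes = length(env$sim$genes),
             genomeBases = sum(Biostrings::width(env$sim$genome)))
    })

    runStage("peakcall", function() {
        trackFiles <- list.files(file.path(outdir, "tracks"),
                                 full.names = TRUE)
        names(trackFiles) <- sub("\\.wig$", "", basename(trackFiles))
        env$peaks <- list()
        out <- list()
        for (nm in names(trackFiles)) {
            pars <- if (startsWith(nm, "sumo")) cfg$peaks$sumo
                    else if (nm == "ctcf") cfg$peaks$ctcf
                    else cfg$peaks$marks
            tracks <- readWiggle(trackFiles[[nm]])
            pk <- suppressWarnings(do.call(c, unname(lapply(
                tracks, callPeaks,
                valueThreshold = pars$threshold,
                maxGap = pars$maxGap, minRun = pars$minRun))))
            env$peaks[[nm]] <- pk
            writePeaksBed(pk, file.path(outdir, paste0("peaks_", nm, ".bed")))
            out[[paste0("n_", nm)]] <- length(pk)
        }
        truth <- env$sim$trackTruth$sumoPeaks
        sc <- .score(truth, env$peaks$sumo_mock)
        mockSummary <- peakSummary(env$peaks$sumo_mock)
        dnrSummary <- peakSummary(env$peaks$sumo_dnr)
        c(out, list(sumoPeakScore = sc,
                    mockMeanIntensity = mockSummary$meanIntensity,
                    dnrMeanIntensity = dnrSummary$meanIntensity))
    })

    runStage("annotate", function() {
        genes <- readGenesGff3(file.path(outdir, "genes.gff3"))
        env$genes <- genes
        prom <- definePromoters(genes, env$peaks$h3k4me3)
        enh <- defineEnhancers(env$peaks$h3k4me1, prom)
        prom <- classifyActivity(prom, env$peaks$h3k27ac)
        enh <- classifyActivity(enh, env$peaks$h3k27ac)
        env$promoters <- prom
        env$enhancers <- enh
        anchors <- GRanges(seqnames(genes),
                           IRanges(ifelse(strand(genes) == "+",
                                          start(genes), end(genes)),
                                   width = 1L),
                           strand = strand(genes))
        mockTracks <- readWiggle(file.path(outdir, "tracks",
                                           "sumo_mock.wig"))
        dnrTracks <- readWiggle(file.path(outdir, "tracks",
                                          "sumo_dnr.wig"))
        mp <- metaprofile(mockTracks, anchors, flank = 1000, bin = 50)
        mpD <- metaprofile(dnrTracks, anchors, flank = 1000, bin = 50)
        .writeTsv(data.frame(position = mp$positions,
                             mock = mp$profile, dnr = mpD$profile),
                  file.path(outdir, "metaprofile_sumo_promoters.tsv"))
        enhScore <- .score(env$sim$trackTruth$enhancers, enh)
        list(nPromoters = length(prom), nEnhancers = length(enh),
             nActivePromoters = sum(mcols(prom)$active),
             enhancerScore = enhScore,
             meanMockProfile = mean(mp$profile),
             meanDnrProfile = mean(mpD$profile))
    })

    runStage("intersect", function() {
        sumoPk <- env$peaks$sumo_mock
        ctcfPk <- env$peaks$ctcf
        fb <- fractionBound(sumoPk, ctcfPk)
        env$sumoCtcfGenes <- genesWithPromoterFeature(env$promoters,
                                                      sumoPk, ctcfPk)
        writeGeneList(env$sumoCtcfGenes,
                      file.path(outdir, "genes_sumo_ctcf_promoters.txt"))
        list(fractionSumoBoundByCtcf = fb,
             nSumoCtcfGenes = length(env$sumoCtcfGenes))
    })

    runStage("fourc", function() {
        genome <- Biostrings::readDNAStringSet(
            file.path(outdir, "genome.fasta"))
        names(genome) <- sub("\\s.*", "", names(genome))
        map <- digestGenome(genome)
        vpDf <- utils::read.delim(file.path(outdir, "truth",
                                            "viewpoint.tsv"))
        vp <- GRanges(vpDf$chrom, IRanges(vpDf$start + 1L, vpDf$end))
        fq <- list.files(file.path(outdir, "fourc"), pattern = "\\.fastq$",
                         full.names = TRUE)
        profiles <- list()
        for (f in fq) {
            key <- sub("\\.fastq$", "", basename(f))
            cond <- sub("_rep[0-9]+$", "", key)
            rep <- sub("^.*_(rep[0-9]+)$", "\\1", key)
            reads <- readFastq(f)
            tr <- trimCapture(reads)
            mp <- mapReads(tr$trimmed, genome, k = cfg$fourc$k)
            counts <- assignToFragments(mp$placements, map)
            prof <- normalizeProfile(counts, map, vp,
                                     exclusionWindow =
                                         cfg$fourc$exclusionWindow,
                                     replicate = rep, condition = cond)
            profiles[[key]] <- prof
            writeProfileTsv(prof, file.path(
                outdir, "fourc", paste0("profile_", key, ".tsv")))
        }
        env$profiles <- profiles
        conds <- unique(vapply(profiles, profileCondition, character(1)))
        regionsByCond <- list()
        for (cond in conds) {
            pp <- profiles[vapply(profiles, profileCondition,
                                  character(1)) == cond]
            regionsByCond[[cond]] <- callInteractions(
                pp, alpha = cfg$fourc$alpha,
                smoothingWindow = cfg$fourc$smoothingWindow,
                mergeGap = cfg$fourc$mergeGap,
                strataSize = cfg$fourc$strataSize)
        }
        env$regionsByCond <- regionsByCond
        allRegions <- GenomicRanges::reduce(
            suppressWarnings(do.call(c, lapply(unname(regionsByCond),
                                               granges))))
        diffRes <- NULL
        if (length(allRegions) > 0L && length(conds) >= 2L) {
            mcols(allRegions)$label <-
                as.character(utils::as.roman(seq_along(allRegions)))
            dc <- differentialContacts(allRegions, profiles,
                                       contrast = conds[1:2])
            diffRes <- dc$results
            .writeTsv(diffRes, file.path(outdir, "fourc",
                                         "differential_contacts.tsv"))
        }
        truthRegions <- env$sim$fourc[[1L]]$truth$plantedRegions
        strong <- truthRegions[mcols(truthRegions)$fold >= 4]
        sc <- .score(strong, regionsByCond[[1L]])
        for (cond in conds)
            .writeTsv(.grToDf(regionsByCond[[cond]]),
                      file.path(outdir, "fourc",
                                paste0("interactions_", cond, ".tsv")))
        list(nRegions = vapply(regionsByCond, length, integer(1)),
             interactionScore = sc,
             nDifferentialRegions = if (is.null(diffRes)) 0L
                 else sum(diffRes$padj < cfg$de$fdr, na.rm = TRUE))
    })

    runStage("silac", function() {
        tab <- utils::read.delim(file.path(outdir, "silac_ratios.tsv"))
        cls <- classifyRatios(tab, cutoff = cfg$silac$cutoff)
        env$silacSets <- cls
        upUnion <- unionReport(cls$sumo23$up, cls$sumo1$up)
        downUnion <- unionReport(cls$sumo23$down, cls$sumo1$down)
        writeGeneList(upUnion$members,
                      file.path(outdir, "silac_up_union.txt"))
        writeGeneList(downUnion$members,
                      file.path(outdir, "silac_down_union.txt"))
        truth <- env$sim$silac$truth
        list(upS23 = length(cls$sumo23$up), upS1 = length(cls$sumo1$up),
             upCommon = upUnion$intersectionSize,
             upUnion = upUnion$unionSize,
             downUnion = downUnion$unionSize,
             upS23Score = .setScore(truth$upS23, cls$sumo23$up),
             downS23Score = .setScore(truth$downS23, cls$sumo23$down))
    })

    runStage("de", function() {
        cnt <- utils::read.delim(file.path(outdir, "counts.tsv"),
                                 check.names = FALSE)
        counts <- as.matrix(cnt[, -1L])
        rownames(counts) <- cnt$gene
        design <- utils::read.delim(file.path(outdir, "design.tsv"))
        cond <- stats::setNames(design$condition, design$sample)
        ladder <- list(c("mock", "DNR"), c("mock", "ML792"),
                       c("mock", "ML792_DNR"), c("DNR", "ML792_DNR"))
        env$deResults <- list()
        out <- list()
        for (ct in ladder) {
            if (!all(ct %in% cond)) next
            keep <- cond %in% ct
            res <- nbTest(counts[, keep, drop = FALSE],
                          factor(cond[keep], levels = ct))
            res$padj <- bhAdjust(res$pvalue)
            degs <- degFilter(res, fcLinear = cfg$de$fcLinear,
                              fdr = cfg$de$fdr)
            key <- paste(ct[2L], "vs", ct[1L], sep = "_")
            env$deResults[[key]] <- list(res = res, degs = degs)
            .writeTsv(degs$table, file.path(outdir,
                                            paste0("de_", key, ".tsv")))
            out[[paste0("nDEG_", key)]] <-
                length(degs$up) + length(degs$down)
        }
        truth <- env$sim$counts$truth
        dnr <- env$deResults[["DNR_vs_mock"]]
        sc <- .setScore(c(truth$up, truth$down),
                        c(dnr$degs$up, dnr$degs$down))
        c(out, list(degScore = sc))
    })

    runStage("cross", function() {
        dnr <- env$deResults[["DNR_vs_mock"]]
        combo <- env$deResults[["ML792_DNR_vs_DNR"]]
        degs <- c(dnr$degs$up, dnr$degs$down)
        lfc <- stats::setNames(combo$res$log2FoldChange, combo$res$gene)
        mod <- modulatedGenes(lfc, factor = cfg$cross$modulationFactor,
                              mode = cfg$cross$modulationMode)
        crossed <- crossGeneLists(
            list(sumo_ctcf_promoters = env$sumoCtcfGenes,
                 degs = degs, ml792_modulated = mod),
            mode = "intersection")
        writeGeneList(crossed$result,
                      file.path(outdir, "crossed_genes.txt"))
        .writeTsv(crossed$report, file.path(outdir, "cross_report.tsv"))
        list(nSumoCtcf = length(env$sumoCtcfGenes),
             nDEGs = length(degs), nModulated = length(mod),
             nCrossed = length(crossed$result))
    })

    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    provenance <- list(config = cfg,
                       rVersion = R.version.string,
                       packageVersion =
                           as.character(utils::packageVersion("sumopipe")))
    jsonlite::write_json(provenance, file.path(outdir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(report)
}
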