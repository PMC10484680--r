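# One-call simulation driver writing every pipeline input plus the truth
# manifest, so downstream stages can be exercised purely by file contract.

.grToDf <- function(gr, extra = TRUE) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L,  # 0-based half-open on disk
                     end = end(gr),
                     strand = as.character(strand(gr)))
    if (extra && ncol(mcols(gr)) > 0L)
        df <- cbind(df, as.data.frame(mcols(gr)))
    df
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a gene annotation as GFF3
#'
#' @param genes `GRanges` with \code{gene_id}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGenesGff3 <- function(genes, path) {
    out <- genes
    mcols(out) <- NULL
    mcols(out)$type <- "gene"
    mcols(out)$ID <- mcols(genes)$gene_id
    mcols(out)$Name <- mcols(genes)$gene_id
    rtracklayer::export(out, path, format = "gff3")
    invisible(path)
}

#' Read a GFF3 gene annotation
#'
#' @param path GFF3 file.
#' @return `GRanges` with a \code{gene_id} column.
#' @export
readGenesGff3 <- function(path) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    mcols(gr) <- DataFrame(gene_id = gr$ID)
    gr
}

#' Generate every pipeline input with its truth manifest
#'
#' Runs all generators under the config seed and writes: the genome
#' (FASTA, with the 4C capture planted at a central viewpoint fragment),
#' the gene annotation (GFF3), the six signal tracks (fixed-step wiggle),
#' 4C FASTQ read sets (three replicates for mock and DNR), the SILAC
#' ratio table, the RNA-seq count matrix with its design (four-condition
#' comparisons ladder), and a \code{truth/} directory of TSV manifests
#' with every planted interval and set, against which downstream stages
#' are scored.
#'
#' @param config a [simulationConfig()].
#' @param outdir output directory (created if missing).
#' @param fourcConditions conditions simulated for 4C.
#' @param fourcReplicates replicates per 4C condition.
#' @return (invisibly) a list with all in-memory objects: genome, genes,
#'   tracks, viewpoint, fourc (reads + truths), silac, counts, paths.
#' @export
simulateAll <- function(config, outdir,
                        fourcConditions = c("mock", "DNR"),
                        fourcReplicates = 3L) {
    stopifnot(inherits(config, "SimulationConfig"))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(outdir, "tracks"), showWarnings = FALSE)
    dir.create(file.path(outdir, "fourc"), showWarnings = FALSE)
    dir.create(file.path(outdir, "truth"), showWarnings = FALSE)

    genome0 <- makeGenome(config)
    planted <- plantCaptureSite(genome0)
    genome <- planted$genome
    genes <- makeGenes(config, genome)
    trk <- makeTracks(config, genome, genes)

    Biostrings::writeXStringSet(genome, file.path(outdir, "genome.fasta"))
    writeGenesGff3(genes, file.path(outdir, "genes.gff3"))
    for (nm in names(trk$tracks))
        writeWiggle(trk$tracks[[nm]],
                    file.path(outdir, "tracks", paste0(nm, ".wig")),
                    name = nm)

    fourc <- list()
    readTallies <- NULL
    for (cond in fourcConditions) {
        for (r in seq_len(fourcReplicates)) {
            rep <- paste0("rep", r)
            sim <- make4CReads(config, genome, planted$viewpoint,
                               condition = cond, replicate = rep)
            fq <- file.path(outdir, "fourc",
                            sprintf("%s_%s.fastq", cond, rep))
            writeFastq(sim$reads, fq)
            key <- paste(cond, rep, sep = "_")
            fourc[[key]] <- sim
            readTallies <- rbind(readTallies, data.frame(
                condition = cond, replicate = rep,
                nReads = length(sim$reads),
                nCapture = sim$truth$nCapture,
                nDecoy = sim$truth$nDecoy,
                vpIndex = sim$truth$vpIndex))
        }
    }

    silac <- makeSilacTable(config)
    .writeTsv(silac$table, file.path(outdir, "silac_ratios.tsv"))

    genomeIds <- mcols(genes)$gene_id
    nExpr <- max(500L, length(genomeIds))
    exprIds <- c(genomeIds,
                 sprintf("xgene%04d", seq_len(nExpr - length(genomeIds))))
    cnt <- makeCounts(config, nGenes = nExpr,
                      conditions = c("mock", "DNR", "ML792", "ML792_DNR"),
                      geneIds = exprIds)
    .writeTsv(cbind(gene = rownames(cnt$counts),
                    as.data.frame(cnt$counts)),
              file.path(outdir, "counts.tsv"))
    .writeTsv(data.frame(sample = colnames(cnt$counts),
                         condition = as.character(cnt$conditions)),
              file.path(outdir, "design.tsv"))

    # truth manifest
    .writeTsv(.grToDf(trk$truth$sumoPeaks),
              file.path(outdir, "truth", "sumo_peaks.tsv"))
    .writeTsv(.grToDf(trk$truth$enhancers),
              file.path(outdir, "truth", "enhancers.tsv"))
    .writeTsv(.grToDf(trk$truth$ctcfSites),
              file.path(outdir, "truth", "ctcf_sites.tsv"))
    .writeTsv(.grToDf(planted$viewpoint, extra = FALSE),
              file.path(outdir, "truth", "viewpoint.tsv"))
    firstKey <- names(fourc)[1L]
    .writeTsv(.grToDf(fourc[[firstKey]]$truth$plantedRegions),
              file.path(outdir, "truth", "fourc_interactions_mock.tsv"))
    .writeTsv(readTallies,
              file.path(outdir, "truth", "fourc_read_tallies.tsv"))
    silacTruthDf <- data.frame(
        set = rep(names(silac$truth),
                  vapply(silac$truth, length, integer(1))),
        protein = unlist(silac$truth, use.names = FALSE))
    .writeTsv(silacTruthDf, file.path(outdir, "truth", "silac_sets.tsv"))
    deTruthDf <- data.frame(
        set = rep(names(cnt$truth),
                  vapply(cnt$truth, length, integer(1))),
        gene = unlist(cnt$truth, use.names = FALSE))
    .writeTsv(deTruthDf, file.path(outdir, "truth", "de_genes.tsv"))

    invisible(list(genome = genome, genes = genes, tracks = trk$tracks,
                   trackTruth = trk$truth, viewpoint = planted$viewpoint,
                   fourc = fourc, silac = silac, counts = cnt,
                   outdir = outdir))
}
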