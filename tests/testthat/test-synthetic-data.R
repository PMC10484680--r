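test_that("genomes are deterministic, seed-sensitive and site-uniform", {
    cfg1 <- simulationConfig(seed = 1, chromLength = 50000L)
    g1 <- makeGenome(cfg1)
    expect_equal(Biostrings::width(g1), 50000L)
    expect_identical(as.character(g1), as.character(makeGenome(cfg1)))
    cfg2 <- simulationConfig(seed = 2, chromLength = 50000L)
    expect_false(identical(as.character(g1),
                           as.character(makeGenome(cfg2))))
    # CATG occurrences near the 4-mer expectation of n/256 (within 3 SD)
    nSites <- Biostrings::countPattern("CATG", g1[[1]])
    expected <- 50000 / 256
    sd3 <- 3 * sqrt(50000 * (1 / 256) * (255 / 256))
    expect_lt(abs(nSites - expected), sd3)
    expect_error(simulationConfig(chromLength = 0), "positive")
    expect_error(simulationConfig(chromLength = 5000), "10000")
})

test_that("config validation enforces the planted-set invariants", {
    expect_error(simulationConfig(silacCounts = c(
        nUpS23 = 5L, nUpS1 = 3L, nCommonUp = 4L,
        nDownS23 = 1L, nDownS1 = 1L, nCommonDown = 1L)),
        "common")
    expect_error(simulationConfig(dnrDepletionFactor = 0), "dnrDepletionFactor")
    expect_error(simulationConfig(nSilacProteins = 10L), "universe")
})

test_that("tracks share noise so depletion factor 1 gives identity", {
    cfg <- simulationConfig(seed = 3, chromLength = 60000L, nGenes = 8L,
                            nEnhancers = 3L, dnrDepletionFactor = 1)
    gen <- makeGenome(cfg)
    genes <- makeGenes(cfg, gen)
    trk <- makeTracks(cfg, gen, genes)
    expect_identical(trackValues(trk$tracks$sumo_mock$chr1),
                     trackValues(trk$tracks$sumo_dnr$chr1))

    cfgD <- simulationConfig(seed = 3, chromLength = 60000L, nGenes = 8L,
                             nEnhancers = 3L, dnrDepletionFactor = 0.3)
    trkD <- makeTracks(cfgD, gen, makeGenes(cfgD, gen))
    prom <- trkD$truth$sumoPeaks
    binsOf <- function(tr, gr) {
        unlist(lapply(seq_along(gr), function(i)
            trackValues(tr$chr1)[((start(gr)[i] - 1) %/% 50 + 1):
                                 (end(gr)[i] %/% 50)]))
    }
    expect_lt(mean(binsOf(trkD$tracks$sumo_dnr, prom)),
              mean(binsOf(trkD$tracks$sumo_mock, prom)))
})

test_that("noise-free planted peaks are recovered exactly by the caller", {
    cfg <- simulationConfig(seed = 4, chromLength = 60000L, nGenes = 6L,
                            nEnhancers = 2L, backgroundMean = 0,
                            promoterSumoHeight = 64)
    gen <- makeGenome(cfg)
    genes <- makeGenes(cfg, gen)
    trk <- makeTracks(cfg, gen, genes)
    called <- callPeaks(trk$tracks$sumo_mock$chr1, 32, 100, 100)
    truth <- sort(granges(trk$truth$sumoPeaks))
    # recovered intervals are the planted ones, snapped to bin boundaries
    expect_equal(length(called), length(truth))
    expect_true(all(abs(start(called) - start(truth)) < 50))
    expect_true(all(abs(end(called) - end(truth)) < 50))
})

test_that("generators are pure functions of the config", {
    cfg <- simulationConfig(seed = 5, chromLength = 50000L, nGenes = 5L,
                            n4cReads = 500L,
                            plantedInteractions = data.frame(
                                offsetFragments = c(25L, -30L),
                                nFragments = 5L,
                                foldMock = 8, foldDnr = 8))
    g <- makeGenome(cfg)
    pl <- plantCaptureSite(g)
    r1 <- make4CReads(cfg, pl$genome, pl$viewpoint)
    r2 <- make4CReads(cfg, pl$genome, pl$viewpoint)
    expect_identical(as.character(r1$reads), as.character(r2$reads))
    s1 <- makeSilacTable(cfg)
    s2 <- makeSilacTable(cfg)
    expect_identical(s1$table, s2$table)
    c1 <- makeCounts(cfg)
    expect_identical(c1$counts, makeCounts(cfg)$counts)
    # and replicate streams differ
    r3 <- make4CReads(cfg, pl$genome, pl$viewpoint, replicate = "rep2")
    expect_false(identical(as.character(r1$reads),
                           as.character(r3$reads)))
})

test_that("null count matrices yield FDR-controlled DEG calls", {
    cfg <- simulationConfig(seed = 6,
                            deCounts = c(nUp = 0, nDown = 0, log2fc = 2,
                                         dispersion = 0.05))
    mc <- makeCounts(cfg, nGenes = 500L)
    res <- nbTest(mc$counts, mc$conditions)
    degs <- degFilter(transform(res, padj = bhAdjust(pvalue)))
    expect_equal(length(degs$up) + length(degs$down), 0L)
})

test_that("planted DE genes are recovered at the stated settings", {
    cfg <- simulationConfig(seed = 7)   # log2fc 2, 3 vs 3 samples
    mc <- makeCounts(cfg)
    res <- nbTest(mc$counts, mc$conditions)
    degs <- degFilter(transform(res, padj = bhAdjust(pvalue)))
    truth <- c(mc$truth$up, mc$truth$down)
    recovered <- length(intersect(c(degs$up, degs$down), truth))
    expect_gte(recovered / length(truth), 0.9)
})

test_that("simulateAll writes inputs and a scoreable truth manifest", {
    cfg <- simulationConfig(seed = 8, chromLength = 50000L, nGenes = 6L,
                            nEnhancers = 2L, n4cReads = 2000L,
                            plantedInteractions = data.frame(
                                offsetFragments = c(25L, -30L),
                                nFragments = 5L,
                                foldMock = 8, foldDnr = 2))
    outdir <- withr::local_tempdir()
    sim <- simulateAll(cfg, outdir, fourcReplicates = 2L)
    expect_true(file.exists(file.path(outdir, "genome.fasta")))
    expect_true(file.exists(file.path(outdir, "genes.gff3")))
    expect_length(list.files(file.path(outdir, "tracks")), 6L)
    expect_length(list.files(file.path(outdir, "fourc")), 4L)
    truthFiles <- list.files(file.path(outdir, "truth"))
    expect_true(all(c("sumo_peaks.tsv", "silac_sets.tsv", "de_genes.tsv",
                      "fourc_read_tallies.tsv") %in% truthFiles))
    # the GFF3 round trip preserves gene ids and strands
    back <- sort(readGenesGff3(file.path(outdir, "genes.gff3")))
    genes <- sort(sim$genes)
    expect_setequal(back$gene_id, mcols(genes)$gene_id)
    expect_equal(start(back), start(genes))
    expect_equal(end(back), end(genes))
    expect_equal(as.character(strand(back)), as.character(strand(genes)))
})
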