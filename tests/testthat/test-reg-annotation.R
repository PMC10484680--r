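test_that("promoters are the 2 kb upstream of the TSS, strand-aware", {
    gp <- GRanges("chr1:5001-6000:+", gene_id = "gp")
    pp <- definePromoters(gp)
    expect_equal(start(pp), 3001L)   # [3000, 5000) half-open
    expect_equal(end(pp), 5000L)
    expect_false(mcols(pp)$clipped)

    gm <- GRanges("chr1", IRanges(4001, 5000), strand = "-", gene_id = "gm")
    pm <- definePromoters(gm)
    expect_equal(start(pm), 5000L)   # [4999, 6999) half-open
    expect_equal(end(pm), 6999L)

    # TSS closer than 2 kb to the chromosome start is clipped and flagged
    gc <- GRanges("chr1:501-1500:+", gene_id = "gc")
    pc <- definePromoters(gc)
    expect_equal(start(pc), 1L)
    expect_equal(end(pc), 500L)
    expect_true(mcols(pc)$clipped)
})

test_that("promoters keep their annotation and record H3K4me3 support", {
    g <- GRanges(c("chr1:5001-6000:+", "chr1:20001-21000:+"),
                 gene_id = c("a", "b"))
    k4 <- GRanges("chr1", IRanges(4000, 4500))
    p <- definePromoters(g, h3k4me3Peaks = k4)
    expect_equal(mcols(p)$h3k4me3Supported, c(TRUE, FALSE))
    expect_length(p, 2L)  # unsupported promoters are kept, only flagged
})

test_that("candidate enhancers exclude any promoter-overlapping peak", {
    prom <- GRanges("chr1", IRanges(3001, 5000), gene_id = "a")
    inside <- GRanges("chr1", IRanges(3500, 3700))
    touching <- GRanges("chr1", IRanges(4900, 5200))  # 1-base overlap counts
    outside <- GRanges("chr1", IRanges(8000, 8400))
    enh <- defineEnhancers(c(inside, touching, outside), prom)
    expect_equal(granges(enh), granges(outside))

    # brute-force agreement on random inputs
    set.seed(31)
    for (rep in 1:10) {
        peaks <- randomGRanges(100)
        proms <- randomGRanges(30)
        keep <- vapply(seq_along(peaks), function(i)
            nrow(overlapOracle(peaks[i], proms)) == 0L, logical(1))
        expect_equal(granges(defineEnhancers(peaks, proms)),
                     granges(peaks[keep]))
    }
})

test_that("activity requires a >= 1 base H3K27ac overlap (half-open)", {
    el <- GRanges("chr1", IRanges(1000, 1999))
    over <- GRanges("chr1", IRanges(1999, 2100))
    adjacent <- GRanges("chr1", IRanges(2000, 2100))  # end==start half-open
    expect_true(mcols(classifyActivity(el, over))$active)
    expect_false(mcols(classifyActivity(el, adjacent))$active)
    expect_false(mcols(classifyActivity(el, GRanges()))$active)
})

test_that("metaprofiles average strand-oriented anchor windows", {
    # constant track: profile is that constant everywhere
    st <- SignalTrack("chr1", rep(7, 100), binSize = 50)
    anchors <- GRanges("chr1", IRanges(c(2000, 3000), width = 1),
                       strand = c("+", "-"))
    mp <- metaprofile(st, anchors, flank = 500, bin = 50)
    expect_equal(mp$profile, rep(7, 20))
    expect_equal(mp$anchorsUsed, 2L)

    # single anchor reads back the bin values; minus strand reverses them
    vals <- seq_len(100)
    stv <- SignalTrack("chr1", vals, binSize = 50)
    a1 <- GRanges("chr1", IRanges(2501, width = 1), strand = "+")
    mp1 <- metaprofile(stv, a1, flank = 250, bin = 50)
    expect_equal(mp1$profile, vals[46:55])
    a2 <- GRanges("chr1", IRanges(2501, width = 1), strand = "-")
    mp2 <- metaprofile(stv, a2, flank = 250, bin = 50)
    expect_equal(mp2$profile, rev(vals[46:55]))

    # anchors whose window exits the chromosome are dropped and counted
    a3 <- GRanges("chr1", IRanges(c(100, 2501), width = 1), strand = "+")
    mp3 <- metaprofile(stv, a3, flank = 250, bin = 50)
    expect_equal(mp3$anchorsDropped, 1L)
    expect_error(metaprofile(stv, a3[1], flank = 250, bin = 50),
                 "no usable anchors")
})

test_that("metaprofile is linear in the track", {
    set.seed(32)
    v1 <- rpois(200, 10)
    v2 <- rpois(200, 5)
    anchors <- GRanges("chr1", IRanges(sample(3000:7000, 10), width = 1),
                       strand = sample(c("+", "-"), 10, replace = TRUE))
    mp <- function(v) metaprofile(SignalTrack("chr1", v, binSize = 50),
                                  anchors, flank = 1000, bin = 50)$profile
    expect_equal(mp(v1 + v2), mp(v1) + mp(v2))
})

test_that("DNR metaprofile sits below mock over promoter anchors", {
    cfg <- simulationConfig(seed = 33, chromLength = 60000L, nGenes = 8L,
                            nEnhancers = 2L, backgroundMean = 0)
    gen <- makeGenome(cfg)
    genes <- makeGenes(cfg, gen)
    trk <- makeTracks(cfg, gen, genes)
    tss <- ifelse(strand(genes) == "+", start(genes), end(genes))
    anchors <- GRanges(seqnames(genes), IRanges(tss, width = 1),
                       strand = strand(genes))
    mock <- metaprofile(trk$tracks$sumo_mock, anchors, 1000, 50)$profile
    dnr <- metaprofile(trk$tracks$sumo_dnr, anchors, 1000, 50)$profile
    expect_true(all(dnr <= mock + 1e-9))
})

test_that("heatmap matrices rank regions by the chosen track", {
    v <- numeric(200)
    v[40:45] <- 5
    v[120:125] <- 9
    ts <- list(sumo = SignalTrack("chr1", v, binSize = 50),
               other = SignalTrack("chr1", rep(1, 200), binSize = 50))
    regions <- GRanges("chr1", IRanges(c(2050, 6050), width = 100))
    hm <- heatmapMatrix(ts, regions, rankBy = "sumo", flank = 500, bin = 50)
    expect_equal(hm$order, c(2L, 1L))   # strongest region first
    expect_equal(nrow(hm$matrix), 2L)

    # a constant ranking track preserves input order (stable ties)
    hm2 <- heatmapMatrix(ts, regions, rankBy = "other", flank = 500,
                         bin = 50)
    expect_equal(hm2$order, c(1L, 2L))

    # row means match independently recomputed per-region means
    rowMean <- rowMeans(hm$matrix[, grep("^sumo", colnames(hm$matrix))])
    for (k in 1:2) {
        reg <- regions[hm$order[k]]
        mid <- (start(reg) + end(reg)) %/% 2 - 1L
        bins <- ((mid - 500):(mid + 499)) %/% 50 + 1
        expect_equal(rowMean[k], mean(v[bins]))
    }
})
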