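# shared small 4C simulation used across read-level tests
local4cSim <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            cfg <- simulationConfig(seed = 71, chromLength = 50000L,
                                    nGenes = 5L, nEnhancers = 2L,
                                    n4cReads = 10000L,
                                    plantedInteractions = data.frame(
                                        offsetFragments = c(25L, -60L, 90L),
                                        nFragments = 5L,
                                        foldMock = 8, foldDnr = 8))
            g0 <- makeGenome(cfg)
            pl <- plantCaptureSite(g0)
            map <- digestGenome(pl$genome)
            sim <- make4CReads(cfg, pl$genome, pl$viewpoint)
            cache <<- list(cfg = cfg, genome = pl$genome,
                           viewpoint = pl$viewpoint, map = map, sim = sim)
        }
        cache
    }
})

test_that("capture trimming keeps the ligated partner sequence only", {
    cap <- "CGTGACGCACGGAAACGTC"
    r1 <- paste0(cap, "CATG", "ACGTACGT")
    tr <- trimCapture(c(r1))
    expect_equal(as.character(tr$trimmed[[1]]), "ACGTACGT")
    expect_equal(tr$kept, 1L)

    # a read without the capture is dropped
    tr2 <- trimCapture(c("ACGTACGTACGT"))
    expect_equal(tr2$kept, 0L)
    expect_equal(tr2$dropped, 1L)

    # capture but nothing after the junction site: counted separately
    tr3 <- trimCapture(paste0(cap, "CATG"))
    expect_equal(tr3$kept, 0L)
    expect_equal(tr3$emptyAfterTrim, 1L)

    expect_error(trimCapture("ACGT", capture = "ACG"), "at least 8")
})

test_that("trim-capture tallies match the simulator's own bookkeeping", {
    s <- local4cSim()
    tr <- trimCapture(s$sim$reads)
    expect_equal(tr$kept, s$sim$truth$nCapture)
    expect_equal(tr$dropped, s$sim$truth$nDecoy)
    expect_equal(tr$kept + tr$dropped + tr$emptyAfterTrim,
                 length(s$sim$reads))

    # zero decoys: every read survives
    cfg0 <- simulationConfig(seed = 72, chromLength = 50000L,
                             n4cReads = 2000L, decoyFraction = 0,
                             plantedInteractions = data.frame(
                                 offsetFragments = 25L, nFragments = 5L,
                                 foldMock = 8, foldDnr = 8))
    g0 <- makeGenome(cfg0)
    pl0 <- plantCaptureSite(g0)
    sim0 <- make4CReads(cfg0, pl0$genome, pl0$viewpoint)
    expect_equal(trimCapture(sim0$reads)$kept, 2000L)
})

test_that("exact placement locates reads and flags the rest", {
    g <- local4cSim()$genome
    chr1 <- as.character(g[[1]])
    r <- substring(chr1, 101, 140)  # bases [100,140) 0-based
    mp <- mapReads(c(r), g)
    expect_equal(mp$nPlaced, 1L)
    expect_equal(start(mp$placements), 101L)

    absent <- paste(rep("ACGT", 10), collapse = "")
    mp2 <- mapReads(c(substring(chr1, 101, 140), absent), g)
    expect_equal(mp2$nUnplaced,
                 as.integer(!grepl(substring(absent, 1, 20), chr1)))

    # repetitive genome: ambiguity raises with guidance
    rep2 <- Biostrings::DNAStringSet(c(chr1 = paste0(
        substring(chr1, 1, 100), substring(chr1, 1, 100))))
    expect_error(mapReads(c(substring(chr1, 11, 50)), rep2,
                          maxAmbiguousFraction = 0),
                 "increase k")
})

test_that("simulated reads place on their true source fragments", {
    s <- local4cSim()
    tr <- trimCapture(s$sim$reads)
    mp <- mapReads(tr$trimmed, s$genome)
    expect_gte(mp$nPlaced / length(tr$trimmed), 0.99)
    counts <- assignToFragments(mp$placements, s$map)
    expect_equal(as.integer(counts),
                 as.integer(s$sim$truth$fragmentCounts))
})

test_that("fragment assignment conserves reads and respects boundaries", {
    g <- Biostrings::DNAStringSet(c(chr1 = "TTCATGAAACATGTT"))
    map <- digestGenome(g)  # fragments 1-6, 7-13, 14-15
    pl <- GRanges("chr1", IRanges(c(8, 7, 3), width = 1))
    counts <- assignToFragments(pl, map)
    # base 7 (0-based: boundary) belongs to the downstream fragment
    expect_equal(as.integer(counts), c(1L, 2L, 0L))
    expect_equal(sum(counts), length(pl))

    expect_equal(sum(assignToFragments(GRanges(), map)), 0L)
    outside <- GRanges("chr1", IRanges(99, width = 1))
    expect_error(assignToFragments(outside, map), "outside")
})

test_that("read sets survive the FASTQ round trip", {
    s <- local4cSim()
    tf <- withr::local_tempfile(fileext = ".fastq")
    writeFastq(s$sim$reads[1:100], tf)
    back <- readFastq(tf)
    expect_equal(as.character(back), as.character(s$sim$reads[1:100]),
                 ignore_attr = TRUE)
})

test_that("planted enrichment raises fragment counts above their peers", {
    s <- local4cSim()
    fr <- fragments(s$map)
    vp <- s$sim$truth$vpIndex
    cnt <- s$sim$truth$fragmentCounts
    planted <- s$cfg$plantedInteractions
    for (k in seq_len(nrow(planted))) {
        if (planted$foldMock[k] < 4) next
        idx <- vp + planted$offsetFragments[k] + seq_len(planted$nFragments[k]) - 1L
        d <- abs(idx - vp)
        peers <- setdiff(which(abs(seq_along(cnt) - vp) %in% d), idx)
        expect_gt(min(cnt[idx]), stats::median(cnt[peers]))
    }
})
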