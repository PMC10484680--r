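test_that("threshold/run/gap rules follow the hand-enumerated example", {
    # bridged 100 bp gap, total span 300 bp > 100
    st <- SignalTrack("chr1", c(40, 40, 0, 0, 40, 40), binSize = 50)
    pk <- callPeaks(st, valueThreshold = 32, maxGap = 100, minRun = 100)
    expect_length(pk, 1L)
    expect_equal(start(pk), 1L)
    expect_equal(end(pk), 300L)
    expect_equal(mcols(pk)$maxValue, 40)

    # an all-zero track yields nothing
    expect_length(callPeaks(SignalTrack("chr1", rep(0, 10)), 32), 0L)

    # a 150 bp gap is not bridged and each 100 bp run fails min run > 100
    st2 <- SignalTrack("chr1", c(40, 40, 0, 0, 0, 40, 40), binSize = 50)
    expect_length(callPeaks(st2, 32, maxGap = 100, minRun = 100), 0L)
    # ...but survives with min run 50
    pk2 <- callPeaks(st2, 32, maxGap = 100, minRun = 50)
    expect_length(pk2, 2L)
    expect_equal(start(pk2), c(1L, 251L))

    # a bin exactly at the threshold is below (strict exceedance)
    st3 <- SignalTrack("chr1", c(32, 32, 32, 40, 40, 40), binSize = 50)
    pk3 <- callPeaks(st3, 32, maxGap = 100, minRun = 100)
    expect_equal(start(pk3), 151L)
})

test_that("peak calling equals the brute-force oracle on random tracks", {
    set.seed(401)
    for (rep in seq_len(100)) {
        n <- sample(5:200, 1)
        vals <- rpois(n, 20) * sample(c(0, 1), n, replace = TRUE, prob = c(0.4, 0.6))
        thr <- sample(c(10, 20, 32), 1)
        gap <- sample(c(0, 50, 100, 150), 1)
        run <- sample(c(0, 50, 100, 200), 1)
        st <- SignalTrack("chr1", vals, binSize = 50)
        got <- peaksToBins(callPeaks(st, thr, gap, run), 50)
        want <- peakOracle(vals, 50, thr, gap, run)
        expect_identical(unname(got), unname(want),
                         label = sprintf("rep %d (thr=%d gap=%d run=%d)",
                                         rep, thr, gap, run))
    }
})

test_that("peak calling equals the oracle exhaustively on short tracks", {
    # every above/below pattern up to 10 bins, two parameter settings
    for (n in 1:10) {
        for (code in seq_len(2^n) - 1L) {
            vals <- 40 * as.integer(intToBits(code)[1:n])
            st <- SignalTrack("chr1", vals, binSize = 50)
            for (pars in list(c(100, 100), c(50, 0))) {
                got <- peaksToBins(callPeaks(st, 32, pars[1], pars[2]), 50)
                want <- peakOracle(vals, 50, 32, pars[1], pars[2])
                expect_identical(unname(got), unname(want))
            }
        }
    }
})

test_that("raising thresholds is monotone in coverage and count", {
    set.seed(402)
    for (rep in seq_len(20)) {
        vals <- rpois(100, 25) * rbinom(100, 1, 0.6)
        st <- SignalTrack("chr1", vals, binSize = 50)
        covered <- function(pk) sum(width(pk))
        p1 <- callPeaks(st, 10, 100, 100)
        p2 <- callPeaks(st, 30, 100, 100)
        expect_lte(covered(p2), covered(p1))
        r1 <- callPeaks(st, 10, 100, 0)
        r2 <- callPeaks(st, 10, 100, 200)
        expect_lte(length(r2), length(r1))
    }
})

test_that("re-calling on an idealized track reproduces the intervals", {
    set.seed(403)
    vals <- rpois(120, 20) * rbinom(120, 1, 0.5)
    st <- SignalTrack("chr1", vals, binSize = 50)
    pk <- callPeaks(st, 15, 100, 100)
    ideal <- numeric(120)
    for (i in seq_along(pk)) {
        b <- (start(pk)[i] - 1L) %/% 50 + 1L
        e <- end(pk)[i] %/% 50
        ideal[b:e] <- 16
    }
    pk2 <- callPeaks(SignalTrack("chr1", ideal, binSize = 50), 15, 100, 100)
    expect_equal(granges(pk2), granges(pk))
})

test_that("peak summaries report count and mean intensity", {
    expect_equal(peakSummary(GRanges())$count, 0L)
    expect_true(peakSummary(GRanges())$undefined)
    pk <- GRanges("chr1", IRanges(c(1, 500), width = 200),
                  maxValue = c(50, 70), meanValue = c(10, 30))
    s <- peakSummary(pk)
    expect_equal(s$count, 2L)
    expect_equal(s$meanIntensity, 20)
})

test_that("wiggle round-trips preserve fixed-bin tracks", {
    st <- SignalTrack("chr1", c(1.5, 2, 3, 0, 7), binSize = 50)
    tf <- withr::local_tempfile(fileext = ".wig")
    writeWiggle(st, tf)
    back <- readWiggle(tf)
    expect_named(back, "chr1")
    expect_equal(trackValues(back$chr1), trackValues(st))
    expect_equal(binSize(back$chr1), 50L)

    # malformed declarations are rejected with the offending line
    tf2 <- withr::local_tempfile(fileext = ".wig")
    writeLines(c("fixedStep chrom=chr1", "1", "2"), tf2)
    expect_error(readWiggle(tf2), "line 1")
    tf3 <- withr::local_tempfile(fileext = ".wig")
    writeLines(c("variableStep chrom=chr1", "10 1"), tf3)
    expect_error(readWiggle(tf3), "span")
})

test_that("peak BED output round-trips interval coordinates", {
    pk <- GRanges("chr1", IRanges(c(101, 501), width = 200),
                  maxValue = c(1500, 70), meanValue = c(10, 30))
    tf <- withr::local_tempfile(fileext = ".bed")
    writePeaksBed(pk, tf)
    back <- readBed(tf)
    expect_equal(granges(back), granges(pk), ignore_attr = TRUE)
    expect_equal(back$score, c(1000, 70))  # clipped at 1000
})

test_that("simulated DNR depletion lowers called peak intensity", {
    cfg <- simulationConfig(seed = 21, chromLength = 60000L, nGenes = 8L,
                            nEnhancers = 3L)
    gen <- makeGenome(cfg)
    genes <- makeGenes(cfg, gen)
    trk <- makeTracks(cfg, gen, genes)
    mock <- peakSummary(callPeaks(trk$tracks$sumo_mock$chr1))
    dnr <- peakSummary(callPeaks(trk$tracks$sumo_dnr$chr1))
    expect_lt(dnr$meanIntensity, mock$meanIntensity)
})
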