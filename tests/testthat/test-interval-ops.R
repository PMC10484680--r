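test_that("interval pairing uses half-open overlap arithmetic", {
    # half-open adjacency is no overlap: [0,10) vs [10,20)
    a <- GRanges("chr1", IRanges(1, 10))
    b <- GRanges("chr1", IRanges(11, 20))
    expect_equal(nrow(intersectPairs(a, b)), 0L)
    # [0,10) vs [5,20) overlap 5
    b2 <- GRanges("chr1", IRanges(6, 20))
    p <- intersectPairs(a, b2)
    expect_equal(nrow(p), 1L)
    expect_equal(p$overlap, 5L)
})

test_that("interval pairing equals the quadratic oracle on random sets", {
    set.seed(51)
    a <- randomGRanges(250)
    b <- randomGRanges(250)
    got <- as.data.frame(intersectPairs(a, b))
    got <- got[order(got$query, got$subject), ]
    want <- overlapOracle(a, b)
    want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$query, want[, 1])
    expect_equal(got$subject, want[, 2])
    expect_equal(got$overlap, want[, 3])
})

test_that("pair existence and overlap length are symmetric", {
    set.seed(52)
    a <- randomGRanges(80)
    b <- randomGRanges(80)
    ab <- as.data.frame(intersectPairs(a, b))
    ba <- as.data.frame(intersectPairs(b, a))
    expect_equal(nrow(ab), nrow(ba))
    key <- function(q, s, o) sort(paste(q, s, o))
    expect_equal(key(ab$query, ab$subject, ab$overlap),
                 key(ba$subject, ba$query, ba$overlap))
})

test_that("fraction bound behaves at the extremes and in simulation", {
    a <- GRanges("chr1", IRanges(c(1, 100, 200), width = 50))
    expect_equal(fractionBound(a, GRanges()), 0)
    expect_equal(fractionBound(a, a), 1)
    expect_error(fractionBound(GRanges(), a), "non-empty")

    # planted co-binding fraction is recovered within a binomial CI
    set.seed(53)
    n <- 300
    a2 <- GRanges("chr1", IRanges(seq(1, by = 1000, length.out = n),
                                  width = 200))
    bound <- rbinom(n, 1, 1 / 3) == 1
    b2 <- granges(a2[bound])
    est <- fractionBound(a2, b2)
    ci <- 1 / 3 + c(-3, 3) * sqrt((1 / 3) * (2 / 3) / n)
    expect_gte(est, ci[1])
    expect_lte(est, ci[2])
})

test_that("promoter-feature gene selection is a per-set conjunction", {
    prom <- GRanges("chr1", IRanges(c(1000, 5000, 9000), width = 500),
                    gene_id = c("A", "B", "C"))
    sumo <- GRanges("chr1", IRanges(1200, 1300))          # A only
    ctcf <- GRanges("chr1", IRanges(c(1100, 5100), width = 50))  # A and B
    expect_equal(genesWithPromoterFeature(prom, sumo, ctcf), "A")
    expect_warning(all <- genesWithPromoterFeature(prom),
                   "vacuous")
    expect_setequal(all, c("A", "B", "C"))

    # any qualifying promoter qualifies a multi-TSS gene
    prom2 <- c(prom, GRanges("chr1", IRanges(20000, 20500), gene_id = "A"))
    sumoFar <- GRanges("chr1", IRanges(20100, 20200))
    expect_equal(genesWithPromoterFeature(prom2, sumoFar), "A")

    # brute-force comparison on random placements
    set.seed(54)
    for (rep in 1:5) {
        proms <- randomGRanges(40, chroms = "chr1")
        mcols(proms)$gene_id <- paste0("g", sample(20, 40, replace = TRUE))
        s1 <- randomGRanges(30, chroms = "chr1")
        s2 <- randomGRanges(30, chroms = "chr1")
        want <- sort(unique(unlist(lapply(unique(proms$gene_id), function(g) {
            pg <- proms[proms$gene_id == g]
            hit1 <- nrow(overlapOracle(pg, s1)) > 0
            hit2 <- nrow(overlapOracle(pg, s2)) > 0
            if (hit1 && hit2) g else NULL
        }))))
        expect_equal(genesWithPromoterFeature(proms, s1, s2),
                     as.character(want))
    }
})

test_that("gene-list crossing reports inclusion-exclusion accounting", {
    # 31 and 11 with 8 common unite to 34
    s23 <- paste0("p", 1:31)
    s1 <- paste0("p", c(1:8, 101:103))
    cr <- crossGeneLists(list(sumo23 = s23, sumo1 = s1), mode = "union")
    expect_equal(cr$report$union, 34L)
    expect_equal(cr$report$intersection, 8L)
    expect_length(cr$result, 34L)

    # disjoint sets: union is the concatenation
    d <- crossGeneLists(list(a = c("x", "y"), b = c("z")), mode = "union")
    expect_setequal(d$result, c("x", "y", "z"))

    # random sets agree with direct set arithmetic at every step
    set.seed(55)
    for (rep in 1:10) {
        sets <- lapply(1:3, function(i)
            sample(paste0("g", 1:50), sample(5:30, 1)))
        names(sets) <- c("a", "b", "c")
        cr2 <- crossGeneLists(sets, mode = "intersection")
        expect_setequal(cr2$result,
                        Reduce(intersect, lapply(sets, unique)))
        expect_true(all(cr2$report$union ==
            cr2$report$sizeA + cr2$report$sizeB - cr2$report$intersection))
    }
})

test_that("modulation filter supports contrast and fold-ratio readings", {
    lfcCombo <- c(g1 = 1.5, g2 = 0.3, g3 = -1.2)
    expect_equal(modulatedGenes(lfcCombo, factor = 2), c("g1", "g3"))
    lfcA <- c(g1 = 2, g2 = 2, g3 = 0)
    lfcB <- c(g1 = 2, g2 = 0.5, g3 = 0)
    expect_equal(modulatedGenes(lfcA, lfcB, factor = 2, mode = "ratio"),
                 "g2")
})
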