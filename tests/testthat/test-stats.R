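test_that("Fisher overlap matches the exhaustive hypergeometric oracle", {
    # balanced table: no association
    mkBins <- function() makeGenomeBins(c(chr1 = 3000), binSize = 100)
    bins <- mkBins()
    expect_length(bins, 30)
    # direct small-margin checks through the oracle
    tabs <- list(matrix(c(10, 10, 10, 10), 2, byrow = TRUE),
                 matrix(c(5, 1, 1, 5), 2, byrow = TRUE),
                 matrix(c(8, 0, 2, 9), 2, byrow = TRUE),
                 matrix(c(3, 7, 9, 1), 2, byrow = TRUE))
    for (tab in tabs) {
        got <- fisher.test(tab)$p.value
        expect_equal(got, fisherTwoTailOracle(tab), tolerance = 1e-10)
    }
    # geometry path: A = B gives the minimal p for the margins, OR maximal
    a <- bins[1:10]
    res <- fisherOverlap(a, a, bins)
    expect_equal(unname(res$contingency[1, 1]), 10)
    expect_equal(unname(res$contingency[2, 2]), 20)
    expect_equal(res$p_two_tailed,
                 fisherTwoTailOracle(res$contingency), tolerance = 1e-10)
    expect_gt(res$odds_ratio, 100)  # Haldane-corrected, zero off-cells
    disj <- fisherOverlap(a, bins[11:20], bins)
    expect_equal(disj$p_two_tailed,
                 fisherTwoTailOracle(disj$contingency), tolerance = 1e-10)
    expect_equal(fisherOverlap(bins[1:20], bins[6:25], bins)$odds_ratio,
                 (15 * 5) / (5 * 5))
    expect_error(fisherOverlap(a, a, GRanges()), "non-empty")
})

test_that("binomial tail equals the summation oracle to 1e-12 relative error", {
    cases <- rbind(c(5, 10), c(9999, 10000), c(5200, 10000), c(0, 50),
                   c(50, 50), c(700, 1000))
    for (i in seq_len(nrow(cases))) {
        k <- cases[i, 1]; n <- cases[i, 2]
        got <- binomTail(k, n, 0.5)
        exp <- binomTailOracle(k, n, 0.5)
        expect_equal(got, exp, tolerance = 1e-12)
    }
})

test_that("windowHits is inclusive at the boundary and monotone in flank", {
    el <- gr0("chr1", 10000, 11000)
    snps <- GRanges("chr1", IRanges(c(10500, 13500, 13501, 20000), width = 1))
    # distances: 0 (inside), 2499, 2500, beyond
    h <- windowHits(el, snps, flanks = c(0, 2499, 2500, 5000))
    expect_equal(h$n_hits, c(1, 2, 3, 3))
    none <- windowHits(el, GRanges("chr9", IRanges(1, 1)), flanks = 2500)
    expect_equal(none$n_hits, 0)
    expect_error(windowHits(el, snps, flanks = -1), "non-negative")
    # doubling schedule stays monotone
    sched <- windowHits(el, snps, flanks = 2500 * 2^(0:4))
    expect_true(all(diff(sched$n_hits) >= 0))
})

test_that("proximity test is calibrated under its own null", {
    set.seed(60)
    seqlens <- c(chr1 = 200000L)
    tss <- GRanges("chr1", IRanges(sample(200000, 60), width = 1))
    pool <- makeBackgroundPool(seqlens, binSize = 300)
    nonsig <- 0
    nRuns <- 25
    for (r in seq_len(nRuns)) {
        fg <- pool[sample(length(pool), 40)]
        res <- proximityResamplingTest(fg, tss, pool, nReps = 300,
                                       seed = 100 + r)
        if (res$binom_p > 0.05) nonsig <- nonsig + 1
        expect_true(res$successes <= res$n_reps)
    }
    expect_gte(nonsig / nRuns, 0.9)
})

test_that("planted TSS-proximal foreground yields a vanishing binomial p", {
    set.seed(61)
    seqlens <- c(chr1 = 200000L)
    tssPos <- sample(seq(5000, 195000, by = 5000))
    tss <- GRanges("chr1", IRanges(tssPos, width = 1))
    fg <- GRanges("chr1", IRanges(tssPos[1:30] + sample(100:800, 30), width = 200))
    pool <- makeBackgroundPool(seqlens, exclude = list(fg), binSize = 300)
    res <- proximityResamplingTest(fg, tss, pool, nReps = 500, seed = 7)
    expect_lte(res$binom_p, 1e-6)
    expect_error(proximityResamplingTest(fg, tss, pool, nReps = 0), "nReps")
    expect_error(proximityResamplingTest(pool, tss, fg), "smaller")
    # cumulative curve is monotone and bounded by the foreground size
    expect_true(all(diff(res$distance_curve$fg_cum) >= 0))
    expect_lte(max(res$distance_curve$fg_cum), length(fg))
})

test_that("background pool construction subtracts blacklist and foreground", {
    seqlens <- c(chr1 = 10000L)
    bl <- gr0("chr1", 0, 3000)
    fg <- gr0("chr1", 6000, 6300)
    pool <- makeBackgroundPool(seqlens, exclude = list(bl, fg), binSize = 300)
    expect_false(any(suppressWarnings(overlapsAny(pool, bl))))
    expect_false(any(suppressWarnings(overlapsAny(pool, fg))))
    full <- makeGenomeBins(seqlens, 300)
    expect_equal(sum(width(full)), 10000)
})
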