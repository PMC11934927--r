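test_that("stitching merges peaks at 12.5 kb and excludes TSS-contained peaks", {
    sig <- function(g, s = 10) { g$score <- s; g }
    # two peaks 12,400 bp apart stitch into one region
    near <- gr0("chr1", c(0, 13400), c(1000, 14400))
    r1 <- stitchAndRank(near, sig(near))
    expect_length(r1, 1)
    # 12,600 bp apart stay separate
    far <- gr0("chr1", c(0, 13600), c(1000, 14600))
    r2 <- stitchAndRank(far, sig(far))
    expect_length(r2, 2)
    # a peak fully inside TSS +/- 2 kb is excluded pre-stitch
    tss <- gr0("chr1", 500, 501)
    inTss <- gr0("chr1", c(0, 30000), c(1000, 31000))
    r3 <- stitchAndRank(inTss, sig(inTss), tss = tss)
    expect_length(r3, 1)
    expect_equal(start(r3), 30001)
    expect_warning(stitchAndRank(inTss[1], sig(inTss[1]), tss = tss),
                   "TSS exclusion")
})

test_that("region signal is marker minus input coverage, floored at zero", {
    peaks <- gr0("chr1", c(0, 30000), c(1000, 31000))
    marker <- peaks; marker$score <- c(10, 2)
    input <- peaks; input$score <- c(3, 5)
    r <- stitchAndRank(peaks, marker, inputSignal = input)
    o <- order(start(r))
    expect_equal(r$signal_rpm[o], c((10 - 3) * 1000, 0))
})

test_that("the x^2 rank curve splits exactly at the slope-1 tangent (x = 0.5)", {
    for (n in c(10, 100, 500)) {
        signals <- (seq_len(n) / n)^2
        cut <- seCutoff(sample(signals))
        expect_equal(cut, n / 2)
    }
    # strictly increasing curves have a unique cutoff; flat curves give no SE
    expect_equal(seCutoff(rep(3, 7)), 7)
    # monotonicity: raising one region's signal cannot lower its rank
    set.seed(4)
    s <- runif(50)
    r <- rank(s, ties.method = "first")
    s2 <- s; s2[17] <- s2[17] + 0.5
    expect_gte(rank(s2, ties.method = "first")[17], r[17])
})

test_that("stitchAndRank flags SEs above the inflection point on synthetic peaks", {
    cfg <- simConfig(seed = 8)
    pk <- generatePeaks(cfg)
    rose <- stitchAndRank(pk$peaks$H3K27ac$`6h`, pk$peaks$H3K27ac$`6h`)
    expect_true(sum(rose$is_se) >= 1)
    # stitched regions are disjoint and cover every peak
    expect_true(isDisjoint(rose, ignore.strand = TRUE))
    expect_true(all(suppressWarnings(overlapsAny(pk$peaks$H3K27ac$`6h`, rose))))
    # planted SE spans rank above planted background: all planted spans SE
    truth <- GRanges(pk$seLedger$chrom,
                     IRanges(pk$seLedger$start, pk$seLedger$end))
    planted6 <- truth[pk$seLedger$dynamics %in% c("pmSE", "viSE")]
    ses <- rose[rose$is_se]
    expect_true(all(suppressWarnings(overlapsAny(planted6, ses))))
})

test_that("SE dynamics labels partition both conditions and match the ledger", {
    a <- gr0("chr1", c(0, 10000), c(2000, 12000))
    b <- gr0("chr1", c(1000, 50000), c(3000, 52000))
    dyn <- classifySeDynamics(a, b)
    expect_equal(sort(dyn$dynamics), c("pdSE", "pmSE", "viSE"))
    expect_length(dyn, 3)  # pm counted once
    same <- classifySeDynamics(a, a)
    expect_true(all(same$dynamics == "pmSE"))
    disj <- classifySeDynamics(a, shift(a, 100000))
    expect_equal(sum(disj$dynamics == "pdSE"), 2)
    expect_equal(sum(disj$dynamics == "viSE"), 2)
    # ledger recovery on generated peaks
    cfg <- simConfig(seed = 77)
    pk <- generatePeaks(cfg)
    rose0 <- stitchAndRank(pk$peaks$H3K27ac$`0h`, pk$peaks$H3K27ac$`0h`)
    rose6 <- stitchAndRank(pk$peaks$H3K27ac$`6h`, pk$peaks$H3K27ac$`6h`)
    dyn2 <- classifySeDynamics(rose0[rose0$is_se], rose6[rose6$is_se])
    truth <- GRanges(pk$seLedger$chrom,
                     IRanges(pk$seLedger$start, pk$seLedger$end))
    hits <- suppressWarnings(findOverlaps(truth, dyn2))
    expect_equal(dyn2$dynamics[subjectHits(hits)],
                 pk$seLedger$dynamics[queryHits(hits)])
    expect_equal(length(hits), length(truth))
})

test_that("SE-gene assignment honours the distance window and expression floor", {
    se <- gr0("chr1", 1000000, 1001000)   # center at 1000500 (1-based 1000501)
    center <- floor((1000001 + 1001000) / 2)
    tss <- GRanges("chr1", IRanges(c(center - 499999, center - 500001, center + 100),
                                   width = 1))
    tss$feature_id <- c("inWin", "outWin", "lowExpr")
    expr <- c(inWin = 12, outWin = 50, lowExpr = 9.9)
    asg <- assignSeGenes(se, tss, expr)
    expect_equal(sort(asg$feature_id), "inWin")
    # empty association when no gene sits in the window
    none <- assignSeGenes(gr0("chr2", 0, 1000), tss, expr)
    expect_equal(nrow(none), 0)
    # floor is inclusive at 10
    expr2 <- c(inWin = 10, outWin = 1, lowExpr = 1)
    expect_equal(assignSeGenes(se, tss, expr2)$feature_id, "inWin")
})

test_that("element localization is exhaustive with SE priority", {
    ses <- gr0("chr1", 0, 10000)
    tes <- gr0("chr1", 50000, 60000)
    els <- gr0("chr1", c(100, 51000, 200000, 9999), c(200, 52000, 201000, 10050))
    lab <- localizeElements(els, ses, tes)
    expect_equal(lab, c("SE", "tE", "safG", "SE"))
    expect_error(localizeElements(els, ses, shift(ses, 100)), "disjoint")
})
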