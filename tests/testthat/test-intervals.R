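test_that("mergeIntervals matches worked examples and the merge-at-equality rule", {
    expect_length(mergeIntervals(GRanges(), 5), 0)
    # {[0,10),[8,20),[30,40)}, gap 0 -> {[0,20),[30,40)}
    m <- mergeIntervals(gr0("chr1", c(0, 8, 30), c(10, 20, 40)), 0)
    expect_equal(start(m), c(1, 31))
    expect_equal(end(m), c(20, 40))
    # {[0,10),[20,25)}, gap 12 -> one interval (gap 10 <= 12)
    m2 <- mergeIntervals(gr0("chr1", c(0, 20), c(10, 25)), 12)
    expect_length(m2, 1)
    expect_equal(c(start(m2), end(m2)), c(1, 25))
    # merge exactly at equality, split one beyond
    g <- gr0("chr1", c(0, 20), c(10, 25))
    expect_length(mergeIntervals(g, 10), 1)
    expect_length(mergeIntervals(g, 9), 2)
    expect_error(mergeIntervals(g, -1), "non-negative")
})

test_that("mergeIntervals agrees with the union-closure oracle and is idempotent", {
    set.seed(11)
    for (rep in 1:25) {
        g <- randomGRanges(40, maxPos = 2000L, maxW = 60L)
        gap <- sample(c(0L, 1L, 10L, 100L), 1)
        got <- mergeIntervals(g, gap)
        exp <- bruteMerge(g, gap)
        expect_equal(grDf(got), grDf(exp))
        expect_equal(grDf(mergeIntervals(got, gap)), grDf(got))
    }
})

test_that("intersectMulti is base-exact, order-independent, and handles degenerate cases", {
    s1 <- gr0("chr1", 0, 10)
    s2 <- gr0("chr1", 5, 15)
    got <- intersectMulti(list(s1, s2))
    expect_equal(c(start(got), end(got)), c(6, 10))  # [5,10) in 0-based
    expect_equal(grDf(intersectMulti(list(s1))), grDf(s1))
    expect_length(intersectMulti(list(s1, gr0("chr1", 20, 30))), 0)
    expect_error(intersectMulti(list()), "non-empty")
    set.seed(7)
    for (rep in 1:10) {
        sets <- replicate(sample(2:4, 1),
                          randomGRanges(15, maxPos = 3000L), simplify = FALSE)
        got <- intersectMulti(sets)
        expect_equal(grDf(got), grDf(bruteIntersect(sets)))
        perm <- sample(length(sets))
        expect_equal(grDf(intersectMulti(sets[perm])), grDf(got))
    }
})

test_that("nearestDistance counts bases between edges, with NA sentinel off-reference", {
    refs <- gr0("chr1", c(0, 150), c(10, 160))
    q <- gr0("chr1", 100, 101)
    expect_equal(nearestDistance(q, refs), 49)
    inside <- gr0("chr1", 3, 6)
    expect_equal(nearestDistance(inside, refs), 0)
    lost <- gr0("chrX", 5, 10)
    expect_true(is.na(nearestDistance(lost, refs)))
    # equidistant tie resolves to the leftmost reference
    refsTie <- gr0("chr1", c(0, 151), c(10, 161))
    mid <- gr0("chr1", 80, 81)   # 70 bp to either side
    h <- nearestDistance(mid, refsTie, returnHits = TRUE)
    expect_equal(h$distance, 70)
    expect_equal(h$ref, 1)
    # symmetry of the zero distance for a shared interval
    a <- gr0("chr1", 50, 70)
    expect_equal(nearestDistance(a, a), 0)
})

test_that("clusterIntervals finds strict-gap runs and matches the quadratic oracle", {
    # 25-bp instances at 0, 50, 120 (0-based): gaps 25 and 45, both < 75
    inst <- gr0("chr1", c(0, 50, 120), c(25, 75, 145))
    cl <- clusterIntervals(inst, maxGap = 75, minCount = 3)
    expect_length(cl, 1)
    expect_equal(c(start(cl), end(cl)), c(1, 145))
    expect_equal(cl$n_members, 3)
    # two instances never qualify at minCount 3
    expect_length(clusterIntervals(inst[1:2], 75, 3), 0)
    # gap exactly 75 breaks the run
    brk <- gr0("chr1", c(0, 100, 150), c(25, 125, 175))  # first gap = 75
    expect_length(clusterIntervals(brk, 75, 3), 0)
    expect_length(clusterIntervals(brk, 76, 3), 1)
    expect_error(clusterIntervals(inst, 75, 0), ">= 1")
    set.seed(23)
    for (rep in 1:20) {
        n <- sample(5:60, 1)
        g <- sort(randomGRanges(n, chroms = "chr1", maxPos = 4000L, maxW = 30L))
        maxGap <- sample(c(10L, 75L, 200L), 1)
        minCount <- sample(2:4, 1)
        got <- clusterIntervals(g, maxGap, minCount)
        exp <- bruteCluster(start(g), end(g), maxGap, minCount)
        expect_equal(length(got), nrow(exp))
        if (length(got)) {
            expect_equal(start(got), unname(exp[, 1]))
            expect_equal(end(got), unname(exp[, 2]))
            expect_equal(got$n_members, unname(exp[, 3]))
        }
    }
})

test_that("BED round-trip preserves coordinates through the 0-based boundary", {
    g <- gr0("chr1", c(0, 99), c(10, 250))
    g$name <- c("a", "b")
    g$score <- c(1, 2)
    path <- withr::local_tempfile(fileext = ".bed")
    writeBed(g, path)
    back <- readBed(path)
    expect_equal(grDf(back), grDf(g))
    raw <- read.table(path, sep = "\t")
    expect_equal(raw$V2, c(0, 99))  # 0-based starts on disk
})
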