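test_that("scanMotif matches a regex oracle on random 10-kb sequences", {
    set.seed(5)
    consensi <- c("GAAAG", "GGGNNNNNCC", "RAAAGGAAAG", "GGGRCTTTCC",
                  "RRAARGGAAAGGAAAGGAAAGGAAA")
    for (cons in consensi) {
        seqChar <- paste(sample(c("A", "C", "G", "T"), 10000,
                                replace = TRUE), collapse = "")
        # spike in a few planted instances so matches exist
        for (p in sample(9000, 4))
            substr(seqChar, p, p + nchar(cons) - 1L) <-
                gsub("R", "A", gsub("N", "T", cons))
        m <- scanMotif(seqChar, consensusMotif("x", cons),
                       strands = "forward", nonoverlapping = FALSE)
        expect_equal(start(m), regexScanStarts(seqChar, cons))
        # minus-strand hits equal forward hits of the reverse complement
        mb <- scanMotif(seqChar, consensusMotif("x", cons),
                        strands = "both", nonoverlapping = FALSE)
        minus <- mb[strand(mb) == "-"]
        expect_equal(start(minus),
                     regexScanStarts(seqChar, revcompChar(cons)))
    }
})

test_that("scanMotif reports reverse-complement instances on the minus strand", {
    cons <- "GGGACTTTCC"
    seqChar <- paste0(strrep("T", 30), revcompChar(cons), strrep("T", 30))
    m <- scanMotif(seqChar, consensusMotif("kB", cons))
    expect_length(m, 1)
    expect_equal(as.character(strand(m)), "-")
    expect_equal(start(m), 31)
    expect_length(scanMotif("", consensusMotif("kB", cons)), 0)
    expect_error(consensusMotif("bad", "ACGTX"), "IUPAC")
})

test_that("greedy nonoverlap resolution keeps leftmost-then-strongest hits", {
    # the printed 25-mer with R -> A holds 3 nonoverlapping GAAAG half sites
    printed <- gsub("R", "A", "RRAARGGAAAGGAAAGGAAAGGAAA")
    m <- scanMotif(printed, consensusMotif("half", "GAAAG"),
                   strands = "forward")
    expect_length(m, 3)
    expect_true(all(start(m)[-1] > head(end(m), -1)))
    # overlapping AAAA run: 10-mer of A holds 2 nonoverlapping AAAG-free AAAA
    m2 <- scanMotif(strrep("A", 10), consensusMotif("a4", "AAAA"),
                    strands = "forward")
    expect_equal(start(m2), c(1, 5))
})

test_that("PWM scanning honours the exact tail-probability threshold", {
    pfm <- matrix(c(20, 0, 0, 0,
                    0, 20, 0, 0,
                    0, 0, 20, 0,
                    0, 0, 0, 20,
                    20, 0, 0, 0), nrow = 4,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    pwm <- pwmFromPfm(pfm)
    # uniform-background distribution: every 5-mer equally likely, so the
    # exact-match score has tail probability 4^-5 and must stay reachable
    thr <- pwmThreshold(pwm, pvalue = 1 / 4^5 + 1e-12)
    expect_lte(thr, sum(apply(pwm, 2, max)) + 1e-9)
    mot <- pfmMotif("acgta", pfm, pvalue = 1e-3)
    hits <- scanMotif("TTTACGTATTT", mot, strands = "forward")
    expect_length(hits, 1)
    expect_equal(start(hits), 4)
    # DP tail matches direct enumeration over all 4^5 sequences
    allseq <- expand.grid(rep(list(1:4), 5))
    scores <- apply(allseq, 1, function(ix)
        sum(pwm[cbind(ix, 1:5)]))
    for (pv in c(1e-1, 1e-2, 1e-3)) {
        thr <- pwmThreshold(pwm, pvalue = pv)
        expect_lte(mean(scores >= thr), pv + 1e-9)
    }
})

test_that("IR-HCTFBS calling follows the core and half-site rules", {
    site <- "AAAAGGAAAG"   # realization of the perfect consensus
    pad <- function(n) strrep("C", n)
    # 3 perfect sites spanning <= 400 bp -> core call
    el <- paste0(pad(20), site, pad(150), site, pad(150), site, pad(20))
    call <- callIrHctfbs(el, irfPerfectMotif())
    expect_equal(call$subclass, "core")
    expect_equal(call$site_count, 3)
    expect_lte(call$span, 400)
    # same sites stretched beyond 400 bp -> no core; few halves -> none
    el2 <- paste0(pad(20), site, pad(300), site, pad(300), site, pad(20))
    expect_null(callIrHctfbs(el2, irfPerfectMotif()))
    # 11 AAAG half sites within 900 bp, one perfect site -> half-site call
    halves <- paste(rep("AAAG", 11), collapse = pad(76))
    expect_lte(nchar(halves), 1000)
    el3 <- paste0(pad(10), site, pad(500), halves, pad(10))
    call3 <- callIrHctfbs(el3, irfPerfectMotif())
    expect_equal(call3$subclass, "half-site")
    expect_gt(call3$site_count, 10)
    # exactly 10 halves is not enough (strict > 10)
    h10 <- paste(rep("AAAG", 10), collapse = pad(76))
    expect_null(callIrHctfbs(paste0(pad(10), h10), irfPerfectMotif()))
    expect_null(callIrHctfbs(pad(500), irfPerfectMotif()))
})

test_that("kB-HCTFBS calling follows perfect, degenerate and out-of-range rules", {
    site <- "GGGACTTTCC"
    deg <- "GGGTTTTTCC"    # matches GGGNNNNNCC
    pad <- function(n) strrep("A", n)
    el <- paste0(pad(10), site, pad(170), site, pad(170), site)
    call <- callKbHctfbs(el, kbPerfectMotif())
    expect_equal(call$subclass, "core")
    # 5 degenerate sites in ~1200 bp, no perfect sites -> degenerate call
    el2 <- paste(rep(deg, 5), collapse = pad(280))
    expect_lte(nchar(el2), 1300)
    call2 <- callKbHctfbs(el2, kbPerfectMotif())
    expect_equal(call2$subclass, "degenerate")
    expect_equal(call2$site_count, 5)
    # 15 degenerate sites in ~1200 bp -> out-of-range, not a call
    el3 <- paste(rep(deg, 15), collapse = pad(75))
    expect_lte(nchar(el3), 1300)
    call3 <- callKbHctfbs(el3, kbPerfectMotif())
    expect_false(call3$is_call)
    expect_equal(call3$subclass, "out-of-range")
    # GGRR half sites annotated but never triggering
    el4 <- paste(rep("GGAA", 20), collapse = pad(30))
    expect_null(callKbHctfbs(el4, kbPerfectMotif()))
})

test_that("syntax labels follow strand geometry with majority voting", {
    expect_equal(classifySyntax(c("+", "+")), "Head-to-Tail")
    expect_equal(classifySyntax(c("-", "-")), "Head-to-Tail")
    expect_equal(classifySyntax(c("+", "-")), "Head-to-Head")
    expect_equal(classifySyntax(c("-", "+")), "Tail-to-Tail")
    expect_equal(classifySyntax(c("+", "+", "+", "-")), "Head-to-Tail")
    expect_equal(classifySyntax(c("+", "-", "+")), "mixed")
    expect_equal(classifySyntax("+"), "n/a")
    gr <- GRanges("seq", IRanges(c(100, 1), width = 10),
                  strand = c("-", "+"))
    expect_equal(classifySyntax(gr), "Head-to-Head")  # sorted by position
})

test_that("genome coverage formula is exact and linear in instance count", {
    # 4 planted instances on a 1000-bp-per-chrom genome
    cons <- cirMotif()@consensus
    inst <- gsub("R", "G", cons)
    chr1 <- paste0(strrep("C", 100), inst, strrep("C", 100), inst,
                   strrep("C", 1000 - 2 * 25 - 200))
    chr2 <- chr1
    genome <- Biostrings::DNAStringSet(c(chr1 = chr1, chr2 = chr2))
    sc <- scanGenomeCoverage(genome)
    expect_equal(sc$n_instances, 4)
    expect_equal(sc$coverage_pct, 100 * 4 * 25 / 2000)  # 5%
    expect_equal(sc$coverage_pct, 5)
    empty <- Biostrings::DNAStringSet(c(chr1 = strrep("C", 1000)))
    expect_equal(scanGenomeCoverage(empty)$coverage_pct, 0)
})

test_that("IRHAD mapping needs three instances spaced strictly under 75 bp", {
    inst <- gr0("chr1", c(0, 50, 120), c(25, 75, 145))
    d <- mapIrhads(inst)
    expect_length(d, 1)
    expect_equal(d$n_members, 3)
    expect_length(mapIrhads(inst[1:2]), 0)
    # gap exactly 75 splits the run
    far <- gr0("chr1", c(0, 100, 200), c(25, 125, 225))
    expect_length(mapIrhads(far), 0)
})

test_that("JASPAR PFM files round-trip into PWM models", {
    path <- withr::local_tempfile(fileext = ".jaspar")
    writeLines(c(">MA0000.1 toy",
                 "A [ 10  0  0 10 ]",
                 "C [  0 10  0  0 ]",
                 "G [  0  0 10  0 ]",
                 "T [  0  0  0  0 ]"), path)
    rec <- readJasparPfm(path)
    expect_equal(rec$name, "MA0000.1 toy")
    expect_equal(dim(rec$pfm), c(4L, 4L))
    expect_equal(unname(colSums(rec$pfm)), rep(10, 4))
    mot <- pfmMotif(rec$name, rec$pfm, pvalue = 1e-2)
    hits <- scanMotif("GGACGAGG", mot, strands = "forward")
    expect_equal(start(hits), 3)  # ACGA is the consensus realization
})
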