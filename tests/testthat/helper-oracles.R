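# Independent brute-force oracles used to pin down the interval algebra,
# motif scanner and exact tests. Deliberately naive implementations that
# share no code with the package internals.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(Biostrings)
})

# bind the generics used throughout the tests in this environment, so the
# oracles and test files resolve them regardless of how the suite is run
GRanges <- GenomicRanges::GRanges
IRanges <- IRanges::IRanges
granges <- GenomicRanges::granges
seqnames <- GenomeInfoDb::seqnames
start <- BiocGenerics::start
end <- BiocGenerics::end
width <- BiocGenerics::width
strand <- BiocGenerics::strand
sort <- BiocGenerics::sort
shift <- IRanges::shift
setdiff <- BiocGenerics::setdiff
overlapsAny <- IRanges::overlapsAny
findOverlaps <- GenomicRanges::findOverlaps
queryHits <- S4Vectors::queryHits
subjectHits <- S4Vectors::subjectHits
isDisjoint <- IRanges::isDisjoint
DNAString <- Biostrings::DNAString
reverseComplement <- Biostrings::reverseComplement

# build a GRanges from 0-based half-open coordinates (the notation used in
# the worked examples)
gr0 <- function(chrom, start0, end0) {
    GRanges(chrom, IRanges(start0 + 1L, end0))
}

# union-closure merge oracle: repeatedly merge any pair with gap <= maxGap
# (0-based gap = next.start0 - prev.end0); O(n^2) per pass
bruteMerge <- function(gr, maxGap) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr), end = end(gr))
    repeat {
        merged <- FALSE
        i <- 1L
        while (i <= nrow(df)) {
            j <- i + 1L
            while (j <= nrow(df)) {
                if (df$chrom[i] == df$chrom[j]) {
                    gap <- max(df$start[i], df$start[j]) - 1L -
                        min(df$end[i], df$end[j])
                    if (gap <= maxGap) {
                        df$start[i] <- min(df$start[i], df$start[j])
                        df$end[i] <- max(df$end[i], df$end[j])
                        df <- df[-j, , drop = FALSE]
                        merged <- TRUE
                        next
                    }
                }
                j <- j + 1L
            }
            i <- i + 1L
        }
        if (!merged) break
    }
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    GRanges(df$chrom, IRanges(df$start, df$end))
}

# per-base intersection oracle
bruteIntersect <- function(sets) {
    chroms <- Reduce(intersect, lapply(sets, function(g)
        unique(as.character(seqnames(g)))))
    out <- GRanges()
    for (ch in chroms) {
        baseSets <- lapply(sets, function(g) {
            gg <- g[as.character(seqnames(g)) == ch]
            unique(unlist(Map(seq.int, start(gg), end(gg))))
        })
        common <- sort(Reduce(intersect, baseSets))
        if (length(common)) {
            runs <- cumsum(c(1L, diff(common) != 1L))
            for (r in unique(runs)) {
                b <- common[runs == r]
                out <- suppressWarnings(c(out, GRanges(ch, IRanges(min(b), max(b)))))
            }
        }
    }
    sort(out)
}

# quadratic cluster oracle on one chromosome: clusters are the connected
# components of "gap < maxGap", i.e. the union-closure merge at maxGap - 1
# (strict inequality on integer coordinates); members counted per span
bruteCluster <- function(starts, ends, maxGap, minCount) {
    g <- GRanges("chr1", IRanges(starts, ends))
    spans <- bruteMerge(g, maxGap - 1L)
    res <- list()
    for (i in seq_along(spans)) {
        inside <- starts >= start(spans)[i] & ends <= end(spans)[i]
        if (sum(inside) >= minCount)
            res[[length(res) + 1L]] <-
                c(start(spans)[i], end(spans)[i], sum(inside))
    }
    if (!length(res)) return(matrix(numeric(0), ncol = 3))
    do.call(rbind, res)
}

# IUPAC consensus -> regular expression
iupacRegex <- function(cons) {
    map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
             S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
             D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
    paste(map[strsplit(cons, "")[[1]]], collapse = "")
}

# all (overlapping) forward-strand match start positions via regex lookahead
regexScanStarts <- function(seqChar, cons) {
    m <- gregexpr(paste0("(?=", iupacRegex(cons), ")"), seqChar,
                  perl = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
}

revcompChar <- function(x) {
    as.character(reverseComplement(DNAString(x)))
}

# exact two-tailed Fisher p by enumeration over tables with fixed margins
fisherTwoTailOracle <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    lo <- max(0L, k - n); hi <- min(m, k)
    probs <- dhyper(lo:hi, m, n, k)
    pObs <- dhyper(tab[1, 1], m, n, k)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# binomial upper tail by direct log-space summation
binomTailOracle <- function(k, n, p = 0.5) {
    if (k > n) return(0)
    ks <- k:n
    sum(exp(lchoose(n, ks) + ks * log(p) + (n - ks) * log1p(-p)))
}

randomGRanges <- function(n, chroms = c("chr1", "chr2"), maxPos = 10000L,
                          maxW = 50L) {
    w <- sample.int(maxW, n, replace = TRUE)
    s <- sample.int(maxPos, n, replace = TRUE)
    GRanges(sample(chroms, n, replace = TRUE), IRanges(s, width = w))
}

# order-normalized coordinate frame for comparing interval sets
grDf <- function(g) {
    d <- data.frame(chrom = as.character(seqnames(g)),
                    start = start(g), end = end(g))
    d <- d[order(d$chrom, d$start, d$end), , drop = FALSE]
    rownames(d) <- NULL
    d
}
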