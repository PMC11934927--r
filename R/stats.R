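#' Tile a genome into fixed-size bins
#'
#' @param seqlengths Named integer vector of chromosome lengths.
#' @param binSize Bin width, bp (default 300, the proximity-test bin).
#' @return GRanges of bins (the last bin of a chromosome may be shorter).
#' @export
makeGenomeBins <- function(seqlengths, binSize = 300L) {
    grs <- lapply(names(seqlengths), function(chr) {
        L <- seqlengths[[chr]]
        starts <- seq.int(1L, L, by = binSize)
        GenomicRanges::GRanges(chr, IRanges::IRanges(
            starts, pmin(starts + binSize - 1L, L)))
    })
    do.call(.concatGR, grs)
}

#' Background pool for the proximity resampling test
#'
#' Bins the genome into \code{binSize} windows and removes every bin
#' overlapping the blacklist, the foreground, or any of the supplied peak
#' sets, mirroring the subtraction of blacklisted regions, SHAe and ChIP
#' peaks from the binned genome.
#'
#' @param seqlengths Named chromosome lengths.
#' @param exclude List of GRanges to subtract (blacklist, foreground,
#'   peaks, ...).
#' @param binSize Bin width, bp.
#' @return GRanges of background bins.
#' @export
makeBackgroundPool <- function(seqlengths, exclude = list(), binSize = 300L) {
    bins <- makeGenomeBins(seqlengths, binSize)
    for (x in exclude) {
        if (!is.null(x) && length(x))
            bins <- bins[!.overlapsAnyQ(bins, x, ignore.strand = TRUE)]
    }
    bins
}

# two-sided rank-sum p-value: exact for small untied samples, otherwise
# normal approximation with tie and continuity correction
.ranksumP <- function(x, y, exactMax = 20L) {
    nx <- length(x); ny <- length(y)
    hasTies <- anyDuplicated(c(x, y)) > 0
    if (min(nx, ny) <= exactMax && !hasTies)
        return(stats::wilcox.test(x, y, exact = TRUE)$p.value)
    r <- rank(c(x, y))
    W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    ties <- table(r)
    sig2 <- nx * ny / 12 *
        ((nx + ny + 1) - sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1)))
    if (sig2 <= 0) return(1)
    z <- W - mu
    corr <- sign(z) * 0.5
    p <- 2 * stats::pnorm(-abs((z - corr) / sqrt(sig2)))
    min(1, p)
}

#' Resampling-binomial proximity test of elements against TSSs
#'
#' Tests whether foreground elements sit closer to a TSS catalog than
#' random genomic background. Foreground distances are each element's
#' distance to the nearest TSS. For each of \code{nReps} repetitions, an
#' equal number of background bins is sampled (without replacement) from
#' \code{bgPool}, and a two-sided rank-sum test compares foreground against
#' sampled background distances; a repetition with p <= \code{alphaInner}
#' is a success. The reported p-value is the exact one-sided binomial tail
#' P(X >= successes | nReps, 0.5). Cumulative distance curves over the
#' first \code{curveMax} bp are emitted for the foreground and the expected
#' (pool-wide) background.
#'
#' @param fg GRanges of foreground elements.
#' @param tss GRanges of TSS points.
#' @param bgPool GRanges background pool (see \code{makeBackgroundPool});
#'   must hold at least \code{length(fg)} elements.
#' @param nReps Number of resampling repetitions (default 10000).
#' @param alphaInner Per-repetition success level (default 0.05).
#' @param seed Optional integer seed for the sampling.
#' @param curveMax,curveBin Distance grid for the cumulative curves.
#' @return List with n_reps, successes, binom_p, fg_median_distance, and a
#'   \code{distance_curve} data.frame (distance, fg_cum, bg_expected_cum).
#' @export
proximityResamplingTest <- function(fg, tss, bgPool, nReps = 10000L,
                                    alphaInner = 0.05, seed = NULL,
                                    curveMax = 10000L, curveBin = 500L) {
    if (nReps < 1L) stop("'nReps' must be >= 1", call. = FALSE)
    .checkGRanges(fg)
    .checkGRanges(tss)
    .checkGRanges(bgPool)
    if (length(bgPool) < length(fg))
        stop("background pool smaller than the foreground", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    fgD <- nearestDistance(fg, tss)
    fgD <- fgD[!is.na(fgD)]
    bgD <- nearestDistance(bgPool, tss)
    bgD <- bgD[!is.na(bgD)]
    n <- length(fgD)
    succ <- 0L
    for (r in seq_len(nReps)) {
        smp <- bgD[sample.int(length(bgD), n)]
        if (.ranksumP(fgD, smp) <= alphaInner) succ <- succ + 1L
    }
    binomP <- stats::pbinom(succ - 1L, nReps, 0.5, lower.tail = FALSE)
    grid <- seq(0L, curveMax, by = curveBin)
    curve <- data.frame(
        distance = grid,
        fg_cum = vapply(grid, function(d) sum(fgD <= d), numeric(1)),
        bg_expected_cum = vapply(grid, function(d)
            n * mean(bgD <= d), numeric(1)))
    list(n_reps = nReps, successes = succ, alpha_inner = alphaInner,
         binom_p = binomP, fg_median_distance = stats::median(fgD),
         distance_curve = curve)
}

#' Two-tailed Fisher overlap test on genome bins
#'
#' Classifies each genome bin by overlap with set A and set B and tests the
#' 2x2 contingency table (both / A only / B only / neither) with the exact
#' two-tailed hypergeometric (Fisher) test. The odds ratio is the sample
#' cross-product ratio, with the Haldane 0.5 correction applied when any
#' cell is zero.
#'
#' @param setA,setB GRanges.
#' @param genomeBins GRanges tiling the genome (see \code{makeGenomeBins}).
#' @return List with contingency (2x2 matrix), odds_ratio, p_two_tailed.
#' @export
fisherOverlap <- function(setA, setB, genomeBins) {
    .checkGRanges(setA)
    .checkGRanges(setB)
    .checkGRanges(genomeBins)
    if (length(genomeBins) == 0L)
        stop("'genomeBins' must be non-empty", call. = FALSE)
    inA <- .overlapsAnyQ(genomeBins, setA, ignore.strand = TRUE)
    inB <- .overlapsAnyQ(genomeBins, setB, ignore.strand = TRUE)
    tab <- matrix(c(sum(inA & inB), sum(inA & !inB),
                    sum(!inA & inB), sum(!inA & !inB)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(A = c("A", "notA"), B = c("B", "notB")))
    or <- if (any(tab == 0))
        (tab[1, 1] + 0.5) * (tab[2, 2] + 0.5) /
            ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
    else tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])
    p <- stats::fisher.test(tab)$p.value
    list(contingency = tab, odds_ratio = or, p_two_tailed = p)
}

#' Count features within flanking windows of elements
#'
#' A feature is a hit at flank f when its distance to the nearest element
#' is at most f bp (inclusive at the boundary; distance 0 means overlap).
#' Supports a schedule of flanks (e.g. a doubling series) and returns the
#' hit count per flank, which is monotone non-decreasing.
#'
#' @param elements GRanges (e.g. SHAe loci).
#' @param features GRanges (e.g. SNP positions).
#' @param flanks Numeric vector of flank widths, bp (default 2500).
#' @return data.frame(flank, n_hits).
#' @export
windowHits <- function(elements, features, flanks = 2500L) {
    .checkGRanges(elements)
    .checkGRanges(features)
    if (any(flanks < 0)) stop("flanks must be non-negative", call. = FALSE)
    d <- if (length(elements) == 0L) rep(NA_integer_, length(features))
         else nearestDistance(features, elements)
    data.frame(flank = flanks,
               n_hits = vapply(flanks, function(f)
                   sum(!is.na(d) & d <= f), numeric(1)))
}

#' Exact one-sided binomial tail
#'
#' P(X >= k) for X ~ Binomial(n, p); the statistic behind the proximity
#' test's outer binomial.
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param p Success probability (default 0.5).
#' @return Upper-tail probability.
#' @export
binomTail <- function(k, n, p = 0.5) {
    stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}
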