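#' ROSE-style stitching, ranking and the SE/tE split
#'
#' Peaks fully contained in a TSS +/- \code{tssExcl} window are removed
#' before stitching (excluded peaks that end up inside a final stitched
#' region are re-admitted for signal purposes, which the region span already
#' captures). Remaining peaks are merged with gap <= \code{stitchDist}.
#' Each region's signal is the sum over its bases of (marker - input)
#' coverage, floored at zero and divided by \code{scaleFactor} (an RPM-like
#' nominal per-million factor). Regions are ranked ascending by signal; with
#' ranks and signals scaled to [0, 1], the super-enhancer cutoff sits at the
#' first rank where the finite-difference slope of the signal curve exceeds
#' 1 (the inflection point where the tangent reaches slope 1); regions above
#' the cutoff are super-enhancers (SEs), the rest typical enhancers (tEs).
#'
#' @param peaks GRanges of marker peaks.
#' @param signal GRanges with \code{score}: marker signal (bedGraph-like).
#' @param inputSignal Optional GRanges with \code{score}: input background.
#' @param tss Optional GRanges of TSS points for the exclusion rule.
#' @param stitchDist Stitching distance, bp (default 12500).
#' @param tssExcl TSS exclusion half-width, bp (default 2000).
#' @param scaleFactor Divisor applied to the raw region signal.
#' @return GRanges of stitched regions, sorted by genomic position, with
#'   \code{signal_rpm}, \code{rank} (ascending with signal) and \code{is_se}
#'   columns.
#' @export
stitchAndRank <- function(peaks, signal, inputSignal = NULL, tss = NULL,
                          stitchDist = 12500L, tssExcl = 2000L,
                          scaleFactor = 1) {
    .checkGRanges(peaks)
    .checkGRanges(signal)
    if (length(peaks) == 0L)
        stop("'peaks' must be non-empty", call. = FALSE)
    kept <- peaks
    if (!is.null(tss) && length(tss)) {
        win <- GenomicRanges::resize(GenomicRanges::granges(tss),
                                     width = 2L * tssExcl + 1L,
                                     fix = "center")
        inside <- .overlapsAnyQ(peaks, win, type = "within",
                                       ignore.strand = TRUE)
        kept <- peaks[!inside]
        if (length(kept) == 0L) {
            warning("all peaks fall within TSS exclusion windows")
            out <- GenomicRanges::GRanges()
            S4Vectors::mcols(out)$signal_rpm <- numeric(0)
            S4Vectors::mcols(out)$rank <- integer(0)
            S4Vectors::mcols(out)$is_se <- logical(0)
            return(out)
        }
    }
    regions <- mergeIntervals(kept, maxGap = stitchDist)
    sig <- regionSignal(regions, signal, inputSignal) / scaleFactor
    rk <- rank(sig, ties.method = "first")
    cutoff <- seCutoff(sig)
    S4Vectors::mcols(regions)$signal_rpm <- sig
    S4Vectors::mcols(regions)$rank <- rk
    S4Vectors::mcols(regions)$is_se <- rk > cutoff
    regions
}

# sum of (marker - input) coverage over each region, floored at 0
regionSignal <- function(regions, signal, inputSignal = NULL) {
    sumCov <- function(track) {
        if (is.null(track) || length(track) == 0L)
            return(numeric(length(regions)))
        cov <- GenomicRanges::coverage(track, weight = "score")
        vapply(seq_along(regions), function(i) {
            chr <- as.character(GenomeInfoDb::seqnames(regions))[i]
            if (!chr %in% names(cov)) return(0)
            r <- cov[[chr]]
            lo <- max(BiocGenerics::start(regions)[i], 1L)
            hi <- min(BiocGenerics::end(regions)[i], length(r))
            if (hi < lo) return(0)
            sum(as.numeric(S4Vectors::window(r, lo, hi)))
        }, numeric(1))
    }
    pmax(sumCov(signal) - sumCov(inputSignal), 0)
}

#' Inflection-point cutoff on a ranked signal curve
#'
#' Scales ranks to (0, 1] and signals to [0, 1] and returns the rank index
#' i such that regions with rank > i are super-enhancers: the first rank at
#' which the finite-difference slope of the scaled curve exceeds 1. On the
#' analytic curve y = x^2 the slope-1 tangent sits at x = 0.5, so exactly
#' half the regions are flagged.
#'
#' @param signals Numeric vector of region signals (any order).
#' @return Integer cutoff rank; regions ranked above it are SEs. Returns
#'   \code{length(signals)} (no SEs) for flat curves.
#' @export
seCutoff <- function(signals) {
    n <- length(signals)
    if (n < 2L) return(n)
    y <- sort(signals)
    if (max(y) == min(y)) return(n)
    ys <- (y - min(y)) / (max(y) - min(y))
    xs <- seq_len(n) / n
    slope <- diff(ys) / diff(xs)
    idx <- which(slope > 1)
    if (length(idx) == 0L) return(n)
    idx[1]
}

#' Temporal dynamics of super-enhancers across infection
#'
#' A 0 h SE with no 6 h overlap is preassembled-decommissioned (pdSE); an
#' overlapping pair is preassembled-maintained (pmSE, counted once, on the
#' 6 h coordinates); a 6 h SE with no 0 h overlap is virus-induced (viSE).
#' The pd/pm/vi labels partition the union of both conditions' SE sets.
#'
#' @param se0h,se6h GRanges of SEs called at 0 h and 6 h.
#' @param minOverlap Minimum overlap in bp (default 1).
#' @return GRanges of all SEs (pm on 6 h coordinates) with a
#'   \code{dynamics} column in \{pdSE, pmSE, viSE\}.
#' @export
classifySeDynamics <- function(se0h, se6h, minOverlap = 1L) {
    .checkGRanges(se0h)
    .checkGRanges(se6h)
    ov6 <- .overlapsAnyQ(se6h, se0h, minoverlap = minOverlap,
                                ignore.strand = TRUE)
    ov0 <- .overlapsAnyQ(se0h, se6h, minoverlap = minOverlap,
                                ignore.strand = TRUE)
    pd <- GenomicRanges::granges(se0h[!ov0])
    pm <- GenomicRanges::granges(se6h[ov6])
    vi <- GenomicRanges::granges(se6h[!ov6])
    out <- .concatGR(pd, pm, vi)
    S4Vectors::mcols(out)$dynamics <- c(rep("pdSE", length(pd)),
                                        rep("pmSE", length(pm)),
                                        rep("viSE", length(vi)))
    BiocGenerics::sort(out, ignore.strand = TRUE)
}

#' Assign super-enhancers to expressed genes
#'
#' Bidirectional scan: a gene is assigned to an SE when its TSS lies within
#' \code{window} bp (inclusive) of the SE center and its replicate-average
#' normalized expression in the state under examination is at least
#' \code{minExpr}.
#'
#' @param ses GRanges of SEs.
#' @param tss GRanges of 1-bp TSS points with a \code{feature_id} column.
#' @param expression Named numeric vector of replicate-average normalized
#'   expression, names matching \code{feature_id}.
#' @param window Assignment half-window, bp (default 5e5).
#' @param minExpr Expression floor (default 10, inclusive).
#' @return data.frame(se, feature_id, distance) with one row per
#'   assignment; \code{se} indexes into \code{ses}.
#' @export
assignSeGenes <- function(ses, tss, expression, window = 500000L,
                          minExpr = 10) {
    .checkGRanges(ses)
    .checkGRanges(tss)
    ids <- S4Vectors::mcols(tss)$feature_id
    expr <- expression[ids]
    keep <- !is.na(expr) & expr >= minExpr
    tssK <- tss[keep]
    idsK <- ids[keep]
    center <- floor((BiocGenerics::start(ses) + BiocGenerics::end(ses)) / 2)
    out <- list()
    chromsS <- as.character(GenomeInfoDb::seqnames(ses))
    chromsT <- as.character(GenomeInfoDb::seqnames(tssK))
    posT <- BiocGenerics::start(tssK)
    for (i in seq_along(ses)) {
        sel <- which(chromsT == chromsS[i] &
                     abs(posT - center[i]) <= window)
        if (length(sel))
            out[[length(out) + 1L]] <- data.frame(
                se = i, feature_id = idsK[sel],
                distance = abs(posT[sel] - center[i]))
    }
    if (length(out) == 0L)
        return(data.frame(se = integer(0), feature_id = character(0),
                          distance = integer(0)))
    do.call(rbind, out)
}

#' Localize elements into SEs, tEs or stand-alone stretches
#'
#' An element overlapping any SE (>= 1 bp) is labelled \code{SE}; failing
#' that, overlap with any typical enhancer gives \code{tE}; everything else
#' is a stand-alone functional genomic stretch (\code{safG}). The SE and tE
#' inputs must be disjoint (guaranteed when both come from one
#' \code{stitchAndRank} run).
#'
#' @param elements GRanges of elements (e.g. SHAe).
#' @param ses,tes GRanges of super-enhancers and typical enhancers.
#' @return Character vector of labels parallel to \code{elements}.
#' @export
localizeElements <- function(elements, ses, tes) {
    .checkGRanges(elements)
    .checkGRanges(ses)
    .checkGRanges(tes)
    if (length(ses) && length(tes) &&
        sum(.overlapsAnyQ(ses, tes, ignore.strand = TRUE)) > 0)
        stop("SE and tE sets must be disjoint", call. = FALSE)
    lab <- rep("safG", length(elements))
    lab[.overlapsAnyQ(elements, tes, ignore.strand = TRUE)] <- "tE"
    lab[.overlapsAnyQ(elements, ses, ignore.strand = TRUE)] <- "SE"
    lab
}
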