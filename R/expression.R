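#' Call virus-responsive differentially expressed features
#'
#' Fold changes are computed on library-size-normalized, replicate-averaged
#' counts; a pseudocount of \code{pseudocount} per condition mean is applied
#' only when a condition mean is zero (so ratios of strictly positive means
#' are exact). Significance comes from an exact conditional binomial
#' rate-ratio test on replicate-summed counts with library-size offsets:
#' conditional on the feature total, the infected count is tested against
#' the infected library share. P-values are BH-adjusted across features; a
#' feature is called up when \code{fc >= fcMin} (inclusive) and
#' \code{p_adj < alpha}, down symmetrically with \code{1/fc}.
#'
#' The same caller covers transposable-element copy tables with
#' \code{fcMin = 1.4}.
#'
#' @param counts Integer matrix, features x samples (rownames = feature ids).
#' @param condition Factor/character per column, two levels; the second
#'   level of \code{levels} is the infected/numerator condition.
#' @param librarySizes Positive numeric per column; defaults to column sums.
#' @param levels Length-2 character: c(reference, treatment).
#' @param fcMin Inclusive fold-change threshold (default 2).
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param pseudocount Stabilizer used when a condition mean is zero.
#' @return A data.frame with feature_id, fc, p_value, p_adj, direction
#'   (up/down/none).
#' @export
callDegs <- function(counts, condition, librarySizes = NULL,
                     levels = NULL, fcMin = 2, alpha = 0.05,
                     pseudocount = 0.5) {
    counts <- as.matrix(counts)
    if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
    condition <- as.character(condition)
    if (is.null(levels)) levels <- unique(condition)
    if (length(levels) != 2L)
        stop("exactly two condition levels are required", call. = FALSE)
    if (is.null(librarySizes)) librarySizes <- colSums(counts)
    if (any(librarySizes <= 0))
        stop("library sizes must be positive", call. = FALSE)
    refCols <- which(condition == levels[1])
    trtCols <- which(condition == levels[2])
    if (length(refCols) < 1L || length(trtCols) < 1L)
        stop("each condition needs at least one replicate", call. = FALSE)
    # normalize to the mean library so the pseudocount stays on count scale
    scale <- mean(librarySizes)
    norm <- sweep(counts, 2, scale / librarySizes, "*")
    mRef <- rowMeans(norm[, refCols, drop = FALSE])
    mTrt <- rowMeans(norm[, trtCols, drop = FALSE])
    needPc <- mRef == 0 | mTrt == 0
    fc <- ifelse(needPc,
                 (mTrt + pseudocount) / (mRef + pseudocount),
                 mTrt / mRef)
    xTrt <- rowSums(counts[, trtCols, drop = FALSE])
    xRef <- rowSums(counts[, refCols, drop = FALSE])
    pShare <- sum(librarySizes[trtCols]) /
        (sum(librarySizes[trtCols]) + sum(librarySizes[refCols]))
    p <- vapply(seq_len(nrow(counts)), function(i) {
        tot <- xTrt[i] + xRef[i]
        if (tot == 0) return(1)
        stats::binom.test(xTrt[i], tot, p = pShare)$p.value
    }, numeric(1))
    padj <- stats::p.adjust(p, method = "BH")
    direction <- rep("none", nrow(counts))
    direction[fc >= fcMin & padj < alpha] <- "up"
    direction[fc <= 1 / fcMin & padj < alpha] <- "down"
    data.frame(feature_id = if (is.null(rownames(counts)))
                   as.character(seq_len(nrow(counts))) else rownames(counts),
               fc = fc, p_value = p, p_adj = padj, direction = direction,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Gate upregulated calls into responsiveness clusters C/I-III
#'
#' Upregulated features are partitioned by fold change: \code{fc >= 16} is
#' C/I (highly inducible), \code{4 <= fc < 16} is C/II (moderately
#' inducible) and \code{2 <= fc < 4} is C/III (mildly inducible). The three
#' gates partition [2, Inf) with no gaps or overlaps; features that are not
#' upregulated (or upregulated below the lowest gate) are labelled
#' "not-applicable".
#'
#' @param calls data.frame from \code{callDegs}.
#' @param bounds Ascending gate boundaries, default c(2, 4, 16).
#' @return \code{calls} with an added \code{cluster} column.
#' @export
gateClusters <- function(calls, bounds = c(2, 4, 16)) {
    stopifnot(is.data.frame(calls), all(c("fc", "direction") %in% names(calls)))
    cl <- rep("not-applicable", nrow(calls))
    up <- calls$direction == "up"
    cl[up & calls$fc >= bounds[3]] <- "C/I"
    cl[up & calls$fc >= bounds[2] & calls$fc < bounds[3]] <- "C/II"
    cl[up & calls$fc >= bounds[1] & calls$fc < bounds[2]] <- "C/III"
    calls$cluster <- cl
    calls
}
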