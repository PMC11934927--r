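#' Call STARR-highly-activated elements (SHAe)
#'
#' Fold change is computed on raw (unnormalized) paired reporter counts,
#' infected over mock; when the mock count is zero it is replaced by
#' \code{pseudocount} (and the element flagged \code{mock_zero}).
#' Significance is an exact conditional binomial test of the infected count
#' against the infected-library share of the element total; the raw p-value
#' is gated (no multiplicity adjustment by default, switchable with
#' \code{adjust}). An element is a SHAe when \code{fc >= fcMin} (inclusive,
#' default 1.44) and p < alpha. SHAe are stratified by fold change:
#' low [1.4, 2), mid [2, 10), high [10, Inf).
#'
#' @param countMock,countInfected Non-negative integer vectors per element.
#' @param elements Optional GRanges parallel to the counts.
#' @param libMock,libInfected Library totals; default to the column sums.
#' @param fcMin Inclusive fold-change gate (default 1.44).
#' @param alpha Significance level on the (raw) p-value.
#' @param adjust Apply BH adjustment before gating (off by default).
#' @param pseudocount Replaces a zero mock count in the fold change.
#' @param strata Lower bounds of the low/mid/high strata.
#' @return data.frame with count_mock, count_infected, fc, p_value, is_shae,
#'   stratum, mock_zero (plus coordinates when \code{elements} given).
#' @export
callShae <- function(countMock, countInfected, elements = NULL,
                     libMock = NULL, libInfected = NULL,
                     fcMin = 1.44, alpha = 0.05, adjust = FALSE,
                     pseudocount = 1, strata = c(1.4, 2, 10)) {
    if (any(countMock < 0) || any(countInfected < 0))
        stop("counts must be non-negative", call. = FALSE)
    if (length(countMock) != length(countInfected))
        stop("mock and infected counts must be parallel", call. = FALSE)
    if (is.null(libMock)) libMock <- sum(countMock)
    if (is.null(libInfected)) libInfected <- sum(countInfected)
    mockZero <- countMock == 0
    denom <- ifelse(mockZero, pseudocount, countMock)
    fc <- countInfected / denom
    pShare <- libInfected / (libInfected + libMock)
    p <- vapply(seq_along(countMock), function(i) {
        tot <- countMock[i] + countInfected[i]
        if (tot == 0) return(1)
        stats::binom.test(countInfected[i], tot, p = pShare)$p.value
    }, numeric(1))
    pGate <- if (adjust) stats::p.adjust(p, "BH") else p
    isShae <- fc >= fcMin & pGate < alpha
    stratum <- rep("none", length(fc))
    stratum[isShae & fc >= strata[1] & fc < strata[2]] <- "low"
    stratum[isShae & fc >= strata[2] & fc < strata[3]] <- "mid"
    stratum[isShae & fc >= strata[3]] <- "high"
    out <- data.frame(count_mock = countMock, count_infected = countInfected,
                      fc = fc, p_value = p, is_shae = isShae,
                      stratum = stratum, mock_zero = mockZero,
                      stringsAsFactors = FALSE)
    if (!is.null(elements)) {
        .checkGRanges(elements)
        out <- cbind(data.frame(
            chrom = as.character(GenomeInfoDb::seqnames(elements)),
            start = BiocGenerics::start(elements),
            end = BiocGenerics::end(elements)), out)
    }
    out
}

#' Intersect two SHAe cohorts and summarize the overlap
#'
#' An element of cohort A is common when it overlaps (>= 1 bp) any element
#' of cohort B. Fractions are percentages of each cohort, reported both to
#' one decimal and to the nearest integer (half-up rounding).
#'
#' @param a,b GRanges cohorts.
#' @return A list with n_a, n_b, n_common, frac_a, frac_b (one decimal),
#'   frac_a_int, frac_b_int, and \code{common} (the overlapping subset of a).
#' @export
intersectCohorts <- function(a, b) {
    .checkGRanges(a)
    .checkGRanges(b)
    common <- a[.overlapsAnyQ(a, b, ignore.strand = TRUE)]
    nA <- length(a); nB <- length(b); nC <- length(common)
    fa <- if (nA > 0) 100 * nC / nA else NA_real_
    fb <- if (nB > 0) 100 * nC / nB else NA_real_
    list(n_a = nA, n_b = nB, n_common = nC,
         frac_a = roundHalfUp(fa, 1), frac_b = roundHalfUp(fb, 1),
         frac_a_int = roundHalfUp(fa, 0), frac_b_int = roundHalfUp(fb, 0),
         common = common)
}
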