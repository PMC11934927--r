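#' @title Interval algebra on genomic ranges
#'
#' @description Thin, convention-fixing layer over GenomicRanges on which
#' every other stage of the pipeline is built. All operations are
#' strand-agnostic; strand is carried on the objects but ignored by the
#' algebra. Coordinates are held in the usual 1-based closed GRanges form
#' internally; BED files (0-based half-open) are converted at the I/O
#' boundary by rtracklayer.
#'
#' @name interval-algebra
NULL

.checkGRanges <- function(x, arg = deparse(substitute(x))) {
    if (!methods::is(x, "GRanges"))
        stop("'", arg, "' must be a GRanges object", call. = FALSE)
    invisible(x)
}

# concatenate GRanges quietly even when seqlevels are disjoint
.concatGR <- function(...) suppressWarnings(c(...))

# overlap query quiet across disjoint seqlevel universes
.overlapsAnyQ <- function(...) suppressWarnings(IRanges::overlapsAny(...))

#' Merge intervals closer than a maximum gap
#'
#' Merges intervals on the same chromosome whose gap (bases strictly between
#' them) is less than or equal to \code{maxGap}. With \code{maxGap = 0} only
#' overlapping or book-ended intervals are merged. This is the primitive
#' behind ROSE-style peak stitching and Cis-Hotspot construction.
#'
#' @param x A \link[GenomicRanges]{GRanges}.
#' @param maxGap Non-negative integer gap in bp; intervals separated by a gap
#'   \code{<= maxGap} are merged (merge at equality).
#' @return A GRanges of disjoint merged intervals, sorted.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 9, 31), c(10, 20, 40)))
#' mergeIntervals(gr, 0)
#' @export
mergeIntervals <- function(x, maxGap = 0L) {
    .checkGRanges(x)
    if (length(maxGap) != 1L || is.na(maxGap) || maxGap < 0)
        stop("'maxGap' must be a single non-negative number", call. = FALSE)
    GenomicRanges::reduce(x, min.gapwidth = as.integer(maxGap) + 1L,
                          ignore.strand = TRUE)
}

#' Base-level intersection of several interval sets
#'
#' Computes the bases covered by every one of the supplied sets, by
#' sequential pairwise intersection. Base-level semantics make the result
#' independent of the order of the sets; this realizes the hierarchical
#' multi-assay peak intersection used for Cis-Hotspot mapping.
#'
#' @param sets A non-empty list of GRanges.
#' @return A GRanges covering exactly the bases present in all sets.
#' @export
intersectMulti <- function(sets) {
    if (!is.list(sets) && methods::is(sets, "GRangesList"))
        sets <- as.list(sets)
    if (!is.list(sets) || length(sets) == 0L)
        stop("'sets' must be a non-empty list of GRanges", call. = FALSE)
    for (s in sets) .checkGRanges(s, "sets[[i]]")
    Reduce(function(a, b)
        GenomicRanges::intersect(a, b, ignore.strand = TRUE),
        lapply(sets, function(g) GenomicRanges::reduce(g, ignore.strand = TRUE)))
}

#' Distance from each query interval to its nearest reference interval
#'
#' Zero for overlapping pairs, otherwise the number of bases strictly
#' between the nearest edges, computed per chromosome. Queries on a
#' chromosome carrying no reference interval receive \code{NA} (the
#' "unreachable" sentinel). Ties between equidistant references resolve to
#' the leftmost reference, which only matters to callers that ask for the
#' index of the nearest hit.
#'
#' @param query,reference GRanges; \code{reference} must be non-empty.
#' @param returnHits If \code{TRUE} also return the index of the nearest
#'   reference interval (leftmost on ties; \code{NA} when unreachable).
#' @return An integer vector of distances parallel to \code{query}, or a
#'   data.frame with columns \code{distance} and \code{ref} when
#'   \code{returnHits}.
#' @export
nearestDistance <- function(query, reference, returnHits = FALSE) {
    .checkGRanges(query)
    .checkGRanges(reference)
    if (length(reference) == 0L)
        stop("'reference' must be non-empty", call. = FALSE)
    d <- rep(NA_integer_, length(query))
    ref <- rep(NA_integer_, length(query))
    if (length(query)) {
        hits <- suppressWarnings(GenomicRanges::distanceToNearest(
            query, reference, ignore.strand = TRUE))
        qh <- S4Vectors::queryHits(hits)
        d[qh] <- S4Vectors::mcols(hits)$distance
        ref[qh] <- S4Vectors::subjectHits(hits)
        if (returnHits) {
            # resolve ties to the leftmost reference: inspect every
            # reference at the minimum distance of each resolved query
            qchr <- as.character(GenomeInfoDb::seqnames(query))
            rchr <- as.character(GenomeInfoDb::seqnames(reference))
            for (i in qh) {
                cand <- which(rchr == qchr[i])
                dd <- suppressWarnings(GenomicRanges::distance(
                    rep(query[i], length(cand)), reference[cand],
                    ignore.strand = TRUE))
                tied <- cand[!is.na(dd) & dd == d[i]]
                ref[i] <- tied[which.min(BiocGenerics::start(reference)[tied])]
            }
        }
    }
    if (returnHits) data.frame(distance = d, ref = ref) else d
}

#' Gap-bounded clustering of motif instances into domains
#'
#' Finds maximal runs of intervals in which every consecutive gap (bases
#' strictly between neighbours) is strictly less than \code{maxGap}; runs
#' holding at least \code{minCount} members are emitted as a single interval
#' spanning the first to the last member. A consecutive gap exactly equal to
#' \code{maxGap} breaks the run (strict inequality). This is the primitive
#' behind IRHAD mapping (\code{>= 3} instances spaced by \code{< 75} bp).
#'
#' @param x GRanges of instances (sorted or sortable).
#' @param maxGap Strict upper bound on the within-run gap, bp.
#' @param minCount Minimum run size emitted; must be \code{>= 1}.
#' @return GRanges of cluster spans with an \code{n_members} metadata column.
#' @export
clusterIntervals <- function(x, maxGap = 75L, minCount = 3L) {
    .checkGRanges(x)
    if (length(minCount) != 1L || is.na(minCount) || minCount < 1)
        stop("'minCount' must be >= 1", call. = FALSE)
    if (length(maxGap) != 1L || is.na(maxGap) || maxGap < 0)
        stop("'maxGap' must be a single non-negative number", call. = FALSE)
    emptyOut <- function() {
        g <- GenomicRanges::GRanges()
        S4Vectors::mcols(g)$n_members <- integer(0)
        g
    }
    if (length(x) == 0L)
        return(emptyOut())
    x <- BiocGenerics::sort(GenomicRanges::granges(x), ignore.strand = TRUE)
    chrom <- as.character(GenomeInfoDb::seqnames(x))
    s <- BiocGenerics::start(x)
    e <- BiocGenerics::end(x)
    # run end positions must be monotone for the gap to be meaningful
    emax <- stats::ave(e, chrom, FUN = cummax)
    n <- length(x)
    # gap in 0-based half-open terms between instance i and i+1
    gap <- s[-1L] - 1L - emax[-n]
    newrun <- c(TRUE, chrom[-1L] != chrom[-n] | gap >= maxGap)
    runid <- cumsum(newrun)
    cnt <- tabulate(runid)
    keep <- which(cnt >= minCount)
    if (length(keep) == 0L)
        return(emptyOut())
    first <- match(keep, runid)
    out <- GenomicRanges::GRanges(
        chrom[first],
        IRanges::IRanges(
            start = s[first],
            end = vapply(keep, function(k) max(e[runid == k]), integer(1))))
    S4Vectors::mcols(out)$n_members <- cnt[keep]
    BiocGenerics::sort(out, ignore.strand = TRUE)
}

#' Read and write BED intervals
#'
#' Convenience wrappers over \link[rtracklayer]{import} /
#' \link[rtracklayer]{export} fixing the format to BED (0-based half-open on
#' disk, 1-based closed in memory) so every stage reads and writes intervals
#' the same way.
#'
#' @param path File path.
#' @param x GRanges to write.
#' @return \code{readBed} returns a GRanges.
#' @export
readBed <- function(path) {
    rtracklayer::import(path, format = "BED")
}

#' @rdname readBed
#' @export
writeBed <- function(x, path) {
    .checkGRanges(x)
    rtracklayer::export(x, path, format = "BED")
    invisible(path)
}

#' @rdname readBed
#' @export
readBedGraph <- function(path) {
    rtracklayer::import(path, format = "bedGraph")
}

#' @rdname readBed
#' @export
writeBedGraph <- function(x, path) {
    .checkGRanges(x)
    rtracklayer::export(x, path, format = "bedGraph")
    invisible(path)
}
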