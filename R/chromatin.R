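#' Map Cis-Hotspots by four-way assay intersection
#'
#' A Cis-Hotspot (CH) is a locus co-occupied by open chromatin (DNaseI),
#' H3K27ac, MED1 and RNA polymerase II in one condition. CH intervals are
#' the base-level intersection of the four defining peak tracks (order
#' independent); transcription-factor occupancy flags are set when a CH
#' overlaps the corresponding TF track by at least 1 bp.
#'
#' @param tracks Named list of GRanges holding at least the four defining
#'   assays \code{DNaseI}, \code{H3K27ac}, \code{MED1}, \code{RNAPII}.
#' @param tfTracks Optional named list of GRanges (e.g. IRF3, p65, CBP);
#'   each yields a logical occupancy column.
#' @param tss Optional GRanges of TSS points with a \code{feature_id}
#'   column; CHs are associated with features whose TSS +/- \code{assocWindow}
#'   they intersect.
#' @param assocWindow Half-width of the TSS association window (bp).
#' @return GRanges of CHs with occupancy flag columns and, when \code{tss}
#'   is given, a comma-separated \code{assoc_features} column.
#' @export
mapCisHotspots <- function(tracks, tfTracks = NULL, tss = NULL,
                           assocWindow = 2000L) {
    defining <- c("DNaseI", "H3K27ac", "MED1", "RNAPII")
    missing <- setdiff(defining, names(tracks))
    if (length(missing))
        stop("missing defining assay track(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    ch <- intersectMulti(unname(tracks[defining]))
    if (!is.null(tfTracks)) {
        for (tf in names(tfTracks)) {
            S4Vectors::mcols(ch)[[paste0("occ_", tf)]] <-
                .overlapsAnyQ(ch, tfTracks[[tf]], ignore.strand = TRUE)
        }
    }
    if (!is.null(tss) && length(ch)) {
        win <- GenomicRanges::resize(GenomicRanges::granges(tss),
                                     width = 2L * assocWindow + 1L,
                                     fix = "center")
        hits <- GenomicRanges::findOverlaps(ch, win, ignore.strand = TRUE)
        ids <- S4Vectors::mcols(tss)$feature_id
        assoc <- rep("", length(ch))
        if (length(hits)) {
            sp <- split(ids[S4Vectors::subjectHits(hits)],
                        S4Vectors::queryHits(hits))
            assoc[as.integer(names(sp))] <-
                vapply(sp, paste, character(1), collapse = ",")
        }
        S4Vectors::mcols(ch)$assoc_features <- assoc
    }
    ch
}

#' Classify temporal dynamics of Cis-Hotspots across infection
#'
#' A 6 h CH overlapping any 0 h CH (>= \code{minOverlap} bp) is
#' "pre-printed" (conveyed by epigenetic memory); a 6 h CH with no 0 h
#' overlap is "newly-established"; a 0 h CH with no 6 h overlap is
#' "decommissioned". Pre-printed and newly-established partition the 6 h
#' set.
#'
#' @param ch0h,ch6h GRanges of CHs at 0 h and 6 h.
#' @param minOverlap Minimum overlap in bp (default 1).
#' @return A list with \code{ch6h} and \code{ch0h}, each carrying a
#'   \code{status} metadata column.
#' @export
classifyChDynamics <- function(ch0h, ch6h, minOverlap = 1L) {
    .checkGRanges(ch0h)
    .checkGRanges(ch6h)
    ov6 <- .overlapsAnyQ(ch6h, ch0h, minoverlap = minOverlap,
                                ignore.strand = TRUE)
    ov0 <- .overlapsAnyQ(ch0h, ch6h, minoverlap = minOverlap,
                                ignore.strand = TRUE)
    S4Vectors::mcols(ch6h)$status <-
        ifelse(ov6, "pre-printed", "newly-established")
    S4Vectors::mcols(ch0h)$status <-
        ifelse(ov0, "pre-printed", "decommissioned")
    list(ch0h = ch0h, ch6h = ch6h)
}

#' Reference-point signal matrix (computeMatrix-style)
#'
#' For each reference point, averages a scored track over bins of
#' \code{binSize} bp across \code{+/- flank}; bases not covered by the track
#' contribute zero. Reference points are the start base of each range in
#' \code{refs} (use 1-bp TSS ranges, peak centers, or element centers).
#'
#' @param track GRanges with a numeric \code{score} column (bedGraph-like,
#'   assumed non-overlapping).
#' @param refs GRanges of reference points; the first base of each range is
#'   the anchor.
#' @param flank Half-window, bp (default 2000).
#' @param binSize Bin width; must divide \code{2 * flank}.
#' @return Numeric matrix, one row per reference, one column per bin;
#'   column names give bin start offsets relative to the anchor.
#' @export
signalMatrix <- function(track, refs, flank = 2000L, binSize = 50L) {
    .checkGRanges(track)
    .checkGRanges(refs)
    if ((2L * flank) %% binSize != 0L)
        stop("'binSize' must divide 2*flank", call. = FALSE)
    nbin <- as.integer(2L * flank / binSize)
    offsets <- seq(-flank, flank - binSize, by = binSize)
    if (length(refs) == 0L) {
        m <- matrix(numeric(0), nrow = 0, ncol = nbin)
        colnames(m) <- offsets
        return(m)
    }
    if (is.null(S4Vectors::mcols(track)$score))
        stop("'track' needs a numeric score column", call. = FALSE)
    cov <- GenomicRanges::coverage(track, weight = "score")
    anchors <- BiocGenerics::start(refs)
    chroms <- as.character(GenomeInfoDb::seqnames(refs))
    m <- matrix(0, nrow = length(refs), ncol = nbin)
    for (i in seq_along(refs)) {
        v <- numeric(2L * flank)
        if (chroms[i] %in% names(cov)) {
            r <- cov[[chroms[i]]]
            from <- anchors[i] - flank
            to <- anchors[i] + flank - 1L
            lo <- max(from, 1L)
            hi <- min(to, length(r))
            if (hi >= lo)
                v[(lo - from + 1L):(hi - from + 1L)] <-
                    as.numeric(S4Vectors::window(r, lo, hi))
        }
        m[i, ] <- colMeans(matrix(v, nrow = binSize))
    }
    colnames(m) <- offsets
    rownames(m) <- names(refs)
    m
}
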