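#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' MotifModel: a consensus or PWM motif with scanning parameters
#'
#' Holds either an IUPAC consensus string (exact degenerate-code matching)
#' or a position frequency matrix scanned as a log-odds PWM against a
#' uniform background. The score threshold of a PWM model defaults to the
#' score whose tail probability under the uniform background is 1e-5,
#' mirroring common genome-scanning defaults.
#'
#' @slot name Motif name.
#' @slot consensus IUPAC consensus string, or \code{NA} in PWM mode.
#' @slot pfm 4 x width position frequency matrix (rows A,C,G,T), or NULL.
#' @slot scoreThreshold Minimum log2-odds score for a PWM hit.
#' @exportClass MotifModel
setClass("MotifModel",
    representation(name = "character", consensus = "character",
                   pfm = "matrixOrNULL", scoreThreshold = "numeric"),
    prototype(name = NA_character_, consensus = NA_character_,
              pfm = NULL, scoreThreshold = NA_real_))

IUPAC_EXPAND <- c(A = "A", C = "C", G = "G", T = "T",
                  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

setValidity("MotifModel", function(object) {
    msgs <- character(0)
    hasCons <- !is.na(object@consensus)
    hasPfm <- !is.null(object@pfm)
    if (!hasCons && !hasPfm)
        msgs <- c(msgs, "either 'consensus' or 'pfm' must be supplied")
    if (hasCons) {
        bad <- setdiff(strsplit(toupper(object@consensus), "")[[1]],
                       names(IUPAC_EXPAND))
        if (length(bad))
            msgs <- c(msgs, paste0("invalid IUPAC code(s): ",
                                   paste(unique(bad), collapse = ", ")))
    }
    if (hasPfm) {
        if (nrow(object@pfm) != 4L)
            msgs <- c(msgs, "'pfm' must have 4 rows (A, C, G, T)")
        cs <- colSums(object@pfm)
        if (any(abs(cs - cs[1]) > 1e-6 * max(cs, 1)))
            msgs <- c(msgs, "'pfm' columns must sum to a common total")
    }
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "MotifModel", function(object) {
    mode <- if (!is.na(object@consensus)) "consensus" else "PWM"
    cat("MotifModel '", object@name, "' (", mode, " mode, width ",
        motifWidth(object), ")\n", sep = "")
    if (!is.na(object@consensus))
        cat("  consensus: ", object@consensus, "\n", sep = "")
    else
        cat("  log2-odds threshold: ",
            format(object@scoreThreshold, digits = 4), "\n", sep = "")
})

#' Construct a consensus MotifModel
#' @param name Motif name.
#' @param consensus IUPAC consensus string.
#' @return A \linkS4class{MotifModel}.
#' @examples
#' consensusMotif("kB-degenerate", "GGGNNNNNCC")
#' @export
consensusMotif <- function(name, consensus) {
    methods::new("MotifModel", name = name,
                 consensus = toupper(as.character(consensus)))
}

#' Construct a PWM MotifModel from a position frequency matrix
#'
#' @param name Motif name.
#' @param pfm 4 x width count matrix, rows A, C, G, T (JASPAR order).
#' @param scoreThreshold Minimum log2-odds score for a hit; when NULL it is
#'   set by \code{pwmThreshold(pfm, pvalue)}.
#' @param pvalue Tail probability defining the default threshold.
#' @param pseudocount Added to every PFM cell before normalization.
#' @return A \linkS4class{MotifModel}.
#' @export
pfmMotif <- function(name, pfm, scoreThreshold = NULL, pvalue = 1e-5,
                     pseudocount = 0.5) {
    pfm <- as.matrix(pfm)
    rownames(pfm) <- c("A", "C", "G", "T")
    if (is.null(scoreThreshold))
        scoreThreshold <- pwmThreshold(pwmFromPfm(pfm, pseudocount), pvalue)
    methods::new("MotifModel", name = name, consensus = NA_character_,
                 pfm = pfm, scoreThreshold = scoreThreshold)
}

#' @rdname pfmMotif
#' @param motif A MotifModel.
#' @export
motifWidth <- function(motif) {
    if (!is.na(motif@consensus)) nchar(motif@consensus) else ncol(motif@pfm)
}

#' Log2-odds position weight matrix from a frequency matrix
#'
#' @param pfm 4 x width count matrix, rows A, C, G, T.
#' @param pseudocount Added to every cell before normalization.
#' @return 4 x width numeric matrix of log2(p / 0.25) scores.
#' @export
pwmFromPfm <- function(pfm, pseudocount = 0.5) {
    pfm <- as.matrix(pfm) + pseudocount
    p <- sweep(pfm, 2, colSums(pfm), "/")
    log2(p / 0.25)
}

#' Score threshold at a given tail probability under a uniform background
#'
#' Computes the exact distribution of the PWM score of a random uniform
#' sequence by dynamic programming (column-by-column convolution of the
#' per-position score distributions, on scores discretized to \code{digits}
#' decimals) and returns the smallest score t with P(score >= t) <= pvalue.
#'
#' @param pwm Log-odds matrix from \code{pwmFromPfm}.
#' @param pvalue Target tail probability.
#' @param digits Discretization of scores, decimal places.
#' @return A single numeric threshold.
#' @export
pwmThreshold <- function(pwm, pvalue = 1e-5, digits = 3L) {
    scale <- 10^digits
    si <- round(pwm * scale)
    dist <- c(`0` = 1)  # named by integer score
    for (j in seq_len(ncol(si))) {
        cur <- as.integer(names(dist))
        out <- new.env(hash = TRUE, parent = emptyenv())
        for (k in seq_along(cur)) {
            for (b in 1:4) {
                key <- as.character(cur[k] + si[b, j])
                prev <- if (is.null(out[[key]])) 0 else out[[key]]
                out[[key]] <- prev + dist[k] * 0.25
            }
        }
        keys <- ls(out)
        dist <- vapply(keys, function(k) out[[k]], numeric(1))
        names(dist) <- keys
    }
    sc <- as.integer(names(dist))
    o <- order(sc, decreasing = TRUE)
    tail <- cumsum(dist[o])
    idx <- which(tail <= pvalue)
    if (length(idx) == 0L) return(max(sc) / scale + 1 / scale)
    sc[o][max(idx)] / scale
}

.asDNAString <- function(x) {
    if (methods::is(x, "DNAString")) x else Biostrings::DNAString(as.character(x))
}

# all (possibly overlapping) hits of a motif on one strand of a sequence;
# returns data.frame(start, end, score) in plus coordinates of `subject`
.scanOneStrand <- function(subject, motif, strand) {
    w <- motifWidth(motif)
    L <- length(subject)
    if (L < w) return(data.frame(start = integer(0), end = integer(0),
                                 score = numeric(0)))
    if (!is.na(motif@consensus)) {
        pat <- Biostrings::DNAString(motif@consensus)
        if (strand == "-") pat <- Biostrings::reverseComplement(pat)
        m <- Biostrings::matchPattern(pat, subject,
                                      fixed = c(pattern = FALSE, subject = TRUE))
        data.frame(start = BiocGenerics::start(m), end = BiocGenerics::end(m),
                   score = rep(as.numeric(w), length(m)))
    } else {
        pwm <- pwmFromPfm(motif@pfm)
        if (strand == "-") {
            pwm <- pwm[4:1, ncol(pwm):1]
            rownames(pwm) <- c("A", "C", "G", "T")
        }
        m <- Biostrings::matchPWM(pwm, subject,
                                  min.score = motif@scoreThreshold,
                                  with.score = TRUE)
        data.frame(start = BiocGenerics::start(m), end = BiocGenerics::end(m),
                   score = as.numeric(S4Vectors::mcols(m)$score))
    }
}

#' Scan a sequence for motif matches
#'
#' Consensus models are matched by exact degenerate IUPAC code matching
#' (an N in the subject matches nothing but the code N); PWM models by
#' log2-odds score against a uniform background with hits at or above the
#' model threshold. Minus-strand hits are reported in plus coordinates with
#' strand \code{-}. When \code{nonoverlapping}, overlaps are resolved
#' greedily left to right by position, then by higher score, then by plus
#' strand.
#'
#' @param subject A DNAString or character sequence over A,C,G,T,N.
#' @param motif A \linkS4class{MotifModel}.
#' @param strands \code{"both"} or \code{"forward"}.
#' @param nonoverlapping Drop lower-priority overlapping hits.
#' @param seqname Chromosome name used for the returned GRanges.
#' @return GRanges of matches with \code{score} and \code{motif} columns,
#'   strand set per hit.
#' @export
scanMotif <- function(subject, motif, strands = c("both", "forward"),
                      nonoverlapping = TRUE, seqname = "seq") {
    strands <- match.arg(strands)
    methods::validObject(motif)
    subject <- .asDNAString(subject)
    hitsF <- .scanOneStrand(subject, motif, "+")
    hitsF$strand <- rep("+", nrow(hitsF))
    hits <- hitsF
    if (strands == "both") {
        hitsR <- .scanOneStrand(subject, motif, "-")
        if (nrow(hitsR)) {
            hitsR$strand <- "-"
            hits <- rbind(hits, hitsR)
        }
    }
    if (nrow(hits) && nonoverlapping) {
        o <- order(hits$start, -hits$score, hits$strand)
        hits <- hits[o, , drop = FALSE]
        keep <- logical(nrow(hits))
        lastEnd <- 0L
        for (i in seq_len(nrow(hits))) {
            if (hits$start[i] > lastEnd) {
                keep[i] <- TRUE
                lastEnd <- hits$end[i]
            }
        }
        hits <- hits[keep, , drop = FALSE]
    }
    gr <- GenomicRanges::GRanges(
        rep(seqname, nrow(hits)),
        IRanges::IRanges(hits$start, hits$end),
        strand = if (nrow(hits)) hits$strand else character(0))
    S4Vectors::mcols(gr)$score <- hits$score
    S4Vectors::mcols(gr)$motif <- rep(motif@name, nrow(hits))
    BiocGenerics::sort(gr, ignore.strand = TRUE)
}

# pool hits of several motif models and re-resolve nonoverlap greedily
.pooledNonoverlapping <- function(subject, motifs, strands = "both",
                                  seqname = "seq") {
    if (methods::is(motifs, "MotifModel")) motifs <- list(motifs)
    all <- do.call(.concatGR, lapply(motifs, function(m)
        scanMotif(subject, m, strands = strands, nonoverlapping = FALSE,
                  seqname = seqname)))
    if (length(all) == 0L) return(all)
    o <- order(BiocGenerics::start(all), -S4Vectors::mcols(all)$score,
               as.character(BiocGenerics::strand(all)))
    all <- all[o]
    keep <- logical(length(all))
    lastEnd <- 0L
    for (i in seq_along(all)) {
        if (BiocGenerics::start(all)[i] > lastEnd) {
            keep[i] <- TRUE
            lastEnd <- BiocGenerics::end(all)[i]
        }
    }
    all[keep]
}

# best (max-count, then min-span) run of sorted hits with span <= maxSpan;
# span = first matched base to last matched base
.bestRun <- function(starts, ends, maxSpan) {
    n <- length(starts)
    if (n == 0L) return(list(count = 0L, span = 0L, from = NA_integer_,
                             to = NA_integer_))
    best <- list(count = 0L, span = 0L, from = NA_integer_, to = NA_integer_)
    j <- 1L
    for (i in seq_len(n)) {
        if (j < i) j <- i
        while (j < n && ends[j + 1L] - starts[i] + 1L <= maxSpan) j <- j + 1L
        cnt <- j - i + 1L
        spn <- ends[j] - starts[i] + 1L
        if (cnt > best$count || (cnt == best$count && spn < best$span))
            best <- list(count = cnt, span = spn, from = i, to = j)
    }
    best
}

.hctfbsRecord <- function(family, subclass, siteCount, span, syntax, sites,
                          extra = list(), isCall = TRUE) {
    c(list(family = family, subclass = subclass, site_count = siteCount,
           span = span, syntax = syntax, sites = sites, is_call = isCall),
      extra)
}

#' Call a homotypic IRF-family binding site cluster (IR-HCTFBS)
#'
#' An element is a core IR-HCTFBS when it holds at least \code{minPerfect}
#' nonoverlapping perfect IRF3/IRF1 sites whose span (first matched base to
#' last) is at most \code{coreWindow} bp; failing that it is a half-site
#' IR-HCTFBS when more than \code{halfMin} nonoverlapping AAAG half sites
#' fall within a window of at most \code{halfWindow} bp. Core calls carry a
#' syntax label from \code{classifySyntax}.
#'
#' @param subject Element sequence (DNAString or character).
#' @param perfectMotifs A MotifModel or list of MotifModels for perfect sites.
#' @param halfSite Half-site consensus, default \code{"AAAG"}.
#' @param coreWindow,halfWindow Maximum spans, bp.
#' @param minPerfect Minimum perfect sites for a core call.
#' @param halfMin Half-site count must strictly exceed this for a call.
#' @return A list describing the call (family, subclass, site_count, span,
#'   syntax, sites), or NULL when neither rule fires.
#' @export
callIrHctfbs <- function(subject, perfectMotifs, halfSite = "AAAG",
                         coreWindow = 400L, halfWindow = 1000L,
                         minPerfect = 3L, halfMin = 10L) {
    subject <- .asDNAString(subject)
    perfect <- .pooledNonoverlapping(subject, perfectMotifs)
    run <- .bestRun(BiocGenerics::start(perfect), BiocGenerics::end(perfect),
                    coreWindow)
    if (run$count >= minPerfect) {
        sel <- perfect[seq(run$from, run$to)]
        return(.hctfbsRecord("IR", "core", run$count, run$span,
                             classifySyntax(sel), sel))
    }
    halves <- scanMotif(subject, consensusMotif("half", halfSite),
                        strands = "forward")
    hrun <- .bestRun(BiocGenerics::start(halves), BiocGenerics::end(halves),
                     halfWindow)
    if (hrun$count > halfMin) {
        sel <- halves[seq(hrun$from, hrun$to)]
        return(.hctfbsRecord("IR", "half-site", hrun$count, hrun$span,
                             "n/a", sel))
    }
    NULL
}

#' Call a homotypic NF-kB binding site cluster (kBR-HCTFBS)
#'
#' Rule (i): at least \code{minPerfect} nonoverlapping perfect
#' NFKB1/2/REL/A/B sites within \code{coreWindow} bp. Rule (ii):
#' \code{degRange[1]}--\code{degRange[2]} nonoverlapping degenerate sites
#' (default \code{GGGNNNNNCC}, both strands) within \code{degWindow} bp; a
#' densest window holding more than \code{degRange[2]} sites is reported as
#' out-of-range and does not trigger a call. GGRR half sites are counted and
#' reported but never call-triggering.
#'
#' @inheritParams callIrHctfbs
#' @param degenerate Degenerate-site consensus.
#' @param degRange Inclusive site-count range for rule (ii).
#' @param degWindow Maximum degenerate-cluster span, bp.
#' @param halfSite NF-kB half-site consensus, annotated only.
#' @return A call list as in \code{callIrHctfbs} (with
#'   \code{ggrr_half_sites} and \code{degenerate_out_of_range} extras), or
#'   NULL.
#' @export
callKbHctfbs <- function(subject, perfectMotifs, degenerate = "GGGNNNNNCC",
                         degRange = c(4L, 14L), degWindow = 1300L,
                         coreWindow = 400L, minPerfect = 3L,
                         halfSite = "GGRR") {
    subject <- .asDNAString(subject)
    halves <- scanMotif(subject, consensusMotif("kB-half", halfSite))
    extra <- list(ggrr_half_sites = length(halves),
                  degenerate_out_of_range = FALSE)
    perfect <- .pooledNonoverlapping(subject, perfectMotifs)
    run <- .bestRun(BiocGenerics::start(perfect), BiocGenerics::end(perfect),
                    coreWindow)
    if (run$count >= minPerfect) {
        sel <- perfect[seq(run$from, run$to)]
        return(.hctfbsRecord("kB", "core", run$count, run$span,
                             classifySyntax(sel), sel, extra))
    }
    deg <- scanMotif(subject, consensusMotif("kB-degenerate", degenerate))
    drun <- .bestRun(BiocGenerics::start(deg), BiocGenerics::end(deg),
                     degWindow)
    if (drun$count > degRange[2]) {
        # densest window exceeds the printed upper bound: reported, not a call
        extra$degenerate_out_of_range <- TRUE
        sel <- deg[seq(drun$from, drun$to)]
        return(.hctfbsRecord("kB", "out-of-range", drun$count, drun$span,
                             "n/a", sel, extra, isCall = FALSE))
    }
    if (drun$count >= degRange[1] && drun$count <= degRange[2]) {
        sel <- deg[seq(drun$from, drun$to)]
        return(.hctfbsRecord("kB", "degenerate", drun$count, drun$span,
                             "n/a", sel, extra))
    }
    NULL
}

#' Syntax (relative orientation) of an ordered run of motif sites
#'
#' Consecutive pairs on the same strand are Head-to-Tail; a plus site
#' followed by a minus site points the two 5'->3' directions towards each
#' other (Head-to-Head); a minus then a plus site point apart
#' (Tail-to-Tail). The element label is the majority over pairs, "mixed" on
#' a tie, and "n/a" with fewer than two sites.
#'
#' @param sites GRanges of sites with strand set, or a character vector of
#'   strands ordered by position.
#' @return One of "Head-to-Tail", "Head-to-Head", "Tail-to-Tail", "mixed",
#'   "n/a".
#' @export
classifySyntax <- function(sites) {
    st <- if (methods::is(sites, "GRanges")) {
        o <- order(BiocGenerics::start(sites))
        as.character(BiocGenerics::strand(sites))[o]
    } else as.character(sites)
    if (length(st) < 2L) return("n/a")
    a <- st[-length(st)]
    b <- st[-1L]
    lab <- ifelse(a == b, "Head-to-Tail",
                  ifelse(a == "+", "Head-to-Head", "Tail-to-Tail"))
    tab <- table(lab)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) "mixed" else top
}

#' Scan a genome with the clustered-IRF3 consensus and report coverage
#'
#' Scans every chromosome on both strands for nonoverlapping instances of
#' the 25-bp clustered-IRF3 ("cIR") bait motif and reports the percent of
#' the genome covered as 100 * instances * motif_width / genome_length.
#'
#' @param genome A DNAStringSet (named by chromosome) or single sequence.
#' @param motif MotifModel; defaults to the built-in cIR consensus.
#' @return A list with \code{instances} (GRanges), \code{n_instances},
#'   \code{coverage_pct} and \code{genome_length}.
#' @export
scanGenomeCoverage <- function(genome, motif = cirMotif()) {
    if (!methods::is(genome, "DNAStringSet"))
        genome <- Biostrings::DNAStringSet(.asDNAString(genome))
    if (is.null(names(genome)))
        names(genome) <- paste0("chr", seq_along(genome))
    instances <- do.call(.concatGR, lapply(names(genome), function(chr)
        scanMotif(genome[[chr]], motif, seqname = chr)))
    L <- sum(Biostrings::width(genome))
    n <- length(instances)
    list(instances = instances, n_instances = n,
         coverage_pct = 100 * n * motifWidth(motif) / L,
         genome_length = L)
}

#' The 25-bp clustered-IRF3 consensus motif
#'
#' Built-in bait consensus \code{RRAARGGAAAGGAAAGGAAAGGAAA} used for
#' cross-genome scanning and IRHAD mapping.
#'
#' @return A \linkS4class{MotifModel}.
#' @export
cirMotif <- function() {
    consensusMotif("cIR", "RRAARGGAAAGGAAAGGAAAGGAAA")
}

#' Built-in perfect-site consensus models
#'
#' IUPAC consensus stand-ins for the perfect IRF-family site (two AAAG half
#' sites) and the perfect NF-kB site used by the synthetic data generator
#' and the HCTFBS examples; real analyses should load JASPAR PFMs via
#' \code{readJasparPfm} and \code{pfmMotif}.
#'
#' @return A \linkS4class{MotifModel}.
#' @export
irfPerfectMotif <- function() consensusMotif("IRF-perfect", "RAAAGGAAAG")

#' @rdname irfPerfectMotif
#' @export
kbPerfectMotif <- function() consensusMotif("kB-perfect", "GGGRCTTTCC")

#' Map IR-HCTFBS aggregated domains (IRHADs)
#'
#' Delegates to \code{clusterIntervals}: domains are maximal runs of at
#' least \code{minCount} motif instances with consecutive gaps strictly
#' below \code{maxGap} bp.
#'
#' @param instances GRanges of cIR-motif instances.
#' @param maxGap,minCount Clustering parameters (defaults 75 bp, 3).
#' @return GRanges of IRHADs with member counts.
#' @export
mapIrhads <- function(instances, maxGap = 75L, minCount = 3L) {
    clusterIntervals(instances, maxGap = maxGap, minCount = minCount)
}

#' Read a JASPAR-format position frequency matrix
#'
#' Reads the 4-line JASPAR text layout (\code{>ID name} header then
#' \code{A [ ... ]} etc.) into a 4 x width count matrix.
#'
#' @param path Path to a JASPAR .pfm/.jaspar text file.
#' @return A named list with \code{name} and \code{pfm}.
#' @export
readJasparPfm <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    hdr <- grep("^>", lines)
    name <- if (length(hdr)) trimws(sub("^>\\s*", "", lines[hdr[1]])) else basename(path)
    rows <- grep("^[ACGT]", lines, value = TRUE)
    if (length(rows) != 4L)
        stop("expected 4 base rows in JASPAR file: ", path, call. = FALSE)
    parse1 <- function(x) {
        x <- gsub("^[ACGT]\\s*\\[?", "", x)
        x <- gsub("\\]\\s*$", "", x)
        as.numeric(strsplit(trimws(x), "\\s+")[[1]])
    }
    pfm <- do.call(rbind, lapply(rows, parse1))
    rownames(pfm) <- substr(rows, 1, 1)
    pfm <- pfm[c("A", "C", "G", "T"), , drop = FALSE]
    list(name = name, pfm = pfm)
}
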