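#' SimConfig: parameters of the synthetic study generator
#'
#' One object holds every knob of the synthetic multi-omics study the
#' package can generate: genome geometry, planted regulatory features,
#' count-model parameters and library sizes. With a fixed seed the three
#' generators are fully deterministic. Defaults are sized for a compact
#' two-chromosome study that still exercises every analysis stage.
#'
#' @slot seed Integer RNG seed.
#' @slot nChroms Number of chromosomes.
#' @slot chromLength Length of each chromosome, bp.
#' @slot nGenes Number of genes in the expression table.
#' @slot nPeaksPerAssay Background peaks per assay and condition.
#' @slot plantedChCount Planted four-way co-occupied (Cis-Hotspot) loci.
#' @slot plantedSeCount Planted dense peak runs that must stitch into SEs.
#' @slot nStarrElements Number of STARR elements.
#' @slot plantedShaeFraction Fraction of STARR elements that are truly
#'   active.
#' @slot degClusterSizes Named counts of planted upregulated genes per
#'   responsiveness cluster (CI, CII, CIII).
#' @slot nbDispersion Negative-binomial dispersion of all counts.
#' @slot librarySizes RNA library sizes (naive x2, infected x2).
#' @slot starrLibrarySizes STARR library sizes (mock, infected).
#' @slot plantedHctfbs Named counts of planted homotypic clusters (IR, kB).
#' @slot plantedCirInstances Planted isolated 25-bp cIR-motif instances.
#' @slot plantedIrhadCount Planted IRHAD domains (three cIR instances with
#'   gaps under 75 bp).
#' @slot plantedRepeatFraction Fraction of the genome in repeat segments.
#' @slot conservedFraction Fraction of the genome in conserved segments.
#' @exportClass SimConfig
setClass("SimConfig",
    representation(seed = "integer", nChroms = "integer",
                   chromLength = "integer", nGenes = "integer",
                   nPeaksPerAssay = "integer", plantedChCount = "integer",
                   plantedSeCount = "integer", nStarrElements = "integer",
                   plantedShaeFraction = "numeric",
                   degClusterSizes = "integer", nbDispersion = "numeric",
                   librarySizes = "numeric", starrLibrarySizes = "numeric",
                   plantedHctfbs = "integer", plantedCirInstances = "integer",
                   plantedIrhadCount = "integer",
                   plantedRepeatFraction = "numeric",
                   conservedFraction = "numeric"))

setValidity("SimConfig", function(object) {
    msgs <- character(0)
    cnt <- c(object@nChroms, object@chromLength, object@nGenes,
             object@nPeaksPerAssay, object@plantedChCount,
             object@plantedSeCount, object@nStarrElements,
             object@degClusterSizes, object@plantedHctfbs,
             object@plantedCirInstances, object@plantedIrhadCount)
    if (any(cnt < 0)) msgs <- c(msgs, "all counts must be >= 0")
    fr <- c(object@plantedShaeFraction, object@plantedRepeatFraction,
            object@conservedFraction)
    if (any(fr < 0 | fr > 1)) msgs <- c(msgs, "fractions must be in [0, 1]")
    if (any(object@librarySizes <= 0) || any(object@starrLibrarySizes <= 0))
        msgs <- c(msgs, "library sizes must be positive")
    if (object@nbDispersion <= 0)
        msgs <- c(msgs, "'nbDispersion' must be positive")
    if (object@nChroms * object@chromLength < 10000)
        msgs <- c(msgs, "genome must be at least 10 kb")
    if (!all(c("CI", "CII", "CIII") %in% names(object@degClusterSizes)))
        msgs <- c(msgs, "'degClusterSizes' needs names CI, CII, CIII")
    if (!all(c("IR", "kB") %in% names(object@plantedHctfbs)))
        msgs <- c(msgs, "'plantedHctfbs' needs names IR, kB")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig: seed ", object@seed, ", ", object@nChroms, " x ",
        object@chromLength, " bp, ", object@nGenes, " genes, ",
        object@nStarrElements, " STARR elements\n", sep = "")
})

#' Build a SimConfig
#'
#' @param seed RNG seed.
#' @param nChroms,chromLength Genome geometry.
#' @param nGenes,nPeaksPerAssay,plantedChCount,plantedSeCount Feature counts.
#' @param nStarrElements,plantedShaeFraction STARR design.
#' @param degClusterSizes Named (CI, CII, CIII) planted DEG counts.
#' @param nbDispersion Negative-binomial dispersion.
#' @param librarySizes,starrLibrarySizes Per-replicate library sizes.
#' @param plantedHctfbs Named (IR, kB) planted homotypic cluster counts.
#' @param plantedCirInstances Planted isolated cIR-motif instances.
#' @param plantedIrhadCount Planted IRHAD domains.
#' @param plantedRepeatFraction,conservedFraction Genome composition.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(seed = 7, nGenes = 50)
#' @export
simConfig <- function(seed = 1L, nChroms = 3L, chromLength = 300000L,
                      nGenes = 200L, nPeaksPerAssay = 80L,
                      plantedChCount = 15L, plantedSeCount = 6L,
                      nStarrElements = 200L, plantedShaeFraction = 0.2,
                      degClusterSizes = c(CI = 10L, CII = 15L, CIII = 20L),
                      nbDispersion = 0.1,
                      librarySizes = c(1e6, 1e6, 1e6, 1e6),
                      starrLibrarySizes = c(1e6, 1e6),
                      plantedHctfbs = c(IR = 5L, kB = 5L),
                      plantedCirInstances = 8L, plantedIrhadCount = 2L,
                      plantedRepeatFraction = 0.12,
                      conservedFraction = 0.1) {
    methods::new("SimConfig", seed = as.integer(seed),
                 nChroms = as.integer(nChroms),
                 chromLength = as.integer(chromLength),
                 nGenes = as.integer(nGenes),
                 nPeaksPerAssay = as.integer(nPeaksPerAssay),
                 plantedChCount = as.integer(plantedChCount),
                 plantedSeCount = as.integer(plantedSeCount),
                 nStarrElements = as.integer(nStarrElements),
                 plantedShaeFraction = plantedShaeFraction,
                 degClusterSizes = stats::setNames(
                     as.integer(degClusterSizes), names(degClusterSizes)),
                 nbDispersion = nbDispersion,
                 librarySizes = librarySizes,
                 starrLibrarySizes = starrLibrarySizes,
                 plantedHctfbs = stats::setNames(
                     as.integer(plantedHctfbs), names(plantedHctfbs)),
                 plantedCirInstances = as.integer(plantedCirInstances),
                 plantedIrhadCount = as.integer(plantedIrhadCount),
                 plantedRepeatFraction = plantedRepeatFraction,
                 conservedFraction = conservedFraction)
}

#' @rdname simConfig
#' @param cfg A SimConfig.
#' @export
simSeqlengths <- function(cfg) {
    stats::setNames(rep(cfg@chromLength, cfg@nChroms),
                    paste0("chr", seq_len(cfg@nChroms)))
}

# realize an IUPAC consensus into a concrete sequence
.realizeConsensus <- function(consensus) {
    paste(vapply(strsplit(consensus, "")[[1]], function(code) {
        opts <- strsplit(IUPAC_EXPAND[[code]], "")[[1]]
        if (length(opts) == 1L) opts else sample(opts, 1L)
    }, character(1)), collapse = "")
}

# occupancy bookkeeping: sample a free [start, start+w-1] slot per chrom
.makeOccupancy <- function(seqlens) {
    env <- new.env(parent = emptyenv())
    env$start <- stats::setNames(
        lapply(names(seqlens), function(x) numeric(0)), names(seqlens))
    env$end <- env$start
    env$seqlens <- seqlens
    env
}

.occUsed <- function(occ) {
    grs <- lapply(names(occ$seqlens), function(chr) {
        if (!length(occ$start[[chr]])) return(NULL)
        GenomicRanges::GRanges(chr, IRanges::IRanges(occ$start[[chr]],
                                                     occ$end[[chr]]))
    })
    do.call(.concatGR, c(grs[!vapply(grs, is.null, logical(1))],
                         list(GenomicRanges::GRanges())))
}

.placeFree <- function(occ, w, margin = 10L, maxTries = 200L) {
    chroms <- names(occ$seqlens)
    for (k in seq_len(maxTries)) {
        chr <- sample(chroms, 1L)
        L <- occ$seqlens[[chr]]
        if (L < w + 2L) next
        s <- sample.int(L - w, 1L)
        e <- s + w - 1L
        clash <- any(occ$start[[chr]] <= e + margin &
                     occ$end[[chr]] >= s - margin)
        if (!clash) {
            occ$start[[chr]] <- c(occ$start[[chr]], s)
            occ$end[[chr]] <- c(occ$end[[chr]], e)
            return(GenomicRanges::GRanges(chr, IRanges::IRanges(s, e)))
        }
    }
    stop("could not place a feature of width ", w,
         "; planted features exceed genome capacity", call. = FALSE)
}

.spliceIn <- function(chromSeqs, gr, seqString) {
    chr <- as.character(GenomeInfoDb::seqnames(gr))
    s <- BiocGenerics::start(gr)
    substr(chromSeqs[[chr]], s, s + nchar(seqString) - 1L) <- seqString
    chromSeqs
}

#' Generate a synthetic genome with planted sequence features
#'
#' Background bases are i.i.d. uniform over A, C, G, T. Planted, at
#' recorded coordinates: repeat segments with RepeatMasker-style class
#' labels (tandem classes carry periodic content), cIR-motif instances
#' (realizations of the 25-bp consensus), homotypic IRF clusters (>= 3
#' perfect sites within 400 bp) and NF-kB clusters, and element windows
#' around them. Planted motifs never overlap repeat segments. A
#' piecewise-constant conservation track has mean +2.0 over a designated
#' conserved subset of segments versus mean 0.0 background.
#'
#' @param cfg A \linkS4class{SimConfig}.
#' @return List: \code{genome} (DNAStringSet), \code{cir} (GRanges of
#'   planted cIR instances), \code{hctfbsElements} (GRanges with
#'   \code{family} and \code{element_id}), \code{repeats} (GRanges with
#'   \code{source}, \code{repclass}), \code{conservation} (scored GRanges),
#'   \code{conserved} (GRanges of elevated segments), \code{ledger}.
#' @export
generateGenome <- function(cfg) {
    methods::validObject(cfg)
    set.seed(cfg@seed)
    seqlens <- simSeqlengths(cfg)
    chromSeqs <- lapply(seqlens, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = ""))
    occ <- .makeOccupancy(seqlens)

    # repeat segments
    repGr <- GenomicRanges::GRanges()
    repTarget <- cfg@plantedRepeatFraction * sum(seqlens)
    placedRep <- 0
    src <- character(0); cls <- character(0)
    while (placedRep < repTarget) {
        w <- sample(300:1200, 1L)
        klass <- sample(REPEAT_CLASSES, 1L)
        g <- .placeFree(occ, w)
        if (klass %in% c("Simple_repeat", "Satellite", "Low_complexity")) {
            unit <- paste(sample(c("A", "C", "G", "T"),
                                 sample(2:6, 1L), replace = TRUE),
                          collapse = "")
            content <- substr(strrep(unit, ceiling(w / nchar(unit))), 1L, w)
            chromSeqs <- .spliceIn(chromSeqs, g, content)
        }
        repGr <- .concatGR(repGr, g)
        src <- c(src, if (klass == "Simple_repeat" && stats::runif(1) < 0.5)
                          "TRF" else "RepeatMasker")
        cls <- c(cls, klass)
        placedRep <- placedRep + w
    }
    S4Vectors::mcols(repGr)$source <- src
    S4Vectors::mcols(repGr)$repclass <- cls

    # cIR-motif instances: isolated ones, then IRHAD domains (three
    # instances spaced by gaps strictly under 75 bp)
    cirCons <- cirMotif()@consensus
    cirW <- nchar(cirCons)
    cir <- GenomicRanges::GRanges()
    for (i in seq_len(cfg@plantedCirInstances)) {
        g <- .placeFree(occ, cirW, margin = 100L)
        chromSeqs <- .spliceIn(chromSeqs, g, .realizeConsensus(cirCons))
        cir <- .concatGR(cir, g)
    }
    irhadTruth <- GenomicRanges::GRanges()
    for (i in seq_len(cfg@plantedIrhadCount)) {
        gaps <- sample(10:60, 2L, replace = TRUE)
        span <- 3L * cirW + sum(gaps)
        dom <- .placeFree(occ, span, margin = 100L)
        off <- cumsum(c(0L, cirW + gaps))
        for (o in off) {
            g <- GenomicRanges::shift(GenomicRanges::resize(
                dom, cirW, fix = "start"), o)
            chromSeqs <- .spliceIn(chromSeqs, g, .realizeConsensus(cirCons))
            cir <- .concatGR(cir, g)
        }
        irhadTruth <- .concatGR(irhadTruth, dom)
    }

    # homotypic clusters, each inside a 1-kb element window
    hct <- GenomicRanges::GRanges()
    fam <- character(0)
    plantCluster <- function(cons, nSites, windowSpan) {
        w <- 1000L
        g <- .placeFree(occ, w, margin = 50L)
        siteW <- nchar(cons)
        gap <- (windowSpan - nSites * siteW) %/% nSites
        offs <- cumsum(c(sample(50:80, 1L),
                         rep(siteW + sample(5:max(6, gap), nSites - 1L,
                                            replace = TRUE))))
        for (o in offs[seq_len(nSites)]) {
            sub <- GenomicRanges::shift(GenomicRanges::resize(
                g, siteW, fix = "start"), o)
            chromSeqs <<- .spliceIn(chromSeqs, sub, .realizeConsensus(cons))
        }
        g
    }
    for (i in seq_len(cfg@plantedHctfbs[["IR"]])) {
        hct <- .concatGR(hct, plantCluster(irfPerfectMotif()@consensus,
                                   sample(3:5, 1L), 380L))
        fam <- c(fam, "IR")
    }
    for (i in seq_len(cfg@plantedHctfbs[["kB"]])) {
        hct <- .concatGR(hct, plantCluster(kbPerfectMotif()@consensus,
                                   sample(3:4, 1L), 380L))
        fam <- c(fam, "kB")
    }
    if (length(hct)) {
        S4Vectors::mcols(hct)$family <- fam
        S4Vectors::mcols(hct)$element_id <-
            paste0("hct_", seq_along(hct))
    }

    # piecewise-constant conservation track over 100-bp windows
    consWin <- 100L
    consTrack <- makeGenomeBins(seqlens, consWin)
    nWin <- length(consTrack)
    nCons <- round(cfg@conservedFraction * nWin)
    consIdx <- if (nCons > 0) sample.int(nWin, nCons) else integer(0)
    sc <- stats::rnorm(nWin, 0, 0.3)
    sc[consIdx] <- stats::rnorm(nCons, 2, 0.3)
    S4Vectors::mcols(consTrack)$score <- sc
    conserved <- GenomicRanges::reduce(consTrack[consIdx])

    genome <- Biostrings::DNAStringSet(unlist(chromSeqs))
    names(genome) <- names(seqlens)
    list(genome = genome, cir = BiocGenerics::sort(cir),
         irhads = BiocGenerics::sort(irhadTruth),
         hctfbsElements = BiocGenerics::sort(hct),
         repeats = BiocGenerics::sort(repGr),
         conservation = consTrack, conserved = conserved,
         ledger = list(seed = cfg@seed, n_cir = length(cir),
                       n_irhads = cfg@plantedIrhadCount,
                       n_hctfbs = length(hct),
                       hctfbs_family = fam))
}

ASSAYS <- c("DNaseI", "H3K27ac", "H3K4me3", "MED1", "CBP", "RNAPII",
            "IRF3", "p65")
CONDITIONS <- c("0h", "3h", "6h")
CH_ASSAYS <- c("DNaseI", "H3K27ac", "MED1", "RNAPII")

#' Generate synthetic multi-assay peak tracks with planted loci
#'
#' Produces peak tracks (with log-normal signal scores) for eight assays
#' across three infection time points. Planted Cis-Hotspot loci carry
#' overlapping peaks in all four CH-defining assays in the conditions
#' dictated by their temporal status (pre-printed: 0 h and 6 h;
#' newly-established: 6 h only; decommissioned: 0 h only), plus recorded
#' TF occupancy peaks at 6 h. Planted super-enhancer loci carry dense runs
#' of high-signal H3K27ac/MED1 peaks spaced well under the stitching
#' distance, with pd/pm/vi dynamics. Background peaks are placed uniformly
#' away from planted loci.
#'
#' @param cfg A \linkS4class{SimConfig}.
#' @return List: \code{peaks[[assay]][[condition]]} scored GRanges,
#'   \code{chLedger} (data.frame of planted CH loci with status and TF
#'   flags), \code{seLedger} (data.frame of planted SE spans with
#'   dynamics), \code{tss} shared with \code{generateCounts}.
#' @export
generatePeaks <- function(cfg) {
    methods::validObject(cfg)
    set.seed(cfg@seed + 1L)
    seqlens <- simSeqlengths(cfg)
    occ <- .makeOccupancy(seqlens)
    acc <- stats::setNames(lapply(ASSAYS, function(a)
        stats::setNames(lapply(CONDITIONS, function(cc) list()),
                        CONDITIONS)), ASSAYS)
    addPeak <- function(assay, cond, gr, meanlog = 3) {
        S4Vectors::mcols(gr)$score <- stats::rlnorm(length(gr), meanlog, 0.4)
        acc[[assay]][[cond]][[length(acc[[assay]][[cond]]) + 1L]] <<- gr
    }

    # planted CH loci
    nCh <- cfg@plantedChCount
    status <- rep(c("pre-printed", "newly-established", "decommissioned"),
                  length.out = nCh)
    chLoci <- GenomicRanges::GRanges()
    tfFlags <- matrix(FALSE, nCh, 3,
                      dimnames = list(NULL, c("IRF3", "p65", "CBP")))
    for (i in seq_len(nCh)) {
        locus <- .placeFree(occ, 500L, margin = 1000L)
        chLoci <- .concatGR(chLoci, locus)
        conds <- switch(status[i],
                        "pre-printed" = c("0h", "3h", "6h"),
                        "newly-established" = "6h",
                        "decommissioned" = "0h")
        for (cc in conds) for (a in CH_ASSAYS) {
            jit <- GenomicRanges::resize(locus,
                                         500L + sample(0:200, 1L),
                                         fix = "center")
            addPeak(a, cc, jit, meanlog = 4)
        }
        occFlags <- stats::runif(3) < c(0.8, 0.6, 0.5)
        tfFlags[i, ] <- occFlags
        for (tf in c("IRF3", "p65", "CBP")[occFlags])
            addPeak(tf, "6h", locus, meanlog = 4)
    }

    # planted SE loci: dense runs that must stitch into one region
    nSe <- cfg@plantedSeCount
    seDyn <- rep(c("pmSE", "viSE", "pdSE"), length.out = nSe)
    seSpans <- GenomicRanges::GRanges()
    for (i in seq_len(nSe)) {
        nPk <- sample(4:6, 1L)
        widths <- sample(800:1200, nPk, replace = TRUE)
        gaps <- sample(2000:8000, nPk - 1L, replace = TRUE)
        span <- sum(widths) + sum(gaps)
        locus <- .placeFree(occ, span, margin = 13000L)
        starts <- BiocGenerics::start(locus) +
            cumsum(c(0L, widths[-nPk] + gaps))
        run <- GenomicRanges::GRanges(
            as.character(GenomeInfoDb::seqnames(locus)),
            IRanges::IRanges(starts, width = widths))
        conds <- switch(seDyn[i], pmSE = c("0h", "6h"), viSE = "6h",
                        pdSE = "0h")
        for (cc in conds) for (a in c("H3K27ac", "MED1"))
            addPeak(a, cc, run, meanlog = 6)
        seSpans <- .concatGR(seSpans, locus)
    }

    # background peaks: uniform, rejecting overlap with planted loci, and
    # independent across assays/conditions
    planted <- .occUsed(occ)
    sampleBackground <- function(n) {
        got <- list()
        have <- 0L
        while (have < n) {
            k <- 2L * (n - have)
            w <- sample(300:800, k, replace = TRUE)
            chr <- sample(names(seqlens), k, replace = TRUE)
            s <- vapply(seq_len(k), function(i)
                sample.int(seqlens[[chr[i]]] - w[i], 1L), integer(1))
            cand <- GenomicRanges::GRanges(chr, IRanges::IRanges(s, width = w))
            cand <- cand[!.overlapsAnyQ(cand, planted, ignore.strand = TRUE)]
            got[[length(got) + 1L]] <- cand
            have <- have + length(cand)
        }
        do.call(.concatGR, got)[seq_len(n)]
    }
    for (a in ASSAYS) for (cc in CONDITIONS) {
        if (cfg@nPeaksPerAssay > 0)
            addPeak(a, cc, sampleBackground(cfg@nPeaksPerAssay), meanlog = 3)
    }
    peaks <- lapply(acc, function(byCond) lapply(byCond, function(lst)
        if (length(lst)) do.call(.concatGR, lst) else GenomicRanges::GRanges()))
    chDf <- data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(chLoci)),
        start = BiocGenerics::start(chLoci),
        end = BiocGenerics::end(chLoci),
        status = status, tfFlags)
    seDf <- data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(seSpans)),
        start = BiocGenerics::start(seSpans),
        end = BiocGenerics::end(seSpans),
        dynamics = seDyn)
    list(peaks = peaks, chLedger = chDf, seLedger = seDf)
}

#' Generate synthetic count tables with planted effects
#'
#' Gene counts follow a negative binomial with mean baseline x planted
#' fold change x library factor; planted upregulated genes carry fold
#' changes inside the C/I (>= 16), C/II ([4, 16)) and C/III ([2, 4)) gates
#' and all other genes have fold change 1. STARR element pairs follow the
#' same model across mock/infected with a planted active fraction whose
#' infected/mock ratios mirror the low/mid/high strata. Truth labels are
#' returned as ledgers.
#'
#' @param cfg A \linkS4class{SimConfig}.
#' @return List: \code{counts} (genes x 4 samples), \code{condition},
#'   \code{librarySizes}, \code{tss} (GRanges with feature_id),
#'   \code{geneLedger}, \code{starr} (list with elements GRanges,
#'   countMock, countInfected, libs), \code{starrLedger}.
#' @export
generateCounts <- function(cfg) {
    methods::validObject(cfg)
    set.seed(cfg@seed + 2L)
    seqlens <- simSeqlengths(cfg)
    nG <- cfg@nGenes
    sizes <- cfg@degClusterSizes
    nDeg <- sum(sizes)
    if (nDeg > nG) stop("more planted DEGs than genes", call. = FALSE)
    fc <- rep(1, nG)
    cluster <- rep("none", nG)
    idx <- seq_len(nDeg)
    fc[idx] <- c(stats::runif(sizes[["CI"]], 18, 30),
                 stats::runif(sizes[["CII"]], 5, 12),
                 stats::runif(sizes[["CIII"]], 2.3, 3.6))
    cluster[idx] <- rep(c("C/I", "C/II", "C/III"), sizes)
    baseline <- stats::rlnorm(nG, log(120), 0.6)
    libs <- cfg@librarySizes
    libFac <- libs / mean(libs)
    condition <- c("naive", "naive", "infected", "infected")
    size <- 1 / cfg@nbDispersion
    counts <- sapply(seq_along(condition), function(j) {
        effect <- if (condition[j] == "infected") fc else rep(1, nG)
        stats::rnbinom(nG, mu = baseline * effect * libFac[j], size = size)
    })
    geneIds <- sprintf("gene_%03d", seq_len(nG))
    rownames(counts) <- geneIds
    colnames(counts) <- paste(condition, c(1, 2, 1, 2), sep = "_")
    chroms <- sample(names(seqlens), nG, replace = TRUE)
    pos <- vapply(chroms, function(ch)
        sample.int(seqlens[[ch]] - 1L, 1L), integer(1))
    tss <- GenomicRanges::GRanges(chroms, IRanges::IRanges(pos, width = 1L))
    S4Vectors::mcols(tss)$feature_id <- geneIds

    # STARR element pairs
    nE <- cfg@nStarrElements
    nActive <- round(cfg@plantedShaeFraction * nE)
    ratio <- rep(1, nE)
    if (nActive > 0) {
        stratum <- sample(c("low", "mid", "high"), nActive, replace = TRUE,
                          prob = c(0.16, 0.828, 0.012))
        ratio[seq_len(nActive)] <- ifelse(
            stratum == "low", stats::runif(nActive, 1.6, 2),
            ifelse(stratum == "mid", stats::runif(nActive, 2.5, 8),
                   stats::runif(nActive, 10, 15)))
    }
    eW <- sample(500:1500, nE, replace = TRUE)
    eChrom <- sample(names(seqlens), nE, replace = TRUE)
    eStart <- vapply(seq_len(nE), function(i)
        sample.int(seqlens[[eChrom[i]]] - eW[i], 1L), integer(1))
    elements <- GenomicRanges::GRanges(eChrom,
                                       IRanges::IRanges(eStart, width = eW))
    S4Vectors::mcols(elements)$element_id <- sprintf("el_%04d", seq_len(nE))
    eBase <- stats::rlnorm(nE, log(100), 0.5)
    sLibs <- cfg@starrLibrarySizes
    sFac <- sLibs / mean(sLibs)
    # gamma-Poisson with the technical (plasmid-representation) factor
    # shared between the mock/infected pair of an element: each count is
    # marginally NB(mu, 1/dispersion) while the pair stays conditionally
    # Poisson, matching paired reporter libraries
    gam <- stats::rgamma(nE, shape = size, scale = 1 / size)
    countMock <- stats::rpois(nE, eBase * gam * sFac[1])
    countInfected <- stats::rpois(nE, eBase * gam * ratio * sFac[2])
    list(counts = counts, condition = condition, librarySizes = libs,
         tss = tss,
         geneLedger = data.frame(feature_id = geneIds, baseline = baseline,
                                 fc = fc, cluster = cluster),
         starr = list(elements = elements, countMock = countMock,
                      countInfected = countInfected, libs = sLibs),
         starrLedger = data.frame(element_id = sprintf("el_%04d", seq_len(nE)),
                                  baseline = eBase, ratio = ratio,
                                  active = ratio > 1))
}

#' Generate the complete synthetic study
#'
#' Runs the genome, peak and count generators under one configuration.
#' Each generator derives its stream from the configured seed, so the full
#' study is reproduced exactly by seed.
#'
#' @param cfg A \linkS4class{SimConfig}.
#' @return List with \code{genome} (from \code{generateGenome}),
#'   \code{peaks} (from \code{generatePeaks}), \code{counts} (from
#'   \code{generateCounts}) and \code{cfg}.
#' @export
simulateStudy <- function(cfg = simConfig()) {
    list(genome = generateGenome(cfg), peaks = generatePeaks(cfg),
         counts = generateCounts(cfg), cfg = cfg)
}
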