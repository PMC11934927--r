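#' Round half away from zero at a fixed precision
#'
#' Plain half-up rounding (so 45.25 prints as 45.3 at one decimal and 45 at
#' zero decimals under the conventions used for reported percentages),
#' unlike base \code{round}'s round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric; NA passes through.
#' @export
roundHalfUp <- function(x, digits = 0) {
    s <- 10^digits
    sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Summarize cohort sizes and overlaps as rounded percentages
#'
#' Given two cohort sizes and the size of their intersection, reports the
#' shared fraction of each cohort both to one decimal and to the nearest
#' integer (half-up). A missing cohort size yields NA for its fraction; a
#' zero cohort yields an explicit "undefined".
#'
#' @param nA,nB Cohort sizes (nB may be NA for one-sided summaries).
#' @param nCommon Intersection size; must not exceed either given cohort.
#' @return data.frame with counts, pct_a / pct_b (one decimal),
#'   pct_a_int / pct_b_int, and note ("" or "undefined").
#' @export
summarizeCohorts <- function(nA, nB, nCommon) {
    if (any(c(nA, nB, nCommon) < 0, na.rm = TRUE))
        stop("cohort counts must be non-negative", call. = FALSE)
    if (!is.na(nA) && !is.na(nCommon) && nCommon > nA)
        stop("intersection exceeds cohort A", call. = FALSE)
    if (!is.na(nB) && !is.na(nCommon) && nCommon > nB)
        stop("intersection exceeds cohort B", call. = FALSE)
    pct <- function(n) {
        if (is.na(n)) return(c(NA_real_, NA_real_))
        if (n == 0) return(c(NaN, NaN))
        p <- 100 * nCommon / n
        c(roundHalfUp(p, 1), roundHalfUp(p, 0))
    }
    pa <- pct(nA); pb <- pct(nB)
    note <- if ((!is.na(nA) && nA == 0) || (!is.na(nB) && nB == 0))
        "undefined" else ""
    data.frame(n_a = nA, n_b = nB, n_common = nCommon,
               pct_a = pa[1], pct_a_int = pa[2],
               pct_b = pb[1], pct_b_int = pb[2],
               note = note, stringsAsFactors = FALSE)
}

#' Run the full synthetic-study pipeline end to end
#'
#' Generates a synthetic study from \code{cfg}, runs every analysis stage
#' in dependency order (differential expression and cluster gating,
#' Cis-Hotspot mapping and dynamics, super-enhancer stitching, ranking and
#' dynamics, SHAe calling, element localization, homotypic cluster calling
#' on planted elements, genome scanning with the cIR motif plus IRHAD
#' mapping, repeatome and conservation classification, and the proximity
#' resampling test), and writes per-stage BED/TSV artifacts plus a JSON
#' summary and run log to \code{outdir}. Reruns with the same config are
#' identical.
#'
#' @param cfg A \linkS4class{SimConfig}.
#' @param outdir Output directory (created if missing); NULL for no files.
#' @param proximityReps Repetitions of the resampling test (reduced from
#'   the full 10000 by default to keep the run light).
#' @return Invisibly, a list of all stage results plus \code{summary}.
#' @export
runPipeline <- function(cfg = simConfig(), outdir = NULL,
                        proximityReps = 500L) {
    sim <- simulateStudy(cfg)
    seqlens <- simSeqlengths(cfg)

    degs <- gateClusters(callDegs(sim$counts$counts, sim$counts$condition,
                                  sim$counts$librarySizes,
                                  levels = c("naive", "infected")))
    tracksAt <- function(cond) lapply(sim$peaks$peaks, `[[`, cond)
    ch0 <- mapCisHotspots(tracksAt("0h"))
    ch6 <- mapCisHotspots(tracksAt("6h"),
                          tfTracks = list(IRF3 = sim$peaks$peaks$IRF3$`6h`,
                                          p65 = sim$peaks$peaks$p65$`6h`,
                                          CBP = sim$peaks$peaks$CBP$`6h`),
                          tss = sim$counts$tss)
    chDyn <- classifyChDynamics(ch0, ch6)
    roseAt <- function(cond) stitchAndRank(
        sim$peaks$peaks$H3K27ac[[cond]], sim$peaks$peaks$H3K27ac[[cond]],
        tss = sim$counts$tss)
    rose0 <- roseAt("0h"); rose6 <- roseAt("6h")
    seDyn <- classifySeDynamics(rose0[rose0$is_se], rose6[rose6$is_se])
    shae <- callShae(sim$counts$starr$countMock,
                     sim$counts$starr$countInfected,
                     elements = sim$counts$starr$elements,
                     libMock = sim$counts$starr$libs[1],
                     libInfected = sim$counts$starr$libs[2])
    shaeGr <- sim$counts$starr$elements[shae$is_shae]
    local6 <- localizeElements(shaeGr, rose6[rose6$is_se], rose6[!rose6$is_se])

    hctCalls <- lapply(seq_along(sim$genome$hctfbsElements), function(i) {
        el <- sim$genome$hctfbsElements[i]
        seq <- Biostrings::subseq(
            sim$genome$genome[[as.character(GenomeInfoDb::seqnames(el))]],
            BiocGenerics::start(el), BiocGenerics::end(el))
        ir <- callIrHctfbs(seq, irfPerfectMotif())
        if (!is.null(ir)) return(ir$family)
        kb <- callKbHctfbs(seq, kbPerfectMotif())
        if (!is.null(kb) && isTRUE(kb$is_call)) return(kb$family)
        "none"
    })
    scan <- scanGenomeCoverage(sim$genome$genome)
    irhads <- mapIrhads(scan$instances)

    repClass <- if (length(shaeGr))
        classifyRepeatome(shaeGr, sim$genome$repeats) else character(0)
    phylop <- if (length(shaeGr))
        averagePhylop(shaeGr, sim$genome$conservation) else numeric(0)

    bgPool <- makeBackgroundPool(
        seqlens, exclude = list(sim$counts$starr$elements))
    upTss <- sim$counts$tss[degs$direction == "up"]
    prox <- if (length(shaeGr) && length(upTss))
        proximityResamplingTest(shaeGr, upTss, bgPool,
                                nReps = proximityReps, seed = cfg@seed)
    else NULL

    summary <- list(
        seed = cfg@seed,
        n_degs_up = sum(degs$direction == "up"),
        n_ch_0h = length(ch0), n_ch_6h = length(ch6),
        n_se_6h = sum(rose6$is_se), n_te_6h = sum(!rose6$is_se),
        n_shae = sum(shae$is_shae),
        localization = as.list(table(local6)),
        n_hctfbs_called = sum(unlist(hctCalls) != "none"),
        cir_coverage_pct = scan$coverage_pct,
        n_irhads = length(irhads),
        proximity_binom_p = if (is.null(prox)) NA else prox$binom_p)
    res <- list(sim = sim, degs = degs, ch0h = chDyn$ch0h, ch6h = chDyn$ch6h,
                rose0h = rose0, rose6h = rose6, seDynamics = seDyn,
                shae = shae, localization = local6, hctfbs = hctCalls,
                cirScan = scan, irhads = irhads, repeatome = repClass,
                phylop = phylop, proximity = prox, summary = summary)

    if (!is.null(outdir)) {
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        utils::write.table(degs, file.path(outdir, "degs.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(shae, file.path(outdir, "shae.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        writeBed(GenomicRanges::granges(chDyn$ch6h),
                 file.path(outdir, "cis_hotspots_6h.bed"))
        writeBed(GenomicRanges::granges(rose6[rose6$is_se]),
                 file.path(outdir, "superenhancers_6h.bed"))
        writeBed(GenomicRanges::granges(irhads),
                 file.path(outdir, "irhads.bed"))
        jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        writeLines(c(paste("vrcrm pipeline, seed", cfg@seed),
                     paste(names(summary),
                           vapply(summary, function(x)
                               paste(format(unlist(x)), collapse = ","),
                               character(1)),
                           sep = ": ")),
                   file.path(outdir, "run.log"))
    }
    invisible(res)
}
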