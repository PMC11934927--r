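REPEAT_CLASSES <- c("Simple_repeat", "Low_complexity", "LINE", "SINE",
                    "LTR", "DNA", "Satellite")
TR_CLASSES <- c("Simple_repeat", "Low_complexity", "Satellite")
DR_CLASSES <- c("LINE", "SINE", "LTR", "DNA")

#' Classify elements by repeat composition
#'
#' Overlap (>= 1 bp) with a Tandem Repeats Finder record, or with a
#' RepeatMasker simple repeat, low-complexity or satellite record, is
#' tandem-repeat (TR) evidence; overlap with a transposon class (LINE,
#' SINE, LTR, DNA) is dispersed-repeat (DR) evidence. Elements with both
#' kinds of evidence are hybrids, c(T:D)R; with neither, nonrepetitive.
#' Labels are exhaustive and mutually exclusive.
#'
#' @param elements GRanges of elements.
#' @param annotations GRanges of repeat records with metadata columns
#'   \code{source} (\code{"TRF"} or \code{"RepeatMasker"}) and
#'   \code{repclass} (controlled vocabulary; may be NA for TRF records).
#' @return Character vector in \{TR, DR, c(T:D)R, nonrepetitive\} parallel
#'   to \code{elements}.
#' @export
classifyRepeatome <- function(elements, annotations) {
    .checkGRanges(elements)
    .checkGRanges(annotations)
    src <- S4Vectors::mcols(annotations)$source
    cls <- S4Vectors::mcols(annotations)$repclass
    rm <- is.na(src) | src != "TRF"
    unknown <- unique(cls[rm & !is.na(cls) & !(cls %in% REPEAT_CLASSES)])
    if (length(unknown))
        stop("unknown repeat class(es): ", paste(unknown, collapse = ", "),
             call. = FALSE)
    trAnn <- annotations[(!rm) | (!is.na(cls) & cls %in% TR_CLASSES)]
    drAnn <- annotations[rm & !is.na(cls) & cls %in% DR_CLASSES]
    tr <- .overlapsAnyQ(elements, trAnn, ignore.strand = TRUE)
    dr <- .overlapsAnyQ(elements, drAnn, ignore.strand = TRUE)
    ifelse(tr & dr, "c(T:D)R",
           ifelse(tr, "TR", ifelse(dr, "DR", "nonrepetitive")))
}

#' Length-scaled mean conservation score of elements
#'
#' Each element is rescaled to \code{nBins} equal-width bins by linear
#' coordinate scaling (the scale-regions idea with 1-bp bins at 500-bp
#' body length); each bin's value is the exact length-weighted mean of the
#' per-base scores it covers (uncovered bases score 0), and the element
#' score is the mean over bins. For a constant track this equals the
#' constant for every element length.
#'
#' @param elements GRanges.
#' @param track GRanges with a numeric \code{score} column (bedGraph
#'   semantics, non-overlapping).
#' @param nBins Number of scaled bins (default 500).
#' @return Numeric vector of element means.
#' @export
averagePhylop <- function(elements, track, nBins = 500L) {
    .checkGRanges(elements)
    .checkGRanges(track)
    cov <- GenomicRanges::coverage(track, weight = "score")
    chroms <- as.character(GenomeInfoDb::seqnames(elements))
    vapply(seq_along(elements), function(i) {
        L <- BiocGenerics::width(elements)[i]
        vals <- numeric(L)
        if (chroms[i] %in% names(cov)) {
            r <- cov[[chroms[i]]]
            lo <- max(BiocGenerics::start(elements)[i], 1L)
            hi <- min(BiocGenerics::end(elements)[i], length(r))
            if (hi >= lo)
                vals[(lo - BiocGenerics::start(elements)[i] + 1L):
                     (hi - BiocGenerics::start(elements)[i] + 1L)] <-
                    as.numeric(S4Vectors::window(r, lo, hi))
        }
        # exact fractional-base integration of each scaled bin
        cs <- c(0, cumsum(vals))
        integral <- function(a, b) {  # continuous coords in [0, L]
            ia <- floor(a); ib <- floor(b)
            if (ia == ib) return(vals[ia + 1L] * (b - a))
            cs[ib + 1L] - cs[ia + 1L] - vals[ia + 1L] * (a - ia) +
                (if (ib < L) vals[ib + 1L] * (b - ib) else 0)
        }
        edges <- seq(0, L, length.out = nBins + 1L)
        binw <- L / nBins
        mean(vapply(seq_len(nBins), function(b)
            integral(edges[b], edges[b + 1L]) / binw, numeric(1)))
    }, numeric(1))
}

#' Default species-to-clade groups for evolutionary gating
#'
#' Maps species names to the clades the gate cascade distinguishes:
#' \code{hominidae} (human and great apes), \code{primate} (other
#' primates), \code{mammal} (non-primate mammals) and \code{beyond}
#' (non-mammal vertebrates). Group membership is configuration data and
#' can be replaced wholesale.
#'
#' @return Named character vector: species -> group.
#' @export
defaultSpeciesGroups <- function() {
    c(human = "hominidae", chimpanzee = "hominidae", gorilla = "hominidae",
      orangutan = "hominidae",
      rhesus = "primate", marmoset = "primate", lemur = "primate",
      mouse = "mammal", rat = "mammal", dog = "mammal", cow = "mammal",
      elephant = "mammal",
      chicken = "beyond", lizard = "beyond", frog = "beyond",
      zebrafish = "beyond", lamprey = "beyond")
}

#' Gate an element's evolutionary class from per-species conservation
#'
#' A species "hits" when its conserved-sequence length strictly exceeds
#' \code{minConservedLen} bp and its similarity strictly exceeds
#' \code{minSimilarity} percent. The gate cascade is monotone towards
#' deeper clades: any non-mammal hit gives b-mammals; otherwise any
#' non-primate mammal hit gives e-mammals; otherwise any primate hit
#' beyond the great apes gives e-primates; hits confined to human and
#' great apes (or no hits at all) give HHPe-primates.
#'
#' @param species Character vector of species with conservation records.
#' @param conservedLen Numeric vector, conserved length per species (bp).
#' @param similarity Numeric vector, similarity percent per species.
#' @param groups Named species -> group map (see
#'   \code{defaultSpeciesGroups}).
#' @param minConservedLen,minSimilarity Strict gate thresholds (defaults
#'   100 bp, 60 percent).
#' @return One of "b-mammals", "e-mammals", "e-primates", "HHPe-primates".
#' @export
gateEvolutionaryClass <- function(species, conservedLen, similarity,
                                  groups = defaultSpeciesGroups(),
                                  minConservedLen = 100, minSimilarity = 60) {
    species <- as.character(species)
    unknown <- setdiff(species, names(groups))
    if (length(unknown))
        stop("species missing a group assignment: ",
             paste(unknown, collapse = ", "), call. = FALSE)
    hit <- conservedLen > minConservedLen & similarity > minSimilarity
    g <- groups[species[hit]]
    if (any(g == "beyond")) return("b-mammals")
    if (any(g == "mammal")) return("e-mammals")
    if (any(g == "primate")) return("e-primates")
    "HHPe-primates"
}
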