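---
title: "Methods and design of the vrcrm pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the vrcrm pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vrcrm)
```

# Scope

`vrcrm` assembles the computational chain used to map and classify
virus-responsive cis-regulatory modules: multi-assay peak intersection
(Cis-Hotspots), ROSE-style super-enhancer calling with temporal dynamics,
STARR-reporter activation calling, differential-expression gating,
homotypic transcription-factor binding-site cluster (HCTFBS) discovery,
genome-wide consensus scanning with domain aggregation, resampling
proximity statistics, and repeat/conservation classification. All
interval work rides on `GenomicRanges`; all sequence work on
`Biostrings`. This vignette explains the statistical models, the
parameters that matter, the numerical choices, and what the synthetic
data generator does and does not emulate.

# Coordinate conventions

Internally every interval is a 1-based closed `GRanges`; BED and bedGraph
files (0-based half-open) are converted at the I/O boundary by
`rtracklayer`. Two gap conventions coexist deliberately:

* `mergeIntervals(x, maxGap)` merges at **gap ≤ maxGap** (merge at
  equality). This is the stitching primitive: ROSE's 12.5-kb stitching
  distance is "peaks this close belong together".
* `clusterIntervals(x, maxGap, minCount)` breaks a run at **gap ≥
  maxGap** (strictly less than `maxGap` keeps the run). This mirrors the
  IRHAD selection criterion of at least three motif instances spaced by
  *less than* 75 bp. Clusters are the connected components of the
  strict-gap relation; with nested intervals the running maximum end
  defines the gap, which makes clustering identical to a union-closure
  merge at `maxGap - 1` on integer coordinates — the property the test
  oracle exploits.

Strand is carried but ignored by all interval algebra; only motif
operations consume it. Ties in `nearestDistance` resolve to the leftmost
reference for determinism, and queries on chromosomes without any
reference get `NA` ("unreachable") rather than a fake large number.

# Differential expression and responsiveness gates

The expression model is intentionally assumption-light. Counts are
normalized by library size (scaled to the mean library so values stay on
count scale) and averaged over replicates per condition; the fold change
is the ratio of condition means. A pseudocount of 0.5 per condition is
applied **only when a condition mean is zero**: ratios of strictly
positive means stay exact (40/10 is 4, not 40.5/10.5), while zeros stay
finite. Significance is an exact conditional binomial rate-ratio test:
conditional on a feature's total count, the infected sum is Binomial with
success probability equal to the infected library share, which removes
the nuisance baseline exactly. P-values are BH-adjusted across features;
an up-call needs fold change ≥ 2 (inclusive) and adjusted p < 0.05; both
raw and adjusted p-values are reported because printed gate conventions
vary. Upregulated calls are gated into C/I (FC ≥ 16), C/II (4 ≤ FC < 16)
and C/III (2 ≤ FC < 4) — a partition of [2, ∞) with inclusive lower
bounds, property-checked on a grid in the tests. Transposable-element
copy tables reuse the same caller at FC ≥ 1.4; TMM normalization is
deliberately replaced by library-size normalization, since the caller
only consumes relative rates and multimapper-aware quantification is out
of scope.

The conditional binomial assumes counts are conditionally Poisson given
the feature's expected rate. Between-replicate biological overdispersion
makes it anti-conservative for features near the fold-change gate; the
FC ≥ 2 gate is what controls the realized false-positive rate, which the
calibration tests measure directly (≈ 2% at the default dispersion of
0.1, under the nominal 5%).

# STARR activation calling

SHAe calling follows the "unnormalized counts" convention: the fold
change is raw infected/mock per element (a zero mock count is replaced by
a pseudocount of 1 and flagged), the test is the same exact conditional
binomial against the infected library share, and the raw p-value is gated
(BH adjustment is available but off by default). The gate is FC ≥ 1.44
(inclusive) with p < 0.05; called elements are stratified into
low [1.4, 2), mid [2, 10) and high [10, ∞). The stratum floor of 1.4 and
the call gate of 1.44 are both honored as printed; the discrepancy is an
upstream convention, not resolved here.

For calibration, the generator draws each element's technical
(plasmid-representation) factor once from a Gamma with unit mean and
shares it between the mock and infected draw, so each count is marginally
negative binomial while the pair stays conditionally Poisson. This is the
natural model for paired reporter libraries — both conditions read out
the same plasmid pool — and it is what makes the conditional binomial
exactly calibrated under the null, which the 200-seed calibration suite
verifies.

# Cis-Hotspots and signal matrices

A Cis-Hotspot is the base-level intersection of the DNaseI, H3K27ac, MED1
and RNA pol II peak tracks of one condition. The published description of
"hierarchical, sequential" intersection is realized as order-independent
base-level intersection: sequential pairwise intersection of covered
bases gives the same result in any order, so the layering is
presentational. TF occupancy (IRF3, p65, CBP) is a ≥ 1 bp overlap flag.
Temporal status compares conditions at ≥ 1 bp overlap (configurable):
6-h hotspots split into pre-printed versus newly established, and 0-h
hotspots with no 6-h partner are decommissioned.

`signalMatrix` reproduces reference-point signal matrices: per reference
point, the score-weighted coverage of a (non-overlapping, pre-normalized)
track is averaged in fixed-size bins across ± 2 kb, with zeros where the
track is silent and where windows run off the chromosome. TSS matrices
anchor at the annotated TSS base.

# Super-enhancers

`stitchAndRank` follows the ROSE parameterization: peaks fully contained
in TSS ± 2 kb are excluded before stitching (an excluded peak that lands
inside a final stitched region is implicitly recovered because signal is
integrated over the whole region span); surviving peaks merge at gap ≤
12.5 kb; each region's signal is the sum over its bases of marker minus
input coverage, floored at zero and divided by a nominal scale factor
(read-level RPM bookkeeping is out of scope — scores arrive
pre-normalized). Regions are ranked ascending. The super-enhancer cutoff
is the inflection point of the scaled rank curve: with ranks mapped to
(0, 1] and signals min-max scaled to [0, 1], the cutoff is the first rank
where the finite-difference slope exceeds 1, and regions above it are
SEs. On the analytic curve y = x² the slope-1 tangent sits at x = 0.5, so
exactly half the regions are flagged — the closed-form check in the test
suite. Flat curves yield no SEs; single-region inputs are treated the
same way.

SE dynamics at ≥ 1 bp overlap give pdSE (0 h only), pmSE (both, counted
once on 6-h coordinates) and viSE (6 h only) — a partition of the union
of both SE sets. Gene assignment scans bidirectionally ± 0.5 Mb from the
SE center and requires replicate-average normalized expression ≥ 10
(inclusive). Element localization gives SE priority over tE, with safG
(stand-alone functional genomic stretch) as the exhaustive remainder.

# Motif models and homotypic clusters

`MotifModel` holds either an IUPAC consensus (exact degenerate-code
matching; an N in the *subject* matches only the code N, so ambiguous
bases never inflate hits) or a JASPAR-style position frequency matrix
scanned as a log2-odds PWM against a uniform background. The default PWM
threshold is the score whose tail probability under the uniform
background is 10⁻⁵, computed *exactly* by dynamic programming over the
per-column score distributions on scores discretized to 10⁻³ — exhaustive
sequence enumeration would be needless even for short motifs, since the
DP is exact up to discretization. Both strands are scanned by default;
minus-strand hits are reported in plus coordinates. Nonoverlap is
resolved greedily left to right, then by higher score, then by plus
strand — a deterministic convention.

HCTFBS grammars follow the printed rules. IR family: a core call needs
≥ 3 nonoverlapping perfect IRF3/IRF1 sites whose span (first matched base
to last) is ≤ 400 bp; failing that, a half-site call needs **more than
10** nonoverlapping AAAG half sites within ≤ 1000 bp (the "10–43 within
1 kb" phrasing elsewhere is the observed range, so the strict > 10 gate
is implemented and both knobs are arguments). κB family: rule (i) is the
same ≥ 3-perfect-sites-in-400-bp core; rule (ii) accepts 4–14
nonoverlapping degenerate GGGNNNNNCC sites (both strands) within
≤ 1300 bp, where the densest qualifying window defines the count — a
window holding more than 14 is reported out-of-range and does not call,
treating the printed 4–14 as a hard range. GGRR half sites are counted
and reported but never trigger a call, since no count threshold is
printed for them. Note the degenerate pattern fixes only five bases, so
rule (ii) fires on roughly a fifth of random 1.5-kb windows; it is a
cohort annotation channel, not a de-novo detector, and the planted-truth
recovery suite therefore scores each synthetic cohort with its own family
grammar on core-grade calls.

Syntax labels come from consecutive site pairs ordered by position: same
strand is Head-to-Tail, plus-then-minus faces the 5'→3' directions
together (Head-to-Head), minus-then-plus points them apart
(Tail-to-Tail); the element label is the pair majority, "mixed" on ties,
"n/a" below two sites.

Genome scanning uses the 25-bp clustered-IRF3 consensus
`RRAARGGAAAGGAAAGGAAAGGAAA` and reports coverage as
100 · instances · 25 / genome length; IRHAD domains are
`clusterIntervals` at < 75 bp gaps and ≥ 3 members. Cluster windows are
measured in plus-strand coordinates irrespective of hit strand.

# Resampling proximity and overlap statistics

The proximity test asks whether foreground elements sit closer to a TSS
catalog than random genomic background. The background pool is the
genome tiled into 300-bp bins minus the blacklist, the foreground and any
supplied peak sets. Each of `nReps` (10 000 by default; tests and the
acceptance script use 300–1000) repetitions samples `|fg|` pool bins
**without replacement** (the sampling scheme is a configurable choice; a
pool orders of magnitude larger than the foreground makes the distinction
immaterial) and compares foreground versus sampled distances with a
two-sided rank-sum test — exact for untied samples of ≤ 20, otherwise
normal approximation with tie and continuity correction, for speed at
10⁴ repetitions. A repetition with p ≤ 0.05 is a success, and the
reported statistic is the exact binomial tail P(X ≥ successes | n, 0.5),
one-sided toward enrichment. Cumulative distance curves over the first
10 kb are emitted for the foreground and the pool-wide expectation.

`fisherOverlap` classifies genome bins by overlap with each of two sets
and applies the exact two-tailed Fisher test; the odds ratio is the
sample cross-product with the Haldane 0.5 correction when a cell is
empty. `windowHits` counts features within a flank (inclusive at the
boundary base, distance 0 meaning overlap) and supports doubling flank
schedules; counts are monotone in the flank by construction.

# Repeats and evolutionary gates

Repeat composition: overlap (≥ 1 bp) with a TRF record or a RepeatMasker
simple repeat, low-complexity or satellite record is tandem-repeat
evidence; overlap with LINE/SINE/LTR/DNA transposon classes is
dispersed-repeat evidence; both gives the hybrid class c(T:D)R, neither
gives nonrepetitive. Satellites count as tandem evidence because
satellite records are tallied inside the tandem-repeat cohort in the
study design this follows. Unknown class labels are an error that names
the offending class.

Conservation averaging rescales each element to 500 equal bins (the
scale-regions idea with a 500-bp body and 1-bp bins) and averages exact
fractional-base integrals per bin; with equal-width bins the mean of bin
means equals the plain length-weighted mean, which makes the constant
track invariance exact at every element length — the analytic check in
the tests. Uncovered bases contribute zero.

The evolutionary gate takes per-species records (conserved length,
similarity) as *inputs* — multi-genome alignment is out of scope, and on
synthetic data the similarity comes from the generator's ledger. A
species hits when conserved length > 100 bp **and** similarity > 60 %
(both strict). The cascade is monotone toward deeper clades: any
non-mammal hit → b-mammals; else any non-primate mammal → e-mammals;
else any primate hit beyond the great apes → e-primates; else (hits
confined to Hominidae, or none) → HHPe-primates. The boundary between
e-primates and HHPe-primates is descriptive in its source, so Hominidae
membership is configuration data (`defaultSpeciesGroups()`), not code.

# The synthetic study

`simConfig()` fixes the study conditions: a 3 × 300-kb genome, 200 genes
(2 conditions × 2 replicates), 8 assays × 3 time points with 80
background peaks each, 15 Cis-Hotspot loci split across temporal classes,
6 super-enhancer loci split across pd/pm/vi, 200 STARR elements with a
20 % active fraction whose infected/mock ratios mirror the low/mid/high
strata proportions (16 % / 82.8 % / 1.2 %), planted DEG clusters of
10/15/20 genes with fold changes drawn inside the C/I–III gates,
negative-binomial counts at dispersion 0.1, 5 + 5 homotypic clusters, 8
isolated cIR instances plus 2 IRHAD domains, 12 % repeat content and a
10 % conserved fraction whose track mean is +2.0 against a 0.0
background. These sizes are a deliberately compact study that still
drives every stage; nothing in the defaults was tuned to any particular
test outcome, and the generators are byte-deterministic under a fixed
seed.

What the generator does **not** emulate: read-level data (FASTQ,
alignment, peak calling), fragment-size effects, chromatin-state
autocorrelation along the genome, GC or mappability bias, multimapping
transposon quantification, and real multi-species alignment. Passing
tests therefore demonstrate correctness of the *computational chain* and
calibration of its statistics under the generator's assumptions — not
performance on raw sequencing data.

Planted motifs are placed outside repeat segments so class labels stay
unambiguous; isolated cIR instances are spaced > 75 bp apart so they can
never form spurious IRHADs; Cis-Hotspot and SE loci are placed with
margins (1 kb and 13 kb) that keep planted loci from merging with each
other or with background peaks.

# Numerical choices and problem sizes

Degenerate inputs are defined, not accidental: empty interval sets pass
through every operation; a query chromosome without references yields the
`NA` sentinel; a flat rank curve yields no super-enhancers; a feature
with zero total count gets p = 1; division by a zero cohort is reported
as "undefined". Percent rounding is half-up at the reported precision
(`roundHalfUp`), matching the usual convention for printed percentages.

The test suite and `scripts/acceptance.R` use reduced Monte-Carlo sizes
chosen so each estimate's standard error is far below the margin being
asserted: 200-seed calibrations at 100 features per seed (null
false-positive rates), 200-seed recovery runs at 40–60 features, 100-seed
(tests) / 40-seed (script) homotypic-cluster runs on 40-kb genomes, and
50 × 1000-repetition (tests) / 30 × 500 (script) proximity-null runs.
The oracle comparisons (brute-force merge/intersect/cluster, regex
scanning, hypergeometric enumeration, binomial summation) are exact, not
statistical.

# Known limitations

* The DEG test ignores between-replicate overdispersion (see above); for
  real RNA-seq a shrinkage-based NB model is the better tool, and the
  package's contribution is the gating chain around the test, which is
  test-agnostic.
* ROSE signal is integrated from pre-normalized score tracks; BAM-level
  read counting and input scaling are out of scope.
* The κB degenerate-site rule is permissive on random sequence by
  construction; interpret it only within pre-selected element cohorts.
* The evolutionary gate consumes per-species conservation summaries; it
  does not compute alignments or similarity itself.
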