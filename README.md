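# vrcrm

Discovery and classification of **virus-responsive cis-regulatory modules
(vrCRMs)** from multi-omics assays of virus-infected cells.

When a cell senses a virus, transcription factors of the IRF and NF-κB
families converge on a genome-wide repertoire of enhancers that switch on
the antiviral transcriptome. Characterizing that repertoire requires a
chain of bespoke computational steps that are usually scattered across
shell scripts and external tools: intersecting peak tracks from many
assays, stitching enhancers and splitting super-enhancers from typical
enhancers, calling functionally activated elements from paired episomal
reporter (STARR-seq) counts, detecting homotypic clusters of IRF/NF-κB
binding sites in element sequences, testing whether elements crowd around
induced genes, and classifying elements by repeat content and evolutionary
depth. `vrcrm` implements that chain as one tested, seed-reproducible R
package built on `GenomicRanges` and `Biostrings`, together with a
synthetic-data generator that emulates every required input so the whole
pipeline can be exercised — and its error rates measured — without any
sequencing data.

## What the package computes

* **Interval algebra** (`mergeIntervals`, `intersectMulti`,
  `nearestDistance`, `clusterIntervals`): BED-convention genomic interval
  operations, including the strict-gap clustering used for IRHAD domains
  (≥ 3 motif instances with consecutive gaps < 75 bp).
* **Differential expression gates** (`callDegs`, `gateClusters`):
  virus-responsive DEGs at FC ≥ 2, *P* < 0.05 (exact conditional binomial
  rate-ratio test, BH-adjusted), gated into responsiveness clusters
  C/I (FC ≥ 16), C/II (4 ≤ FC < 16) and C/III (2 ≤ FC < 4). The same
  caller covers transposable-element copy tables at FC ≥ 1.4.
* **Cis-Hotspots** (`mapCisHotspots`, `classifyChDynamics`,
  `signalMatrix`): loci co-occupied by DNaseI, H3K27ac, MED1 and RNA pol II
  (base-level four-way intersection), their temporal status
  (pre-printed / newly established / decommissioned), and
  computeMatrix-style reference-point signal matrices (± 2 kb).
* **Super-enhancers** (`stitchAndRank`, `seCutoff`, `classifySeDynamics`,
  `assignSeGenes`, `localizeElements`): ROSE-parameterized stitching
  (12.5 kb, TSS ± 2 kb exclusion), ranking by marker − input signal, SE/tE
  split at the slope-1 inflection point of the scaled rank curve, pd/pm/vi
  dynamics across infection, gene assignment within ± 0.5 Mb of the SE
  center for genes with mean normalized expression ≥ 10, and localization
  of elements into SEs, tEs or stand-alone stretches (safGs).
* **STARR-activated elements** (`callShae`, `intersectCohorts`): SHAe at
  FC ≥ 1.44 on unnormalized infected/mock counts with an exact binomial
  *P* < 0.05, stratified into 1.4 ≤ FC < 2, 2 ≤ FC < 10 and FC ≥ 10, and
  cohort intersection summaries.
* **Homotypic TFBS clusters** (`scanMotif`, `callIrHctfbs`,
  `callKbHctfbs`, `classifySyntax`, `scanGenomeCoverage`, `mapIrhads`):
  IUPAC-consensus and PWM log-odds scanning (threshold at tail
  probability 10⁻⁵ under a uniform background, computed exactly by dynamic
  programming); IR-HCTFBS calls (≥ 3 perfect sites within 400 bp, or > 10
  AAAG half sites within 1 kb), κBR-HCTFBS calls (≥ 3 perfect sites within
  400 bp, or 4–14 degenerate GGGNNNNNCC sites within 1.3 kb);
  Head-to-Tail / Head-to-Head syntax labels; genome scanning with the
  25-bp clustered-IRF3 consensus `RRAARGGAAAGGAAAGGAAAGGAAA` with percent
  coverage `100 · n · 25 / L`; and IRHAD mapping.
* **Proximity and overlap statistics** (`proximityResamplingTest`,
  `fisherOverlap`, `windowHits`): the resampling-binomial proximity test
  (300-bp genome bins minus blacklist/foreground, equal-size resampling,
  per-repetition rank-sum success at *p* ≤ 0.05, exact binomial tail
  against 0.5), two-tailed Fisher overlap tests on genome bins, and
  windowed variant scans (± 2.5 kb, doubling schedules).
* **Repeats and evolution** (`classifyRepeatome`, `averagePhylop`,
  `gateEvolutionaryClass`): TR / DR / c(T:D)R / nonrepetitive composition
  from TRF and RepeatMasker annotations; phyloP averaging after scaling
  each element to 500 bins; and the conservation gate cascade
  (conserved length > 100 bp and similarity > 60 %) into HHPe-primates,
  e-primates, e-mammals and b-mammals.
* **Synthetic data** (`simConfig`, `generateGenome`, `generatePeaks`,
  `generateCounts`, `simulateStudy`) and an end-to-end driver
  (`runPipeline`, `summarizeCohorts`).

## Worked example

```r
library(vrcrm)

cfg <- simConfig(seed = 42)        # 3 x 300 kb genome, 200 genes, planted truth
res <- runPipeline(cfg, proximityReps = 200)
str(res$summary)
```

```
List of 12
 $ seed             : int 42
 $ n_degs_up        : int 48
 $ n_ch_0h          : int 10
 $ n_ch_6h          : int 10
 $ n_se_6h          : int 6
 $ n_te_6h          : int 18
 $ n_shae           : int 41
 $ localization     :List of 3
  ..$ safG: int 36
  ..$ SE  : int 3
  ..$ tE  : int 2
 $ n_hctfbs_called  : int 10
 $ cir_coverage_pct : num 0.0389
 $ n_irhads         : int 2
 $ proximity_binom_p: num 1
```

The configuration planted 45 upregulated genes (48 called, i.e. 45 true
positives plus a handful of borderline calls), 15 Cis-Hotspot loci split
across temporal classes (10 present at each time point), 6 super-enhancer
loci (all recovered, 2 of them decommissioned by 6 h), 40 active STARR
elements (41 called), 10 homotypic clusters (all 10 called) and 2 IRHAD
domains (both mapped). The proximity test is correctly non-significant
because the synthetic STARR elements are placed independently of TSSs.

Cohort arithmetic on reported cohort sizes:

```r
summarizeCohorts(1949, 1601, 219)
#>    n_a  n_b n_common pct_a pct_a_int pct_b pct_b_int note
#> 1 1949 1601      219  11.2        11  13.7        14
```

219 elements shared between a 1949-element and a 1601-element cohort are
11.2 % of the first and 13.7 % of the second (half-up rounding at one
decimal and at integer precision).

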