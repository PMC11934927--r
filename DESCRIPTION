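Package: vrcrm
Title: Discovery and Classification of Virus-Responsive Cis-Regulatory Modules
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping and classifying virus-responsive cis-regulatory
    modules from multi-omics assays of infected cells. Implements Cis-Hotspot
    mapping by multi-assay peak intersection, ROSE-style super-enhancer
    stitching and inflection-point calling with temporal dynamics, calling of
    STARR-highly-activated elements from paired reporter counts, differential
    expression gating into responsiveness clusters, homotypic transcription
    factor binding site cluster (HCTFBS) discovery for IRF and NF-kB grammars,
    genome scanning with a clustered-IRF3 consensus and IRHAD domain mapping,
    resampling-based proximity enrichment statistics, repeat-class and
    conservation-based evolutionary classification, and a fully deterministic
    synthetic data generator that emulates every required input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
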