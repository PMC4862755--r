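Package: subthresh
Title: Sub-Threshold GWAS Locus Discovery with Epigenomic Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for prioritizing genome-wide association study (GWAS)
    signals that fall below genome-wide significance by integrating
    epigenomic annotations. Implements matched-control permutation
    enrichment of trait loci in enhancer annotations, LD-based locus
    construction and pruning, sliding-threshold sub-threshold enrichment
    curves, enhancer feature comparisons (signal density, cross-tissue
    activity, tissue-specific methylation calls, conservation),
    cross-tissue enhancer-gene linking by one-sided rank tests, allelic
    imbalance binomial testing, 4C-seq interaction calling via isotonic
    background regression, exact 2x2 and binomial evidence statistics,
    and non-centrality-based power projections. Ships a synthetic-data
    generator that emulates the statistical structure of the required
    inputs so the full workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
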