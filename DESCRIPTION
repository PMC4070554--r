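Package: mlcqtl
Title: Multiple-Line Cross QTL Mapping for Dynamic Traits in Multi-Family
    Doubled Haploid Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint ("disconnected") multiple-line cross QTL mapping for
    populations of doubled haploid families: simulation of multi-family DH
    populations on a linkage map, balanced variance components and entry-mean
    heritability, composite interval mapping with family-specific QTL and
    cofactor effects, permutation-based genome-wide LOD thresholds, LOD
    fall-off support intervals, proportion of genotypic variance explained,
    fivefold cross-validation with relative-bias estimation, and a full
    two-dimensional epistasis scan with region-based multiplicity correction.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
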