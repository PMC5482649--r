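Package: exomeburden
Title: Rare-Variant Case-Control Exome QC and Collapsing Burden Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control and association analysis for rare-variant
    case-control exome studies. Implements sample-level QC (missingness and
    heterozygosity outliers, sex checks, duplicate detection), genotype- and
    variant-level filters (genotype quality, allelic depth, truth tranche,
    alignability, simple-repeat proximity, Hardy-Weinberg equilibrium,
    differential missingness, allele balance), a two-sided Fisher single-variant
    scan with minimum-attainable-P pruning and a trimmed genomic-inflation
    diagnostic, the T1 collapsing burden test over nested functional variant
    classes with an exact one-sided mid-P permutation null, candidate-gene
    panel testing, simulation-based power analysis over allele frequency and
    relative risk, and a synthetic cohort generator with planted burden
    signals and injected QC failure modes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
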