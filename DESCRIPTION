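Package: rumpmap
Title: Segregation Filtering and Critical-Interval Mapping for Dominant Mendelian Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Causal-variant mapping toolkit for fully penetrant autosomal
    dominant traits in small sequenced cohorts, modelled on the mapping of
    the rumpless (Rp) locus of the Araucana chicken. Implements
    genotype-pattern segregation filtering of multi-sample VCF variants
    against a cohort design, subtraction of previously catalogued
    variants, recombinant-haplotype exclusion mapping that narrows a
    critical interval from marker haplotype tables, gene-context
    annotation of candidates, marker-phenotype concordance counting, and
    cross-species conservation scoring of fixed-width windows by global
    alignment. A synthetic-cohort generator plants a causal variant on a
    founder haplotype so the whole funnel is testable end to end without
    any sequencing download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    rlang,
    vcfR,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
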