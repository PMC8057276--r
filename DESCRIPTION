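Package: tnprofiler
Title: Paired Tumor-Normal Somatic Profiling: Fisher-Exact Calling, Focal
    Copy Number, MSI and TMB
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic core of a paired tumor-normal comprehensive genomic
    profiling assay. Calls somatic SNVs and indels by a one-sided Fisher's
    exact test on tumor/normal allele counts with Benjamini-Hochberg control
    of the false discovery rate and hotspot-aware allele-frequency filters;
    calls focal copy-number alterations from insert-size-, GC- and
    dinucleotide-normalized per-target coverage log2 ratios adjusted against
    chromosome-arm medians; classifies exome-wide microsatellite instability
    from tumor-specific indels in short tandem repeats; scores tumor
    mutational burden in mutations per megabase. Includes a synthetic
    paired-data simulator (paired allele counts, 1:1 serial dilutions, biased
    coverage tracks, repeat-context indels) and a validation harness for
    sensitivity, positive predictive value, VAF concordance and
    limit-of-detection estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    MASS,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
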