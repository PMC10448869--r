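Package: hetprofiler
Title: Gene-Level Zygosity Profiling and Protein-Domain Mutation
    Clustering for Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Profiles somatic mutation cohorts for genes preferentially
    altered by heterozygous mutations. Computes per-gene zygosity
    statistics from variant allele fractions (oncogenic mutation totals,
    diploid-or-gain mutant sample counts, sub-50 percent allele-fraction
    counts, heterozygous proportions) and classifies genes as
    heterozygous-preferential; maps mutations onto protein-domain models
    and quantifies c-terminal clustering of truncating mutations with an
    exact binomial test; and simulates tumor cohorts with known purity,
    copy number, and zygosity ground truth so the whole pipeline is
    testable without external downloads. Reads MAF-style mutation tables
    and GISTIC-coded gene-level copy-number tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
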