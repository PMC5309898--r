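Package: hybridtrace
Title: Detecting and Dissecting Hybrid-Swarm Ancestry from SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting ancient admixture and tracing the sorting of
    hybrid ancestry in rapidly radiating lineages, motivated by the
    hybrid-swarm origin of the Lake Victoria Region cichlid superflock.
    Implements quartet ABBA-BABA (Patterson's D) statistics with block
    jackknife significance, F4-ratio estimation of ancestry proportions, a
    five-population partitioned-D test of gene-flow direction, fd admixture
    scans in genomic windows, ancestry-block painting and tract merging,
    Weir-Cockerham FST outlier detection, and classification of SNPs into
    parental ancestry categories with Fisher-exact enrichment tests. A
    seeded hybrid-swarm simulator with known truth (parental drift,
    exponential ancestry tracts, post-admixture sorting) makes every stage
    testable end to end. All user-facing functions take and return tidy
    data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
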