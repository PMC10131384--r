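Package: sweepscan
Title: Recent-Selection Genome Scans with Haplotype, FST and PBS Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-level selection analysis for candidate gene sets: a
    recent-selection genome scan on phased haplotypes (EHH, iHS, xpEHH,
    per-site Weir & Cockerham FST, the population branch statistic, empirical
    outlier windowing and an intersection decision rule for exonic SNPs),
    together with its supporting statistical layers (branch-site
    likelihood-ratio decisions with the chi-square mixture p/2 and Bonferroni
    correction, and a two-proportion Z test for incidence comparisons). A
    forward Wright-Fisher simulator generates phased multi-population
    haplotypes with known neutral/sweep ground truth so the whole pipeline
    runs and is testable without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
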