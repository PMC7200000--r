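Package: popgenmon
Title: Genetic and Demographic Monitoring of Small Wildlife Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Combined population-genetic and demographic monitoring toolkit
    for small, fragmented wildlife populations, built around the analyses
    used in conservation assessments of an endangered gartersnake. Provides
    SNP genotype input/filtering, per-site diversity summaries (rarefied
    allelic richness, heterozygosity, nucleotide diversity), Weir-Cockerham
    theta with permutation tests and Mantel isolation-by-distance,
    single-sample linkage-disequilibrium and two-sample temporal effective
    population size estimators with jackknife confidence intervals, Bayesian
    closed-population capture-mark-recapture abundance estimation by data
    augmentation (with a Huggins conditional-likelihood alternative), a
    genetic-erosion / genetic-rescue decision framework, and Wright-Fisher
    and capture-history simulators for validation.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    vegan,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
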