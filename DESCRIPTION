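Package: flabkit
Title: Comparative Gene-Content Analysis of Convergent Reductive Genome
    Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting convergent reductive genome evolution in
    bacterial comparative genomics, motivated by the fructophilic lactic
    acid bacteria (FLAB), a polyphyletic group of Lactobacillaceae with
    strongly reduced carbohydrate metabolism. Provides per-functional-class
    ordinary least-squares regression of gene counts on genome size with
    deduced-count shortfalls, hierarchical clustering of strains on binary
    gene-family presence/absence profiles with Newick export, a
    'specific'/'missing' marker-gene screen under strict prevalence
    thresholds, a binomial null model for the number of marker genes
    expected by chance, and a synthetic-data generator that emulates
    convergent gene loss in a polyphyletic focal group so the whole
    pipeline is testable without any genome download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
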