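Package: reportermet
Title: Reporter Metabolite Analysis of Transcriptional Regulation over
    Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for directional gene-set analysis
    of differential expression projected onto a genome-scale metabolic
    network. Gene sets are built from metabolite-reaction-gene and
    pathway-reaction-gene associations (or read from GMT files), scored
    with the median log2 fold change of their members, and assigned
    permutation p-values for distinct-directional, mixed-directional and
    non-directional classes; significant metabolite sets are reporter
    metabolites, transcriptional hotspots of the network. Companion tools
    correct measured mass-isotopomer distributions for natural isotope
    abundance, estimate growth-normalized metabolite exchange rates from
    spent-media time courses, compute succinate dehydrogenase activity
    from colorimetric assay readings, and derive respiratory parameters
    (including spare respiratory capacity) from oxygen-consumption-rate
    traces. A seeded synthetic-data module generates toy networks,
    expression tables with planted reporter metabolites, convolved
    isotopomer distributions, growth courses and OCR traces for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
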