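Package: nbsevol
Title: Evolutionary Analysis of NBS-Encoding Resistance Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for genome-wide evolutionary analysis of
    plant NBS (nucleotide-binding site) disease-resistance genes: domain-based
    architecture classification (TNL/TN/CNL/CN/XNL/XN with an orthogonal RPW8
    flag), gene-family clustering from global-alignment coverage and identity,
    Nei-Gojobori Ka/Ks estimation with Jukes-Cantor correction and Ks-based
    duplication-age profiles, neighbor-joining phylogenies with bootstrap
    supports and species-specific duplication clade detection, GY94 codon site
    models (M0, M7, M8) with likelihood-ratio tests and empirical-Bayes
    detection of positively selected sites, and IUPAC-degenerate cis-element
    scanning of promoter regions. Includes a seeded synthetic-data generator
    that emulates the statistical structure of such datasets with a
    ground-truth manifest for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    ape,
    phangorn,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    IRanges,
    optparse
Config/testthat/edition: 3
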