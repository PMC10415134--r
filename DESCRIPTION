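Package: lifecon
Title: Cross-Species Gene Expression and Lifespan Concordance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking gene expression to species maximum lifespan
    (MLS) across a mammalian phylogeny. Identifies trait-associated genes by
    Spearman rank correlation and by phylogenetic generalized least squares
    (PGLS) under a Brownian-motion covariance, aggregated conservatively over
    an ensemble of candidate trees (maximum p-value), with two-stage
    Benjamini-Krieger-Yekutieli false discovery rate control. Quantifies the
    concordance of signed gene sets (e.g. lifespan- versus aging-associated
    genes) with observed-versus-expected odds ratios and exact binomial
    overlap tests, performs Fisher-exact enrichment against annotation
    libraries, and scores promoter motif content with a position weight
    matrix scanner whose null p-values come from the exact score
    distribution. A synthetic-data module simulates phylogenies, Brownian
    traits, expression matrices with planted trait effects, signed partner
    gene sets with a target concordance odds ratio, and promoter sequences
    with planted motif trends, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
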