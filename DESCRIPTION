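Package: imppipe
Title: Shotgun Metagenome Quantification and Cohort Associations for
    Microbial Imidazole Propionate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, fully testable implementation of the
    computational chain linking shotgun-metagenome quantification to
    cohort-level associations between serum imidazole propionate (ImP),
    glycemic status, gut microbiome ecology and diet. Provides a synthetic
    cohort generator (gene catalog, metagenomic species panels, urocanate
    reductase reference genes, single-end reads, clinical and nutrition
    tables with planted effects), gene-catalog read mapping with smart
    shared counting, rarefaction gene richness and FPKM normalization,
    Dirichlet multinomial mixture enterotyping at the genus level,
    functional marker quantification (urdA active-site windows with
    position-373 classification, hutH by KEGG ortholog), and the subject
    level statistics used downstream: Grubbs outlier exclusion, derived
    insulin-resistance indices, quartile multinomial odds ratios,
    covariate-adjusted partial correlations with Benjamini-Hochberg FDR,
    and residualized random-forest taxon importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    nnet,
    randomForest,
    mclust,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
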