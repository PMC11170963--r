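Package: pairedbiome
Title: Paired Pre/Post Intervention Analysis of Gut Microbiome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for paired (pre/post) intervention studies of
    the gut microbiome, as used in drug-microbiota trials: compositional
    transforms (relative abundance, centered log-ratio), alpha diversity with
    paired signed-rank testing, four community dissimilarity metrics
    (Bray-Curtis, Hellinger, Spearman, Jensen-Shannon) with PERMANOVA and
    distance-based individual fingerprint classification, paired and
    cross-arm differential abundance of species and functional genes with
    Benjamini-Hochberg correction, species co-occurrence network construction
    and differential network testing, and baseline-microbiota prediction of
    clinical treatment response (partial Spearman screening, elastic-net
    variance explained, responder logistic regression, and longitudinal GEE).
    Includes a synthetic paired-cohort generator with planted ground truth so
    every stage can be validated against known signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
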