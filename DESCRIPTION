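Package: mpramars
Title: Predicting Reporter Activity from Binding-Site Enrichment with
    Redundancy-Sized Regression Trees and MARS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the transcriptional activity measured by massively
    parallel reporter assays (MPRA) and luciferase reporter assays from DNA
    sequence alone.  Sequences are encoded as transcription-factor
    binding-site (TFBS) enrichment scores by scanning position weight
    matrices (TRANSFAC flat-file or JASPAR format) with a normalized,
    information-weighted similarity score.  Constructs are clustered by a
    CART-style regression tree whose minimum leaf size is set automatically
    from the redundancy of the feature matrix (the proportion of variance
    on the first principal component), and a multivariate adaptive
    regression splines (MARS) response function is fitted inside each
    cluster.  Includes barcode-count preprocessing, 100-fold
    cross-validated evaluation, interpretation reports (tree summaries,
    selected-TFBS frequencies, condition-specific TFBS sets, misfit
    enrichment fold changes) and seeded synthetic-data generators for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    rpart,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
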