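Package: pbarray
Title: Cross-Species Microarray Analysis of Lead-Responsive Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-species, two-tissue microarray studies of
    heavy-metal (Pb) response in which RNA from a metal-tolerant species is
    hybridized to arrays designed for a sensitive model relative. Provides
    upper-quartile between-array normalization, per-probe median centering,
    background-based probe retention, pooled-variance t-tests with
    Benjamini-Hochberg correction, a two-species candidate-selection cascade
    (Venn partition into metal-specific and metal-common genes, fold-change and
    cross-species fold-change-ratio filters), bootstrap normed-frequency
    functional-class enrichment with hypergeometric significance, qRT-PCR
    concordance, and a seeded synthetic-data generator with planted differential
    expression and cross-species probe dropout for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
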