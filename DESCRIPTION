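Package: devdelay
Title: Developmental-Delay Analysis of Mutant Embryo Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether transcriptome changes in a mutant
    embryo are explainable by a developmental delay. Provides readers for
    gene-level expression tables and staged developmental reference
    time-courses, a simplified per-gene differential-expression test with
    Benjamini-Hochberg correction, exact small-sample Wilcoxon rank tests,
    a derepression check against reference-silent genes, the early/late
    window rule for delay-explainability, transcriptome stage assignment by
    rank correlation, Fisher's exact gene-set overrepresentation with a
    most-specific-term filter, and a negative-binomial simulator of staged
    embryo expression with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
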