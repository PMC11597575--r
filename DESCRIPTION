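Package: coldtx
Title: Cold-Stress Transcriptome Analysis with Exact Negative-Binomial
    Tests and Logistic Gene-Set Enrichment
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential-expression analysis of low-temperature
    transcriptome experiments: TMM between-sample normalization,
    conditional-likelihood estimation of a common negative-binomial
    dispersion, a pairwise exact negative-binomial test with
    Benjamini-Hochberg FDR control, top-N induced-gene selection with
    exclusive Venn partitioning across treatments, Gene Ontology term
    enrichment by logistic regression of term membership on the signed
    significance score sign(logFC)*-log10(FDR) (with Firth-penalized
    fits under separation), and 2^-deltaCt qPCR quantification with
    one-way ANOVA and Tukey HSD. A seeded synthetic-data generator with
    known ground truth (planted fold changes and planted enriched
    terms) supports calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    edgeR,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
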