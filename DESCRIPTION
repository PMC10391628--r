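Package: bcraging
Title: B Cell Receptor Repertoire Aging Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for B-cell-receptor (BCR) heavy-chain
    repertoires across age and dietary-restriction cohorts. Infers clonal
    lineages from AIRR rearrangement tables (amino-acid identity or
    sample-specific distance thresholds), computes Hill diversity spectra
    with uniform-depth subsampling and bootstrap, the P20 clonal-expansion
    statistic, the repertoire dissimilarity index (RDI) over V/D/J gene
    usage, synonymous and non-synonymous somatic-hypermutation frequencies,
    class-switch staging of clones, CDR3-length statistics, and a
    macromorbidity index, and runs the cohort statistical layer (per-diet
    age regressions, two-way ANOVA, exact Mann-Whitney tests with
    Bonferroni correction, Spearman metric-morbidity correlations). A
    synthetic cohort generator with planted ground truth makes every stage
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    knitr,
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
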