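Package: AgeProteomics
Title: Multi-Tissue Aging Proteomics: TMT Quantification, Differential
    Abundance, and Protein-Complex Co-Abundance
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for multiplexed (TMT)
    proteomics studies of aging across tissues. Peptide intensities are
    rolled up to protein abundances with within-batch scaling factors and
    ratio-normalized to a pooled bridge sample shared between batches.
    Per-tissue age, sex, and age-by-sex effects are estimated by ordinary
    least squares with Benjamini-Hochberg false discovery control;
    cross-tissue consistency and tissue-specific effects are assessed with
    linear mixed models using Satterthwaite degrees of freedom, and
    technical versus biological variation is partitioned into mouse, TMT
    tag, and batch variance components with BLUPs. Protein-complex
    co-abundance ("cohesiveness") is summarized as the median of member-wise
    median pairwise correlations, tested for group differences with paired
    t-tests, and pairwise correlation changes are tested with stratified
    permutations. A synthetic-data generator reproduces the full study
    design (20 mice, two ages, two sexes, 10 tissues, two 11-plex batches
    per tissue) with known ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    lmerTest,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
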