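Package: placentr
Title: Placental Multi-Omic Analysis of Preeclampsia Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for dissecting placental disease
    pathways in preterm and term preeclampsia. Provides tissue-specificity
    calling of predominantly placenta-expressed genes from a multi-tissue
    expression atlas, moderated-t differential expression with weighted
    gene co-expression module discovery (soft-thresholded adjacency,
    topological overlap, dynamic tree cutting) and hub transcription-factor
    selection, gene-clinical-trait association models, a "virtual liquid
    biopsy" aggregating maternal-blood biomarker levels as percent of
    control across gestation, a discretized expression-pattern match-score
    permutation test linking in vitro trophoblast models to in vivo
    signatures, and targeted bisulfite CpG methylation-difference
    classification. Seeded synthetic-data generators with planted ground
    truth support end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
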