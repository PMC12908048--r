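Package: strokedysbiosis
Title: Gut Microbiome Dysbiosis Indices and Biomarker Prognostics for Post-Stroke Infection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for microbiome-biomarker prognosis in acute
    ischemic stroke cohorts: stroke dysbiosis index (SDI) and microbial
    dysbiosis index (MDI) scoring from taxon panels, alpha diversity
    (Shannon, Pielou, Simpson, Chao1), Bray-Curtis beta diversity with
    principal-coordinates analysis, PERMANOVA and multivariate-dispersion
    (BETADISPER-style) permutation tests, group comparisons and
    biomarker-outcome correlations with Benjamini-Hochberg FDR control,
    a screened logistic prognostic model with bootstrap optimism-corrected
    AUC, and microbial co-occurrence network summaries. Includes a
    seeded synthetic cohort generator emulating an infected/non-infected
    stroke cohort so every stage is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    pROC,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
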