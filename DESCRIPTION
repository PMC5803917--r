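Package: skinora
Title: Skin-Centric Pathway Over-Representation Analysis for Paired
    Treatment Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Knowledge-base-agnostic pathway over-representation analysis
    for paired before/after treatment expression studies, modelled on
    skin-centric enrichment platforms. Provides paired-microarray
    preprocessing (per-sample median scaling, Present/Marginal/Absent
    detection-call filtering, probe-to-gene median collapse), per-sample
    and aggregate log2 fold-change calling of differentially expressed
    genes with cutoff sensitivity analysis, one-sided Fisher's exact
    enrichment of curated gene sets per sample, cross-sample enrichment
    summaries, expression overlays on signed pathway interaction graphs,
    and a synthetic paired-cohort generator with planted pathway effects
    for type-I-error and power estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
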