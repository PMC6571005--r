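Package: clvclass
Title: Latent-Variable Clustering and Subject Reclassification for
    High-Dimensional Psychophysiological Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for checking the agreement between a clinical two-class
    labeling and a data-driven labeling built from high-dimensional
    event-related-potential (ERP) and behavioral features on small samples.
    Implements clustering of variables around latent components (CLV):
    agglomerative construction, partitioning consolidation, latent score
    extraction and projection of new subjects; two-cluster k-means subject
    reclassification with cluster-to-class alignment; concordance summaries
    (agreement, Cohen's kappa, sensitivity, specificity, chi-square);
    stratified repeated cross-validation with per-repetition latent-count
    selection and channel-set scanning; Attention Network Test (ANT)
    behavioral scoring and ERP window-measure extraction; and a seeded
    synthetic-data generator with planted latent group structure for
    end-to-end testing without external recordings.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
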