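Package: swayshift
Title: Mechanics-Informed Posturography Analysis for Parkinson's Disease
    Rehabilitation Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to assess Parkinson's disease motor control and
    rehabilitation outcomes from force-plate recordings. Derives
    center-of-pressure (COP) trajectories from raw force/moment channels,
    extracts standing-sway and gait-initiation features (path length, RMS,
    sway area, anticipatory postural adjustment displacement), performs
    forward feature selection with nested cross-validation, embeds feature
    tables with a from-scratch t-SNE, clusters with k-means++ (elbow/WCSS,
    silhouette, Davies-Bouldin and Calinski-Harabasz indices with
    out-of-bag bootstrap confidence intervals), and quantifies effects with
    Cohen's d, classical tests, and exact Shapley attribution. A seeded
    synthetic force-plate cohort generator with known group structure
    provides a fully reproducible test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    cluster,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
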