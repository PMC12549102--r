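Package: fcwas
Title: Connectome-Wide Association Analysis with Distance Matrix Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A connectome-wide association study (CWAS) workflow for
    region-of-interest resting-state functional connectivity. Builds
    subject-level Fisher-z connectomes from ROI time series after
    motion-based volume censoring, tests behavioral covariates against
    inter-subject Manhattan distances with multivariate distance matrix
    regression (MDMR) and Freedman-Lane permutation inference, partitions
    the group connectome into modules by signed-modularity consensus
    clustering, and tests network-pair enrichment of edge-behavior
    correlations against a permuted-score null. Includes a synthetic
    cohort generator with planted modular structure and behavior-coupled
    edges so the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
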