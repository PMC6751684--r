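Package: mirsign
Title: Ensemble Feature Selection for Reduced miRNA Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovers reduced miRNA signatures from labeled expression
    matrices by consensus feature ranking across heterogeneous classifier
    instances (tree ensembles and linear models) run under repeated
    stratified cross-validation. Includes the standard comparison selectors
    (univariate ANOVA-F filtering, recursive feature elimination, LASSO and
    elastic-net, subsampled linear-SVM ensemble elimination, random
    selection), an evaluation battery for full-versus-reduced feature sets
    and binary tasks, a cross-platform expression mapping that rescales
    z-scored external data into the reference dataset's intensity space,
    and a synthetic data generator emulating pan-cancer miRNA-seq structure
    with planted discriminative features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    xgboost,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
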