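Package: cemval
Title: Temporal Validation of Climate Envelope Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating climate envelope models (CEMs) across two
    time periods using independent survey data. Fits presence/background
    suitability models (random forest, or a penalized-logistic maximum-entropy
    surrogate), selects presence/absence thresholds by maximum Cohen's kappa
    or by species prevalence, and evaluates three treatments of climate-driven
    range change - dynamic (the envelope both expands and contracts), static
    (no change), and hybrid (expansion appended to the original envelope) -
    with resampled sensitivity, specificity, TSS and AUC. Includes map algebra
    for range expansion/contraction, trait regressions on per-species metric
    differences, a virtual-species simulator with controllable persistence and
    dispersal limitation, ESRI ASCII grid input/output, and packaged summary
    tables from a published 12-species breeding-bird study for reproduction of
    its reported statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
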