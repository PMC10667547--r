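Package: salovlap
Title: Saliency-Lesion Overlap and Detection Performance Evaluation for
    Mammography AI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates how strongly the saliency maps of AI systems for
    breast-cancer detection concentrate on radiologist-segmented breast
    lesions. Implements per-image min-max normalization of saliency maps,
    optimal-threshold extraction of areas of interest (the threshold that
    maximizes Dice overlap with the lesion mask, found by an exact sweep
    over all distinct saliency values), Dice similarity scoring with
    median/IQR summaries, rank-statistic ROC AUC with stratified percentile
    bootstrap confidence intervals and a CI-excludes-0.5 significance rule,
    exact-key case-control matching on birth year, screening year and
    mammographic system, and a synthetic phantom generator (elliptical
    lesions on half-ellipse breast phantoms, saliency fields with tunable
    lesion localization, binormal detection scores with closed-form true
    AUC) so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
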