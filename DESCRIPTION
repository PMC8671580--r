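Package: dpskin
Title: Kinetic Analysis of Dynamic Planar Myocardial 123I-MIBG Scintigraphy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for 30-minute dynamic planar scintigraphy (DPS) of
    myocardial 123I-meta-iodobenzylguanidine (MIBG). Builds metabolite- and
    platelet-corrected plasma input functions from mediastinal time-activity
    curves, fits one-tissue two- and three-parameter compartment models by
    frame-duration-weighted nonlinear least squares, derives turnover indices
    (iUp, iLoss, iNs, iUp/iLoss, pharmacological half-life) alongside
    conventional planar indices (early/delayed heart-to-mediastinum ratio and
    washout rate), and evaluates diagnostic discrimination of Lewy body
    disease with ROC analysis, bootstrap AUC comparison, SMOTE-balanced
    support vector machines, diagnostic odds ratios and Dunnett subgroup
    tests. Includes a synthetic-cohort simulator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    e1071,
    multcomp,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
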