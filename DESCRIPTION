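Package: qsarfate
Title: QSAR Models of Environmental Fate, Bioconcentration and Brain
    Penetration from Membrane-Permeability Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the soil-water partition coefficient (log Koc), the
    fish bioconcentration factor (log BCF) and the unbound brain-to-plasma
    ratio (log Kp,uu) of small molecules from physico-chemical and membrane
    permeability descriptors, using published fixed-coefficient multiple
    linear regression equations, and turns the predictions into regulatory
    risk categories (EPA soil mobility classes, bioaccumulation flags,
    blood-brain barrier categories, intestinal absorption and Caco-2
    permeability flags, Lipinski rule-of-five checks).  Also provides the
    model-development machinery behind such equations: a tolerance-based
    collinearity screen, forward stepwise multiple linear regression with
    leave-one-out Q2 and external RMSE validation, boosted-tree and neural
    network ensembles with variable-importance and global sensitivity
    analysis, cross-model consensus reporting, per-family summaries,
    applicability-domain range checks, and a synthetic reference-data
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
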