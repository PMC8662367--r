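Package: earlygrowth
Title: Fetal and Infant Growth Exposures and Volumetric Brain Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs standardized early-life growth exposures from
    longitudinal cohort data -- gestational-age- and sex-adjusted weight SD
    scores (internal references or external LMS/moments charts), Hadlock
    estimated fetal weight, birth-outcome categories, the 3x3 fetal-by-infant
    growth-pattern taxonomy, conditional (sequentially residualized) growth
    variables, peak weight velocity from the Reed1 infant curve, and age and
    BMI at adiposity peak from a cubic mixed model on log BMI -- and relates
    them to volumetric brain outcomes with tiered covariate adjustment,
    sex-interaction and nonlinearity checks, and multiple imputation of
    covariates pooled by Rubin's rules. A synthetic-cohort generator with
    known ground truth makes every pipeline stage testable without access to
    the original cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    lme4,
    nnet,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
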