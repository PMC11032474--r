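Package: brainpath
Title: Path-Analytic Mediation of Childhood Maltreatment Effects on Adult
    Brain Structure, with Calibrated Synthetic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for a three-stage path-analytic pipeline linking childhood
    maltreatment (CM) to adult regional brain structure via adult trauma (AT),
    body-mass index (BMI) and C-reactive protein (CRP). Provides a synthetic
    cohort and parcellated brain-map generator calibrated to published summary
    statistics; preprocessing (log transforms, median-absolute-deviation
    outlier masking, nuisance residualization, bilateral symmetrization);
    from-scratch maximum-likelihood estimation of recursive observed-variable
    path models with Huber-White (sandwich) standard errors, Satorra-Bentler
    scaled test statistics, CFI/RMSEA/SRMR fit indices, delta-method indirect
    effects and scaled nested-model comparison; region-wise brain-structure
    regressions with BH-FDR and Holm multiplicity control; spatial-
    autocorrelation-preserving spin permutation tests for parcellated cortical
    maps; and orchestrators for the cohort-level model (H1), the regional
    effect maps (H2) and the region-wise full-versus-sparse mediation models
    (H3).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
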