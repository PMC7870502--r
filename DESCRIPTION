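Package: arcfluid
Title: Fluid-Therapy Augmented Renal Clearance Analysis in a Piglet Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Compartmental pharmacokinetic analysis of intravenous renal
    function markers (iohexol, para-aminohippuric acid, amikacin) in a
    two-period piglet fluid-therapy study of augmented renal clearance.
    Provides closed-form one- and two-compartment IV-bolus models with
    maximum-likelihood fitting under proportional or additive residual
    error and precision-based model fallback, a non-compartmental AUC
    quality gate, urine-based renal clearance and urine output, van
    Beaumont plasma-volume change from hematocrit, test-retest
    reproducibility and Bland-Altman agreement statistics, exact
    nonparametric group comparisons, a seeded synthetic cohort generator
    emulating the study design, and an end-to-end analysis pipeline with
    screening filters and tabular reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
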