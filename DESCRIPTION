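Package: cmremodel
Title: Quantitative Cardiac MRI Analysis of Left-Ventricular Remodeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmental T1 and extracellular volume fraction (ECV) mapping,
    six-standard-deviation late gadolinium enhancement (LGE) quantification,
    AHA 16-segment geometry, left-ventricular volumetrics, and indexed
    cellular/extracellular volume (iCV/iECV) computation for paired pre/post
    cardiac MRI studies, together with the cohort statistics stage
    (normality-gated paired tests with Bonferroni correction, Pearson
    correlations, univariable screening with stepwise multivariable linear
    regression and diagnostics, restricted cubic spline nonlinearity checks).
    Includes a synthetic short-axis phantom generator with analytic ground
    truth so the full pipeline is testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lmtest,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
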