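Package: cvrkit
Title: Cerebrovascular Reactivity Mapping from BOLD MRI Hypercapnia Challenges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify cerebrovascular reactivity (CVR) from
    blood-oxygen-level-dependent (BOLD) MRI acquired during a step
    hypercapnia challenge. Builds end-tidal CO2 (PetCO2) regressors from
    capnograph traces, fits voxelwise least-squares CVR maps (% BOLD
    signal change per mmHg PetCO2) with volume discard and motion
    censoring, summarises tissue-wise CVR indexes and volumes from
    segmentation masks, and runs a cohort-level statistical battery
    (Shapiro-Wilk gating, Mann-Whitney, paired t, Pearson correlation,
    covariate-adjusted group effects). Includes a digital 4D phantom and a
    Gaussian-copula cohort simulator with known ground truth so the whole
    pipeline can be validated end to end without patient data.
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
    Matrix,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
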