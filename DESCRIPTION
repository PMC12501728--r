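Package: renalperf
Title: Dual-Modality Renal Cortical Perfusion Analysis (FAIR-ASL and
    [15O]H2O PET) with Agreement Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies renal cortical perfusion from FAIR arterial spin
    labeling MRI (single-subtraction inversion-recovery model with a
    voxel exclusion rule) and from dynamic [15O]H2O PET (one-tissue
    compartment model with image-derived input function extracted by
    k-means clustering, weighted nonlinear ROI fits with a fitted time
    delay, and basis-function parametric maps).  Implements the
    method-agreement statistics used to compare the two modalities:
    simple regression, Bland-Altman limits of agreement, and a REML
    linear mixed-effects variance-components model with
    modality-specific standard deviations from which repeatability,
    reproducibility and cross-modality limits of agreement and
    coefficients of variation are derived.  Includes a synthetic
    phantom generator (dynamic PET volumes, ASL control/label series
    and long-format perfusion tables with known variance components)
    for validation, since no patient data accompany the methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
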