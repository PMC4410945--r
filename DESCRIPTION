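Package: boldcal
Title: Multi-Field Calibrated BOLD Simulation and CMRO2 Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for hypercapnia-calibrated BOLD fMRI across magnetic field
    strengths (1.5, 3 and 7 T). Implements a four-compartment
    (arterial/capillary/venous/extravascular) BOLD signal simulator that
    predicts the calibration parameter M from baseline physiology and
    field-specific relaxometry, the Davis model calibration engine (M from an
    isometabolic hypercapnic challenge, relative CMRO2 from task responses,
    echo-time scaling), a desk-scale voxelwise analysis chain (gamma-HRF
    design matrices with tag-control interaction regressors, DCT highpass
    filtering, OLS fitting, response normalisation, percentile ROI
    construction, voxel exclusion, per-subject estimates, paired t-tests,
    Bland-Altman agreement, ASL SNR), and a seeded synthetic ASL/BOLD phantom
    generator with per-voxel ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
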