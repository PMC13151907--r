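Package: ecgbp
Title: Blood Pressure Estimation from Short Single-Lead ECGs: Simulation,
    Features, and Leakage-Aware Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying whether blood pressure (BP) can be estimated
    from 30-second single-lead ECG recordings. Provides a seeded synthetic
    cohort generator (asynchronous ECG and cuff-BP logs with sex-specific BP
    distributions, subject-level random effects, optional planted heart-rate
    to BP coupling), ECG preprocessing (band-pass and powerline notch
    filtering, record-length standardization), an interpretable 128-feature
    ECG extractor (beat SNR, HR/HRV, fiducial intervals, amplitudes and
    areas, slopes, Hjorth descriptors, singular-value beat-morphology
    spectrum), windowed ECG-BP pairing with per-subject capping,
    sex- and rhythm-stratified tree-ensemble regression and classification,
    and an evaluation layer covering subject-wise versus record-wise
    cross-validation, AAMI and BHS device standards, AHA BP categories, and
    fixed central-tendency baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    ranger,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
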