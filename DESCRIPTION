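Package: alphadbs
Title: Alpha-Band LFP Biomarker Analysis for DBS Leads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for local field potentials (LFP) recorded from
    deep brain stimulation (DBS) leads in the ventral capsule/ventral striatum.
    Estimates Welch power spectra from bipolar recordings, decomposes them into
    periodic and aperiodic components with a Lorentzian-with-knee spectral
    parameterization, extracts alpha-band biomarkers, projects bipolar pair
    power onto pseudo-monopolar per-contact estimates, predicts the optimal
    stimulation contact with permutation-tested cumulative selection curves,
    quantifies spatial focality of alpha power in template space via the
    moment of inertia, and relates alpha power to symptom severity with
    cluster-based permutation tests, Spearman correlations and linear
    mixed-effects models. Includes a synthetic cohort generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    jsonlite,
    pracma,
    lme4,
    lmerTest,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
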