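Package: sknatools
Title: Complexity Analysis of Skin Sympathetic Nerve Activity from High-Rate ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction and complexity analysis of skin sympathetic nerve
    activity (SKNA) from high-sampling-rate single-channel ECG. Implements the
    neuECG integrated SKNA envelope (500-1000 Hz bandpass, rectification,
    100 ms smoothing) and a time-varying SKNA representation based on variable
    frequency complex demodulation (VFCDM) with Hilbert amplitude estimation;
    preprocessing primitives (polyphase resampling, Kaiser-window FIR design,
    zero-phase filtering, PSD-guided narrowband interference removal);
    segment-level complexity indices (approximate and sample entropy, Hjorth
    mobility and complexity, Katz fractal dimension, standard deviation); and a
    segment-level statistical layer (random-intercept mixed models with
    Tukey-adjusted contrasts and Cohen's d, Benjamini-Hochberg FDR, ROC/AUC
    with DeLong confidence intervals and paired tests, repeated-measures
    correlation). A synthetic-data module generates ECG recordings with
    burst-like band-limited sympathetic activity, subject random effects and
    interference tones so the full pipeline is testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    lme4,
    lmerTest,
    emmeans,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
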