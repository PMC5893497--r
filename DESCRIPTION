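Package: eegreflect
Title: Reflection-Coefficient Features for Mental-Task EEG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and classification tools for mental-task
    brain-computer interfacing from multichannel scalp EEG. Reflection
    coefficients are computed directly from the biased autocorrelation
    function of short overlapping signal frames via the Levinson-Durbin
    recursion, giving a compact, bounded feature vector per channel.
    Includes band-power and inter-hemispheric asymmetry-ratio baseline
    feature sets (PAR4/PAR5/PAR6), kernel support-vector-machine
    classification under frame-level leave-one-out cross-validation,
    principal-component reduction and rank-sum separability screening,
    preprocessing (line-noise notch, normalization, overlapped framing),
    CSV and European Data Format (EDF) input, and a seeded autoregressive
    EEG simulator with known reflection structure for end-to-end testing
    and ablation experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
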