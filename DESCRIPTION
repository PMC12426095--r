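Package: dyadsync
Title: Quantifying Dyadic Movement Coordination from Rhythmic Motion and Gaze
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for quantifying interpersonal movement
    coordination in dyadic trials. Provides a synthetic generator of weakly
    coupled rhythmic arm movements, irregular head sway and area-of-interest
    gaze streams under a 2x2 mixed design; signal preprocessing (trimming,
    centring, zero-phase Butterworth filtering); coordination stability of
    arm movements via Hilbert relative phase and circular statistics (rho,
    Fisher-transformed); head-movement coordination via cross-recurrence
    quantification (percent recurrence) with data-driven embedding parameter
    selection (average mutual information, false nearest neighbours);
    gaze dwell-time summaries; and linear mixed-effects inference with
    Satterthwaite degrees of freedom, likelihood-ratio model comparisons and
    Tukey-corrected post hoc contrasts.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
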