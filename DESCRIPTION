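Package: ictaloop
Title: Closed-Loop Seizure Detection, Optogenetic Intervention Analysis and
    Ictal Onset Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for closed-loop electrographic seizure
    experiments: detection of epileptiform spikes on local field potential
    recordings by configurable amplitude, width and template criteria combined
    with Boolean logic; segmentation of spike clusters into seizures by
    interspike-interval rules; a causal streaming detector with stimulation
    scheduling; peri-event calcium (dF/F) analysis for imaged neurons;
    mixed-model statistics for light-on versus light-off seizure durations;
    and per-channel ictal onset-pattern classification for human
    stereo-EEG with a high-frequency-oscillation band marker. A synthetic
    session generator with full ground truth makes every stage testable
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    lme4,
    lmerTest,
    withr
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    yaml
Config/testthat/edition: 3
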