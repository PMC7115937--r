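Package: arousalkit
Title: Automatic Arousal Detection for Whole-Night Sleep EEG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic, self-calibrating detection of micro-arousals in
    whole-night polysomnography (EEG/EOG/EMG). Implements band-limited
    Butterworth preprocessing on a 30 s scoring-window / 1 s epoch grid, bad
    EEG channel screening and composite submental EMG reconstruction,
    per-epoch EMG tone-shift and theta/alpha/beta EEG frequency-shift
    detection with recording-adapted thresholds, sigma-band (spindle)
    exclusion, and assembly of arousal events under the AASM-style 3 s
    minimum-duration and REM EMG-concomitance rules. Ships an event-level and
    1 s epoch-level scorer-agreement framework (Bennett's S, Cohen's kappa,
    sensitivity, mean event overlap, false discovery ratio), Morlet
    time-frequency profiling of detected events, minimal EDF input/output,
    and a ground-truth-labelled synthetic polysomnography generator so the
    whole pipeline is testable without real recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
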