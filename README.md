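# arousalkit

Automatic detection of micro-arousals in whole-night sleep EEG, with the
scorer-agreement framework used to validate such detectors and a
ground-truth-labelled synthetic polysomnography generator.

## What it is for

Arousals are transient (≥ 3 s) accelerations of the sleep EEG toward
theta/alpha/beta frequencies — excluding sleep spindles — that in REM must
be accompanied by a submental EMG tone increase. They index sleep
fragmentation, but visual scoring is slow and rater-dependent. This package
is for sleep researchers who want a deterministic, training-free detector
whose thresholds adapt to each recording, and for methodologists who need
the event-level agreement machinery (Bennett's S, Cohen's κ, sensitivity,
mean overlap, false discovery ratio) to compare any two arousal scorings.

## The algorithm in brief

On a 30 s scoring-window / 1 s epoch grid, after order-3 Butterworth
filtering per modality (EEG 0.5–30 Hz, EOG 0.1–5 Hz, EMG 10–100 Hz) and
bad-channel screening, a 1 s epoch *e* in window *w* is an EEG shift in
band *b* ∈ {θ (3–7 Hz), α (7–13 Hz), β (16–30 Hz)} when

    P_b(e) > median_all_epochs P_b   and   P_b(e) > 2 · median_{S(w)} P_b

where S(w) is the window's EMG-shift-free epochs plus the nearest ten
EMG-shift-free epochs on each side. Spindle epochs — relative sigma power
σ/(α+σ+β) above 85 % of its recording-wide maximum — are excluded, and
maximal runs of ≥ 3 triggered epochs become events. EMG tone shifts
(a three-step cascade of baseline, local-median and neighbourhood tests on
the composite submental EMG) label events as EMG-associated and gate REM
events. Every threshold is a median or ratio of the recording itself, so
detection is invariant to global amplitude scaling.

At comparison time, scores are rendered on a 1 s grid (> 0.5 s of an epoch
marked ⇒ the epoch is an arousal), events are matched across raters with
≥ 1 s overlap, and the report carries S = 2·P0 − 1, Cohen's κ
(standard marginal chance term; a "paper-literal" variant of the chance
term found in print is also implemented and always labelled), Se, C and
FDR, plus inclusive (union) and conservative (co-detected) fusions of two
raters into a gold standard.

See `vignette("arousal-detection")` for the full model, parameter table,
design decisions and limitations.

## Worked example

Generate one hour of synthetic sleep with ten ground-truth arousals, run
the detector, and score it against the ledger:

```r
library(arousalkit)

stages <- synth_spec(duration_s = 3600, seed = 42)$stages
plan <- plan_events(stages, n = 10, duration_s = 4, gain = 4,
                    with_emg = c(TRUE, FALSE),
                    stage_in = c("N1", "N2", "N3"), seed = 42)
syn <- synth_psg(synth_spec(duration_s = 3600, events = plan, seed = 42))

ad <- detect(syn$recording, syn$hypnogram)
head(ad)
#>   onset_s duration_s rater_id emg_associated            bands stage
#> 1     813          4       AD           TRUE theta,alpha,beta    N2
#> 2    1277          4       AD          FALSE      theta,alpha    N2
#> 3    1356          4       AD           TRUE             beta    N2
#> 4    1414          5       AD           TRUE theta,alpha,beta    N2
#> 5    1487          4       AD           TRUE            alpha    N2
#> 6    1646          4       AD          FALSE      theta,alpha    N2

coefficients(confusion(to_track(ad, 3600), to_track(syn$ledger, 3600)))
#> <agreement_report>
#>   S = 0.999  kappa(standard) = 0.975 (Almost perfect)
#>   Se = 1  C = 1  FDR = 0
#>   epochs: TP 40 FP 2 TN 3558 FN 0 | events: TP 10 FP 0 FN 0
```

All ten injected events are recovered (`Se = 1`, event TP 10), with no
false events; the two false-positive epochs are boundary seconds where a
detected run extends one epoch beyond an injected burst's edge. `kappa = 0.975`
sits in the "Almost perfect" band of the Landis–Koch scale
(`kappa_interpretation()`).

A command-line front end wrapping the same functions (subcommands `synth`,
`detect`, `agree`, `profile`, `demo`) is installed at
`inst/cli/arousalkit.R`:

```sh
Rscript inst/cli/arousalkit.R demo --seed 3 --out report.json
```

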