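# ehgdetect

Automatic recognition of uterine contractions (UCs) in abdominal
electrohysterogram (EHG) recordings, with a parallel tocodynamometry (TOCO)
detector, evaluation against maternal perception, and clinical contraction
parameters. Written for researchers working on non-invasive uterine
monitoring who need a fast, training-free burst detector that runs on plain
multichannel recordings and produces TOCO-like envelopes and event tables.

## The method

An EHG burst is a fast-wave train whose amplitude follows a slow wave
spanning the contraction. The detector makes the zero-crossing rate (ZCR)
amplitude-sensitive by *elevating* the signal before counting crossings:

1. average the EHG channels; zero-phase 4th-order Butterworth low-pass at
   3 Hz; 0.2 s running median;
2. elevate by α·E, where E = mean |x| and α = 1.5: activity below the offset
   stops crossing zero;
3. sliding ZCR in a 40 s window, one-sample step:
   Z = m/W × 100 %, with zeros transparent to the sign regime;
4. min–max normalise Z to [0, 1] and raise to the power γ = 3.5;
5. multiply the (un-elevated) preprocessed signal by this weight and take a
   10 s sliding RMS — the contraction envelope;
6. report a UC wherever the envelope exceeds its mean (T_ha) for more than
   30 s (T_hd); the event peak is the run maximum and the duration is the
   envelope's half-wave width (FWHM).

TOCO is smoothed with a 40 s moving average and thresholded the same way.
A detection whose peak falls within 20 s of a maternal-perception label is a
true positive (one-to-one greedy matching); sensitivity = TP/(TP+FN),
PPV = TP/(TP+FP). On its clinical benchmark counts these formulas give
87.80 % / 93.18 % for EHG and 84.04 % / 90.89 % for TOCO.

## Worked example

Recordings are tibbles (`time_s` plus one column per channel) carrying the
sampling rate as an attribute; every result is a tibble or has `tidy()` /
`glance()` methods, and detections have an `autoplot()`.

```r
library(ehgdetect)

fx  <- simulate_recording(sim_config(seed = 42))   # 8 planted UCs, 30 min, 250 Hz
det <- detect_contractions(fx$recording)
det
#> <uc_detection> 30 min recording at 250 Hz
#>   EHG events:  8
#>   TOCO events: 8

tidy(det)
#> # A tibble: 16 × 6
#>   source onset_s peak_s end_s peak_amplitude duration_s
#>   <chr>    <dbl>  <dbl> <dbl>          <dbl>      <dbl>
#> 1 EHG       121.   143.  169.           7.38       30.8
#> 2 EHG       374.   409.  428.           7.26       39.8
#> 3 EHG       695.   725.  743.           4.63       35.1
#> # … 13 more rows

evaluate_detection(det, fx$annotations, source = "EHG")
#> <uc_evaluation> TP=8 FP=0 FN=0
#>   sensitivity: 100.00%
#>   PPV:         100.00%

uc_parameters(tidy(det)[tidy(det)$source == "EHG", ],
              recording_len_s = recording_duration_s(fx$recording))
#> <uc_parameters> 8 contractions in 30 min (2.67 per 10 min)
#>   duration: 33.9 +/- 6.7 s
#>   interval: 224.9 +/- 52.7 s
```

The event table gives each contraction's onset, peak and end (seconds from
recording start), its envelope peak amplitude (arbitrary units) and its
half-wave-width duration. The evaluation matched all eight detected EHG
peaks to the perception labels within 20 s. `sweep_parameter()` reproduces
the sensitivity/PPV/score trade-off over a grid of α or γ, and
`autoplot(det)` plots both envelopes with the detected events marked.

A command-line interface with `simulate`, `detect`, `evaluate`, `sweep` and
`params` subcommands is installed at
`system.file("cli", "ehgdetect.R", package = "ehgdetect")`; recordings are
read and written as fs-annotated CSV or 16-bit EDF.

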