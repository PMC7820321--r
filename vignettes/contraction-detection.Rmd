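---
title: "Detecting uterine contractions from EHG with zero-crossing-rate modulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting uterine contractions from EHG with zero-crossing-rate modulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehgdetect)
```

## The problem

Uterine contractions (UCs) are monitored throughout pregnancy and labour.
The clinical standard, external tocodynamometry (TOCO), measures abdominal
wall tension with a strain gauge; it is sensitive to belt tightness,
transducer placement and maternal habitus. The electrohysterogram (EHG) —
biopotentials recorded with surface electrodes on the abdomen — measures the
myometrial electrical activity itself, and is attractive for long-term,
non-invasive monitoring.

During a contraction the EHG shows a *burst*: a fast-wave train of action
potentials whose amplitude is modulated by a slow wave spanning the
contraction. Between contractions the signal is quiescent. `ehgdetect`
implements an automatic burst detector built around a single idea: after
shifting the signal upward by a multiple of its mean amplitude, only
high-amplitude activity keeps crossing zero, so a sliding-window
zero-crossing rate (ZCR) becomes an amplitude-sensitive, scale-free marker
of contraction activity.

## The recognition pipeline

For a recording with EHG channels $x_1, \dots, x_K$ (nominally $K = 8$ at
250 Hz) and a TOCO channel:

1. **Preprocessing.** Average the EHG channels pointwise; apply a zero-phase
   4th-order Butterworth low-pass at 3 Hz (uterine electrical activity of
   interest lies below 3 Hz; maternal ECG, movement and power-line
   interference lie above); apply a short running median (0.2 s) to knock
   out residual spikes. Every stage preserves length and sampling rate.
2. **Elevation.** Compute the mean amplitude $E$ of the preprocessed signal
   and shift it upward by $\alpha E$. Oscillations smaller than the offset
   stop crossing zero.
3. **Sliding ZCR.** In a 40 s window ($W$ samples) advancing one sample at a
   time, count sign changes $m$ and set $Z = m/W \times 100\%$. A zero
   sample is transparent: $+,0,-$ counts one crossing, $+,0,+$ none.
4. **Normalisation and power.** Min–max normalise $Z$ to $[0,1]$ over the
   recording (absorbing between-subject differences), then raise it to the
   power $\gamma > 1$, which strengthens large ZCR values relative to small
   ones.
5. **Modulation and envelope.** Multiply the *un-elevated* preprocessed
   signal by the powered ZCR weight, then take a sliding 10 s RMS. The
   result is a smooth, TOCO-like envelope in which bursts stand out.
6. **Thresholding.** Candidate events are maximal runs where the envelope
   strictly exceeds $T_{ha}$ (the mean of the envelope); a candidate is
   accepted when its run lasts strictly longer than $T_{hd} = 30$ s. The
   event peak is the (earliest) run maximum; the reported duration is the
   envelope's half-wave width (FWHM) around that peak.

The TOCO path smooths the raw TOCO trace with a 40 s moving average and
applies the same amplitude-plus-duration rule.

Detections are evaluated against maternal perception (button presses): a
detected peak within 20 s (inclusive) of a label is a true positive, with
one-to-one greedy pairing by smallest time difference so a single press can
never validate two detections. Sensitivity is $TP/(TP+FN)$ and positive
predictive value $TP/(TP+FP)$. Clinical UC parameters are the count, the
frequency per 10 min, the half-wave-width durations, and the inter-peak
intervals.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `lpf_cutoff_hz`, `lpf_order` | 3 Hz, 4 | analysis band of uterine activity |
| `median_kernel_s` | 0.2 s | spike suppression after the low-pass |
| `alpha` | 1.5 | elevation offset, in units of mean amplitude; useful range [1, 2] |
| `gamma` | 3.5 | ZCR contrast exponent; useful range [3, 4] |
| `window_s` | 40 s | ZCR window, sized to cover one 30–60 s contraction |
| `rms_window_s` | 10 s | envelope smoothing (N = 2500 points at 250 Hz) |
| `thd_s` | 30 s | minimum supra-threshold run, from the 30–60 s clinical duration range |
| `match_tol_s` | 20 s | peak-to-perception matching window |

`alpha` and `gamma` default to the midpoints of their useful ranges.
`sweep_parameter()` reproduces the sensitivity/PPV/score trade-off curves
over a grid of either parameter on any cohort of fixtures.

## Design choices where the method description is open

* **Zero-phase filtering.** The detector's output of record is peak *time*;
  causal filtering would delay peaks by a phase lag comparable to seconds.
  All filters run forward–backward. Edges use reflection extension with
  constant-history initial conditions, so DC passes exactly; samples within
  about one settling length (`fs / cutoff`) of either boundary remain
  boundary-condition approximations, as with any zero-phase filter on a
  finite signal.
* **Mean amplitude.** $E$ is the mean of $|x|$. After zero-phase low-pass
  filtering the plain signed mean is ≈ 0, which would make the elevation a
  no-op and defeat its purpose; the signed mean is still available via
  `mean_mode = "signed"`.
* **Windows are centred with reflection padding**, keeping every stage
  length-preserving and the ZCR/envelope peaks time-aligned with the bursts
  they summarise — which matters when peaks feed a 20 s matching rule.
* **Duration gate vs reported duration.** The 30 s threshold applies to the
  supra-threshold *run length* (what the threshold crossing defines); the
  *reported* duration is the half-wave width, the clinical definition. Both
  readings are deliberately kept distinct.
* **Exact zeros in the ZCR** carry the previous sign regime. In floating
  point, exact zeros essentially never occur in real signals; the rule
  matters only for constructed inputs and is implemented to match the
  regime-transition reading.
* **Ties** (equal envelope maxima, equal matching gaps) break toward the
  earlier sample/peak, making every stage deterministic.
* **Complexity.** The sliding ZCR and RMS are computed with cumulative sums
  in O(n); the naive per-window recount (O(nW), ~4.5 × 10⁹ operations for a
  30-min recording) exists only as a test oracle.

## The synthetic generator

No public EHG corpus matches the bespoke-device recordings this method
targets, so the package ships a seeded generator used by every end-to-end
test:

* each contraction is a burst of band-limited Gaussian fast-wave activity
  (0.3–1 Hz by default) multiplied by a raised-cosine (Hann) slow-wave
  envelope. The planted *duration* (drawn uniformly from 30–60 s) is the
  envelope's FWHM — the clinical definition of UC duration — so the Hann
  bump spans twice that duration at its base;
* the burst train is shared across the 8 EHG channels (uterine activity is
  common-mode across electrodes) while white background noise (sd 2,
  against burst RMS amplitude 10) is independent per channel;
* the narrowband fast wave is synthesised at a decimated rate and
  spline-interpolated up to 250 Hz, because a 0.3–1 Hz IIR band-pass
  designed directly at 250 Hz is numerically degenerate;
* TOCO carries a Hann bump per contraction (height 40 over a baseline tone
  of 10, transducer noise sd 1);
* perception labels are burst centres jittered uniformly by ±10 s, each
  dropped with probability 0.1 — perception suggests a contraction but not
  its onset, peak or end, and not every contraction is reported;
* burst centres are placed uniformly at random with a minimum separation
  that keeps whole bump bases from overlapping (2 × the maximum duration,
  plus 10 s); all randomness derives from one seed and the global RNG state
  is left untouched.

What the generator does **not** emulate: electrode geometry and propagation,
motion artifacts, baseline wander, obesity effects, or the spike-train
micro-structure of real fast waves. Passing end-to-end tests therefore shows
the pipeline recovers bursts of the stated morphology at the stated
signal-to-noise ratio — not clinical performance.

## Known limitations

* **Null recordings.** Min–max normalisation guarantees the ZCR weight
  reaches 1 somewhere in every recording. On a recording with *no* genuine
  bursts, noise-driven weight fluctuations (on the 40 s ZCR window scale)
  still produce supra-mean envelope runs longer than 30 s, i.e. spurious
  detections. The detector presumes at least one genuine burst per
  recording; a burst-free recording yields a handful of false positives
  rather than silence.
* **Duration noise on narrowband bursts.** The 10 s RMS of a 0.3–1 Hz
  Gaussian burst retains ~19 % relative envelope fluctuation (Rayleigh
  fading), so the first-crossing half-wave width occasionally collapses to
  the width of a single envelope spike. On synthetic cohorts the recovered
  durations correlate with the planted ones only moderately (rank
  correlation ≈ 0.5–0.85 across cohort seeds, systematically shortened);
  supra-threshold run lengths track planted durations much more tightly
  (≈ 0.9). Real fast waves are less coherent than narrowband Gaussian
  noise, so real envelopes fade less deeply, but reported durations should
  still be read as envelope-relative, not anatomical.
* **The α-sweep shape is cohort-dependent.** On this synthetic model the
  3 Hz-low-passed *white* background crosses zero more often than the
  0.3–1 Hz burst, so without elevation (α = 0) the normalised ZCR weight
  favours the background and detection collapses; sensitivity then jumps at
  α = 1 and drifts gently down as growing elevation narrows the weight
  support and short contractions start failing the 30 s duration gate.
  Monotone sensitivity/PPV trends over the whole α range, as seen on
  clinical cohorts, should not be expected here.

## Problem sizes used by the shipped tests

Unit tests run at reduced sampling rates (10–50 Hz) on minutes-long
signals, which exercises identical code paths since every window is
specified in seconds. The end-to-end acceptance checks use a 10-recording
cohort at the full 250 Hz / 30 min geometry (≈ 4.5 × 10⁶ samples per
channel in total) and a 450,000-sample oracle-equivalence check at the
exact W = 10,000 / N = 2,500 window sizes.
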