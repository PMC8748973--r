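---
title: "Methods: arterial pulse reconstruction and cuffless BP estimation from a Bio-Z sensor array"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: arterial pulse reconstruction and cuffless BP estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A wrist-worn bio-impedance (Bio-Z) sensor array measures the pulsatile
volume change of the radial artery through the tissue: each of K = 6
channels sees the same hidden arterial pulse `Y`, filtered by a transfer
function `h_k` that depends on where that electrode column sits relative to
the artery. Blood-pressure (BP) estimation from pulse *morphology* is
therefore fragile under sensor displacement: a model trained at one
placement sees systematically different features at another. The package
implements a calibration-free answer: reconstruct `Y` itself from the
channel ensemble with an unsupervised linear convolutional autoencoder, and
regress BP on features of the reconstruction rather than of any single raw
channel.

## Signal model and the synthetic generator

Real multi-channel Bio-Z recordings with beat-wise reference BP are not
publicly deposited, so the package ships a generator implementing the same
sensing model the algorithms assume, with full ground truth:

* **Source pulse.** One beat is the negative of a volume pulse built from a
  sharp systolic bump (Gaussian rise, Gaussian-to-exponential decay), a
  broad diastolic "runoff" component, and a Gaussian dicrotic (reflected)
  wave. This family was chosen so that every beat has exactly the six
  canonical characteristic points — diastolic peak (DIA), maximum slope
  (MS), systolic foot (SYS), and the inflection point (IP) flanked by the
  dicrotic peak (DP) and notch (DN) — as genuine extrema/zero-crossings, and
  so that the dicrotic pair remains present over the whole BP coupling
  range. Each beat's contribution to the continuous signal extends over
  three periods with a cosine taper on the final half period; without the
  taper, truncating the slow runoff tail leaves sample-level steps exactly
  in the dicrotic region (an early version did, and the notch detector
  found the glitches instead of the notch).
* **BP coupling.** Per-beat (SBP, DBP) modulate the shape monotonically:
  higher SBP steepens the upstroke (`systolic_width x (1 - 0.25 u_s)`),
  higher pulse pressure enlarges the dicrotic wave (`x (1 + 0.40 u_p)`),
  higher DBP advances the reflection and fills the diastole. The field's
  claim that morphology features correlate with BP is thus true *by
  construction* in the generator; what the tests establish is that the
  pipeline recovers it through preprocessing, reconstruction and
  regression.
* **Transfers.** Each channel's FIR filter attenuates
  (gain `1/(1 + 0.6 d)`), smooths (tap width `0.6 + 15 d` samples at
  250 Hz), delays (`4 d` samples) and reshapes (a trailing negative lobe
  growing with `d`) the source, where `d` is the channel's column distance
  to the artery plus a seeded row offset. `POS2`/`POS3` shift the artery one
  column; `Re-Attach` draws a random offset. The true `h_k` of skin-mounted
  electrodes are unknown in the literature; these families are stand-ins
  whose only asserted properties are location dependence and monotone
  degradation with distance.
* **Scales.** DC near 50 Ohm with a bounded, spline-smoothed random-walk
  drift (band-limited far below 0.05 Hz by a 20 s knot spacing); pulsatile
  peak-to-peak 50-150 mOhm; white measurement noise at a configurable SNR
  (20 dB in the study conditions); heart rate 65 beats/min with AR(1)
  period jitter. The sampling rate defaults to 250 Hz — high enough that
  the +/- 2-sample fiducial tolerance is ~8 ms — and is configurable.
* **BP trials.** Each trial is a handgrip ramp of ~50 mmHg over ~3 min, a
  1 min cold-pressor hold, and ~3.5 min of exponential recovery, with AR(1)
  beat-wise jitter; DBP follows at 45% amplitude. Twelve trials across four
  sensing locations mirror a realistic protocol; reduced beat counts are
  used in tests (problem sizes below).

What the generator does **not** emulate: motion artifacts, electrode-skin
contact impedance changes, arrhythmias, baseline wander faster than
0.05 Hz, or inter-subject variability. Green tests therefore demonstrate
algorithmic correctness under the stated sensing model, not clinical
performance.

## Preprocessing

The heart rate is the largest power-spectral-density peak in 0.6-3.5 Hz
(window up to 2.5 min). Max-slope points are the lower peaks of the first
derivative of the (zero-phase, 15 Hz low-passed) raw signal, constrained by
a minimum distance of `0.57 / HR` and a minimum height of 35% of the
lower-peak envelope — the envelope being a natural cubic spline through
derivative lower peaks at least 0.65 s apart. The 35% rule is only
dimensionally coherent if the envelope lives in derivative units, so the
envelope is computed on the first derivative's lower peaks (the source text
attaches it ambiguously to the raw signal). The DC component is a monotone
piecewise-cubic (Fritsch-Carlson) interpolation through the raw values at
the MS anchors, extended flat at the ends — monotone interpolation cannot
overshoot between anchors, which keeps the "DC" inside the signal envelope;
`raw = DC + pulsatile` holds exactly by construction, and the pulsatile
signal is zero at every anchor.

## Beats and segments

Beat boundaries are the MS points of the highest-amplitude channel, applied
to all channels: the N x K x L segment array needs one common beat grid,
and the per-channel group delays of a few samples are small against a
~230-sample beat. Each beat is linearly resampled to L = 64 points and
scaled per channel to unit peak-to-peak (stored for inversion). Training
segments of N = 8 beats slide over the concatenated normalized-beat stream
with a hop of `0.1 L = 6` samples, read as a sample-domain hop in
normalized time (the alternative per-beat reading would give 10x fewer,
fully beat-aligned segments). (N, L, F) = (8, 64, 9) are package defaults
in lieu of values tabulated only in supplementary material not available
here; all are configurable.

## The linear convolutional autoencoder

The encoder is a single N x K x F convolution window sliding along the
normalized-time axis (stride 1, zero padding, linear activation, zero
bias): `code[t] = sum_{n,k,f} W[n,k,f] seg[n,k,t+f-floor(F/2)]`. The
decoder re-synthesizes every (beat, channel) slice from the code with an
independent F-tap FIR kernel, also linear and bias-free. The parameter
count is exactly `2 N K F` (864 at the defaults). Because the decoder must
reproduce each channel from the code through only F taps, a code that is a
heavily coloured version of the common pulse would need approximately
inverse kernels that F taps cannot represent; minimizing reconstruction
error therefore pushes the code towards a delay/scale version of the
shared source. The residual scale and sign indeterminacy of any linear
autoencoder is resolved at use time: the reconstruction is re-signed so its
dominant intra-beat edge falls (the Bio-Z convention) and re-scaled to unit
peak-to-peak per beat.

Training minimizes mean squared reconstruction error with Adam. Defaults:
learning rate 3e-3, batch 64, at most 80 epochs; when the epoch loss
plateaus (no relative improvement of 1e-3 over 10 epochs) the learning
rate drops by 0.3x, twice, before training stops. The model is linear, so
the loss surface is benign and convergence is fast; these values were
chosen after observing convergence within ~10 epochs on 300-beat
recordings. Consecutive segments at hop 6 overlap by ~98%, so training
caps the segment set at `max_segments = 600` evenly spaced segments — the
information content is in the beats, not in the near-duplicate windows.
Gradients are analytic (the model is a bilinear form in encoder and
decoder) and are verified against numerical differentiation in the test
suite. For the *noiseless identity-chain* check (delta transfers, zero
noise), training is run to a much tighter plateau (300 epochs, tolerance
1e-6): the near-unity correlation target is a statement about the
converged optimum, and the default early stop leaves a visibly coloured
code (~0.99).

Source-recovery fidelity is scored by normalized cross-correlation
maximized over lags within 5 samples (20 ms) on a quarter-sample grid
(`ncc_best_lag()`). The MSE objective is exactly flat along solutions
whose code is a slightly *delayed* copy of the source (the decoder absorbs
the opposite delay), so which delay training lands on is arbitrary;
zero-lag correlation would charge ~0.5% per sample of that arbitrary
shift. Scale and sign, the other two indeterminacies, are resolved at use
time as described above.

For continuous output the encoder kernels are linearly interpolated from
their F normalized-time taps onto each beat's original-rate grid (scaled by
`F/F_up` to preserve gain) and applied to the original-rate,
amplitude-normalized channels; each beat uses the N-beat window centred on
it, with neighbouring beats' contributions phase-resampled onto the target
beat. One autoencoder is kept per sensing location (`AE1`-`AE4`) — the
registry mirrors how an unsupervised model would simply be retrained in
place after the band moves, since no labels are needed.

## Characteristic points and features

Detection windows start a quarter period before each MS anchor so the
preceding diastolic peak is inside the window. Derivatives are taken after
Savitzky-Golay smoothing (order 3, ~60 ms window): unlike a Butterworth
low-pass, it preserves the position of the shallow dicrotic extrema, which
otherwise shift by several samples. MS is the deepest derivative minimum;
DIA/SYS are the adjacent derivative zero crossings; the dicrotic complex is
the most prominent secondary derivative minimum after SYS (threshold: 2% of
the MS depth — below that the "notch" is indistinguishable from noise and
the beat is flagged dicrotic-absent rather than given fabricated points),
with IP at the second-derivative zero crossing and DP/DN at the flanking
first-derivative crossings. All crossings are localized at sub-sample
resolution by linear interpolation; equal-depth candidates resolve to the
earliest.

The 15 features per beat: three DIA-to-{MS, SYS, IP} times over the
inter-beat interval `T_IBI` (MS-to-MS); two DIA-to-{MS, IP} amplitude drops
over the foot-to-peak amplitude `A_SYS`; three trapezoidal areas from DIA
to {MS, SYS, IP} over the full-pulse area (areas integrate the min-shifted
beat at integer samples — sub-sample endpoints would change the oracle
comparison without adding information); the dicrotic amplitude
`(A_DP - A_DN)/A_SYS` and time `(t_DN - t_DP)/T_IBI`; and the fractions of
samples in five equal bins of the amplitude-normalized beat (fractions, so
the histogram is independent of beat length). Beats with an absent dicrotic
complex carry missing values for the five IP/dicrotic-dependent features,
imputed by the per-subject median of valid beats before regression.

## BP regression and evaluation

Separate per-subject models map features to SBP and DBP: AdaBoost.R2 with
squared loss over depth-8 regression trees, 32 rounds. Trees are fitted
with sample weights rather than weighted resampling, which makes training
deterministic for a fixed seed without changing the estimator in
expectation; prediction is the classical weighted median. The tree depth is
fixed at 8 rather than selected on test error — selecting complexity on
the test fold would leak the held-out data into model choice. Reference BP
is smoothed by a centered 20-beat moving average, and predictions are
smoothed the same way ("BP averaging"); the window mirrors the reference
smoothing since the averaging step is otherwise unspecified.

Reports carry ME, SD of error, RMSE, Pearson R and the British Hypertension
Society cumulative percentages (<=5/10/15 mmHg; grade A at 60/85/95). Three
protocols: contiguous 20-fold cross-validation on the primary location
(contiguous blocks, sizes within one beat, because the folds represent
~2 min test spans, not random beats); leave-one-trial-out; and
cross-location (train on the first four primary-location trials, test per
location with that location's autoencoder).

## Problem sizes used in tests and the acceptance script

Source recovery uses 300 beats at 20 dB SNR (and a 120-beat noiseless
delta-transfer run); fiducial accuracy uses ~500 noiseless beats; BP
recovery uses ~2900 beats over six trials; the cross-location property uses
20 seeded replicates of ~150 beats per location with a 40-epoch,
300-segment autoencoder per side. These sizes keep every beat count in the
regime the corresponding claim is about while staying desk-runnable; the
full-scale defaults (12 x ~490-beat trials) remain available through
`pipeline_config()`.

## Known limitations

* The generator's transfer functions are plausibility stand-ins; nothing
  calibrates them to tissue measurements.
* The BP-to-morphology coupling is injective by design; on real data the
  feature-BP relation is noisier and partly non-stationary, and the
  regression ceiling will be far below the synthetic one.
* The autoencoder assumes a linear, time-invariant source-to-sensor path
  within a recording; motion and contact changes violate this.
* Edge beats (first/last of a recording, where the N-beat window is
  clamped and the detection window leaves the series) are discarded or
  reconstructed with reduced context.
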