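---
title: "Detecting and coordinating sleep downstates and spindles with ctcoord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and coordinating sleep downstates and spindles with ctcoord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

During non-REM sleep the cortex and thalamus produce two hallmark events:
slow-oscillation *downstates* (DSs) — hyperpolarized, near-silent periods
visible as 0.1–4 Hz troughs with suppressed 60–100 Hz ("high-gamma")
activity — and *spindles*, 10–16 Hz oscillatory bursts of roughly 0.5–2 s
generated in the thalamus. In simultaneous bipolar depth recordings the
two structures show a stereotyped sequence: cortical DSs converge on the
thalamus and induce thalamic DSs after roughly 200 ms; the thalamic
hyperpolarization releases a spindle at the thalamic DS peak; and the
spindle is projected focally back to cortex with a conduction delay of
about 15 ms, arriving during the cortical down-to-upstate transition
(~250 ms after the cortical DS peak).

`ctcoord` implements the full measurement chain for this phenomenon:
event detection (DSs and spindles), per-channel spindle classification,
coordination statistics (peri-event histograms, temporal-order tests,
conditional probabilities, delay estimators, enrichment and coupling
proportions), detector evaluation, and a synthetic generator that
produces recordings with known ground truth so every stage can be
validated quantitatively.

## Downstate detection

The slow-wave detector band-passes each channel to 0.1–4 Hz with a
zero-phase 4th-order Butterworth filter (the squared-magnitude,
zero-phase response of forward–backward application; edges are handled by
reflection padding long enough for the 0.1 Hz component to settle).
Consecutive zero crossings 0.25–3 s apart delimit half-waves; the
extremum between the crossings is the wave peak. Per channel and sign,
only the `keep_fraction = 0.40` most extreme peaks are retained
(`floor(n * 0.40)` per sign, ties broken toward the earlier peak); a
strict mode uses 0.25–1 s crossings and the bottom 20%.

Which sign is the downstate is decided from high-gamma behaviour, because
bipolar derivations have no fixed polarity convention:

* **Cortex** — the sign whose peak-locked mean 60–100 Hz envelope within
  ±250 ms of the peak is reduced relative to the epoch-wide (±3 s)
  baseline is the DS. A two-sample t-test between the per-event
  modulations of the two signs (p < 0.05) guards against assigning
  polarity from chance asymmetry; otherwise the channel is excluded with
  a "polarity undetermined" error.
* **Thalamus** — baseline high gamma is nearly absent, so the DS sign is
  the one whose peaks are followed by larger 10–16 Hz (spindle-band)
  Hilbert amplitude within 0–500 ms *and* a high-gamma increase at the
  down-to-upstate transition (100–400 ms after the peak). The increase is
  judged against the immediately pre-peak gamma (−600 to −100 ms) rather
  than the wide epoch mean, which would be inflated by neighbouring
  transitions. The assignment is validated by splitting the DSs into the
  top and bottom deciles of spindle-band amplitude and requiring a
  significant (one-sided, p < 0.05) transition increase in both strata —
  i.e. even DSs without spindles must show the rebound signature.

Artifact rejection then removes any event whose epoch (±3 s around DS
peaks, −2 to +4 s around spindle onsets) contains a sample-to-sample step
larger than the channel's difference threshold, or an absolute value
above 7 SD of the pooled absolute epoched signal. Two automated choices
replace per-channel visual settings of the original workflow and are
recorded in the output attributes: the difference threshold defaults to
10× the channel's median absolute first difference, and the pooled SD is
computed over the epochs of the *pre-exclusion* event set, so that
artifact-contaminated epochs contribute to the threshold before being
rejected (computing it only over clean epochs would place the threshold
at the clean-signal maximum and reject physiological event stacks).

## Spindle detection

Two detectors are implemented. The *envelope-threshold* method
(`previous_method_detect`) detects events where the gaussian-smoothed
(300 ms window, 40 ms sigma) Hilbert envelope of the 10–16 Hz signal
exceeds mean + 3 SD (cortex) or mean + 1.5 SD (thalamus), with
boundaries at the mean + 1 SD crossings and durations of 0.3–2 s.

The *candidate-epoch classifier* proceeds in two steps. First, the
rectified 10–16 Hz signal is smoothed with unit-sum Tukey moving averages
of 400 ms (the *edge envelope*, defining onsets/offsets) and again with
600 ms (the *amplitude envelope*, locating candidates). The candidate
threshold is the smallest amplitude-envelope peak over the manually
marked spindles of that channel; every amplitude-envelope peak above it
becomes a candidate whose boundaries are the contiguous region where the
edge envelope is at least 45% of the nearest edge-envelope peak. Epochs
under 300 ms are dropped and overlapping epochs merged.

Fifteen features per candidate feed a per-channel logistic regression:
envelope amplitude and duration; FFT amplitude-spectrum features of the
mean-removed raw segment zero-padded to at least 4 s (0.25 Hz
resolution): maximal 10–16 Hz amplitude, maximal 5–8 Hz amplitude, their
ratio, and the 10–16 Hz argmax frequency; band-envelope maxima at
10–16 / 4–8 / 18–25 Hz; the sleep-stage indicator (N3 = 1); and
oscillation-peak statistics of the band-passed segment (count with
prominence ≥ 10% of the segment envelope peak, rate, inter-peak interval
mean and SD, and an indicator for a 10–16 /s peak rate). Features are
screened by iterative VIF pruning (remove the largest VIF while it
exceeds 10, computed as 1/(1−R²); exact collinearity removes the
larger-index column first), then selected by bidirectional stepwise AIC
from the full model. Complete separation — common on well-separated
training data — is handled by refitting the selected model with a small
ridge penalty (λ = 0.05 on standardized predictors) and a warning. An
optional bootstrap reports per-feature selection frequencies.

The probability cutoff is chosen by leave-one-out cross-validation on
the labelled candidates: thresholds are scanned from 0 to 1 in 0.5%
steps and the one minimising |FPR − FNR| is kept, with
FNR = FN/(TP+FN) and — following the printed definition of the source
method — FPR = FP/(FP+FN). This convention is unusual (the conventional
false-alarm rate is FP/(FP+TN)) and is deliberately not "fixed": a
`fpr_convention = "standard"` switch is available. Rates with zero
denominators count as 0 and ties resolve toward the lower threshold.
Applying the classifier scores every candidate of the channel, keeps
those at or above the cutoff, removes events outside N2/N3 or touching
excluded intervals, and applies the −2/+4 s artifact screen. Events are
classed *slow* (≤ 12 Hz) or *fast* (> 12 Hz) by their spectral peak.

## Coordination statistics

Peri-event histograms count every (reference, target) pair within the
lag window into 50 ms bins with edges at multiples of 50 ms. The
temporal-order test counts target events before versus after each
reference within ±500 ms (all pairs by default; a nearest-only mode is
available) and applies a two-sided exact binomial test at success
probability ½, Bonferroni-corrected across channel pairs. The
cortico-thalamic DS delay averages the 0.1–4 Hz cortical signal locked
to thalamic DS peaks over events preceded by a cortical DS within
500 ms, and takes the waveform minimum in [−0.5, 0] s per pair. DS onset
is estimated as the real root of the second derivative of a degree-20
polynomial fitted on a time axis normalised to [−1, 1] (for
conditioning), nearest to the visually determined guess.

The thalamo-cortical spindle lag uses the 55–100 Hz analytic amplitude
averaged over consecutive subsets of 500 thalamic spindle troughs; each
subset's average waveform is spline-interpolated and its peak located
within ±35 ms of the trough, and the delay is the cortical minus the
thalamic peak time with a paired t-test across subsets. Averaging before
peak-finding is essential: per-trough peak localisation is biased toward
zero by envelope noise.

The enrichment factor is (20·60·count in the tallest 50 ms bin within
±500 ms of DS peaks / n_DS) divided by the overall spindle density per
minute. The coupling proportion counts spindles starting within
[0, +0.75] s of a DS peak (cortex) or [−0.5, +0.25] s (thalamus),
normalised by the channel's DS count relative to the subject maximum.
For the conditional-probability matrix, each off-diagonal cell is tested
against its *complement* (reference-channel DSs without a DS on the
conditioning channel) rather than against the diagonal: the diagonal
contains the conditioned events as a subset, which makes the nominal
two-proportion chi-square structurally conservative (measured type-I
error ~0.027 at nominal 0.05), whereas the complement split is disjoint
and calibrated (measured 0.050).

## The synthetic generator

`sim_config()` defaults encode the study conditions: 30 min at 256 Hz,
4 cortical and 2 thalamic channels, cortical DS rate 16.3/min,
cortical→thalamic DS lag 218 ± 66 ms, thalamic spindles released at the
thalamic DS peak with probability matched to a 7.1/min thalamic spindle
rate, and thalamo-cortical projection with a 15 ms lag — focally (0.9
probability) to one primary cortical channel per thalamic channel, and
diffusely to the rest at a rate matched to 5 spindles/min per cortical
channel. Thalamic DSs arise from clusters of near-simultaneous cortical
DSs (linkage gap 0.25 s) with probability increasing in the number of
participating channels; the defaults (0.25, 0.46, 0.62, 0.72 for k =
1…4+) were chosen so the emergent thalamic DS rate is ~11.5/min.

Waveform morphology: a DS is a 500 ms negative half-sine with a 40%
positive rebound over the following 500 ms; a spindle is a sinusoid with
a fast (~120 ms) rise and a slower waning tail — a symmetric window
would delay envelope-detected onsets by ~125 ms relative to the
scheduled onset and misplace the coupling histograms. Cortical DS
renewal uses a shifted-gamma inter-event distribution (hard minimum
period 1.1 s, mean preserved) and thalamic DSs are refractory for 1.1 s,
because overlapping rendered DS templates are unphysical (a structure
cannot hyperpolarize twice at once) and their summed troughs trip the
amplitude artifact screen. Spindle amplitudes have a visibility floor
(0.7 and 0.6 of the regional median for cortex/thalamus): the marked
spindle population that defines the candidate threshold consists of
events distinguishable from the sigma background.

The background has four components per channel: 1/f^a noise with a
regional exponent and a low-frequency roll-off emulating the
acquisition high-pass; ongoing 0.5–2 Hz delta noise; ongoing 6–22 Hz
sigma noise with brief irregular "burst" bumps (0.25–0.6 s, refractory)
that produce the non-spindle candidate epochs a human marker would leave
unmarked; band-limited (> 4 Hz) broadband instrument noise; and a
60–100 Hz carrier whose amplitude is suppressed during cortical DS
troughs, raised at thalamic down-to-upstate transitions, burst-modulated
at spindle troughs (emulating spindle-locked population firing, with a
smooth firing-rate saturation), with a low thalamic baseline. Sharp
rectangular artifact pulses (~400 µV, 0.3/min) are injected and exported
as exclusion intervals, emulating the clinically marked bad periods; they
also give the 7-SD amplitude screen the heavy-tailed context it assumes.

Two families of parameters were calibrated once, against their design
targets, and then frozen:

* the regional background shape (`noise_exponent`, `noise_hp_hz`,
  `delta_amp`) sets the spontaneous 0.1–4 Hz half-wave rate so that the
  scheduled DSs make up approximately the bottom 40% of negative peaks —
  mirroring the original calibration of the 40% retention threshold to
  the real DS population; and
* the distractor-burst amplitude and rate balance a usable supply of
  non-spindle training candidates against label consistency: bursts are
  strictly shorter than true spindles (0.25–0.6 vs 0.9–1.8 s), since a
  long, strong, coherent in-band burst would be indistinguishable from a
  spindle and a human marker would have marked it.

What the generator does *not* emulate: volume conduction (bipolar
derivations exclude it by design), across-channel correlated noise,
biophysical spindle waxing dynamics, epileptiform discharges beyond
simple pulses, sleep-stage-dependent event rates, and inter-subject
variability. Passing the recovery tests therefore demonstrates that the
pipeline measures what it claims under realistic SNR and event
statistics, not that it would reach the same numbers on any given
patient recording.

## Numerical choices and problem sizes

* Filters: zero-phase Butterworth filtering is applied exactly in the
  frequency domain as the squared analog-prototype magnitude response
  (what forward–backward application computes), because the time-domain
  recursion of the 8-coefficient band filter is numerically unstable for
  narrow normalized bands such as 0.1–4 Hz at 256 Hz. Mirror-reflection
  padding of `3 * rate / low_hz` samples, tapered to zero at the outer
  ends, suppresses edge and wrap-around transients; FFT lengths are
  rounded up to 2-3-5-smooth sizes. The one-directional variant uses the
  `signal` package's recursive filter.
* The analytic signal is computed by the standard FFT construction
  (negative frequencies zeroed, positive doubled) after mean removal.
* The event-locked spectrogram uses a 0.5 s Hann window stepped by
  25 ms, baseline-corrected by the epoch-wide mean per frequency (dB),
  with significance from circularly shifted surrogate event sets
  (200 by default), two-sided, uncorrected.
* Degree-20 polynomial fits use a raw-coefficient least-squares fit on a
  [−1, 1]-normalised axis; inflections come from `polyroot` on the
  twice-differentiated coefficients.
* Validation problem sizes: module tests run on 5–10 min simulations;
  the acceptance suite uses a single 30 min recording (fixed seed) plus
  1,000-replicate null simulations for the calibration checks. These
  sizes keep the entire suite within a normal CI budget while leaving
  every statistic with comfortable margins.

## Known limitations

The classifier's cutoff rule (equalising the printed FPR/FNR) is
sensitive to single unusual non-spindle candidates when the training
classes are nearly separable, since the optimum then sits just above the
highest-scoring non-spindle; this mirrors the printed procedure and is
visible in per-channel sensitivity fluctuations. The automated
difference threshold and TN convention (unmatched non-spindle candidate
epochs) replace per-channel manual choices of the original workflow and
are flagged in outputs. EDF support covers the common uniform-rate
16-bit layout only.
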