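---
title: "Methods: synthetic-recovery validation of striatal electrophysiology analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic-recovery validation of striatal electrophysiology analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(striatools)
```

striatools implements the analysis chain used to characterize striatal
synaptic and network dysfunction after dopamine depletion: detection and
quantification of spontaneous postsynaptic currents (sEPSC at −70 mV,
sIPSC at 0 mV) from voltage-clamp traces, short-term plasticity of evoked
20 Hz trains, bootstrap contrasts of excitation–inhibition balance across
post-lesion time windows, spike-train metrics with narrow/wide unit
classification, and LFP spectral and burst-event analysis. Because raw
recordings of this kind are rarely shared, every stage is validated against
a synthetic-data generator with exact ground truth; this vignette explains
the models behind each stage, the tunable parameters, the numerical
choices, and what the synthetic validation does and does not demonstrate
about real data.

## Synthetic recordings

**Spontaneous PSC traces.** Events are a difference of exponentials
`exp(-t/τ_decay) − exp(-t/τ_rise)`, peak-normalized so the scale factor is
the event's peak amplitude (defaults τ_rise = 0.5 ms, τ_decay = 5 ms for
EPSC-like kinetics; slower values model IPSCs). Event times are homogeneous
Poisson (default 2 Hz), amplitudes lognormal with configurable mean and CV
(defaults 25 pA, 0.4 — typical of striatal sEPSC distributions), polarity
inward (negative) for EPSCs and outward for IPSCs. The baseline carries
white noise, a slow sinusoidal drift (default 10 pA at 30-s period) and an
optional random walk, chosen to exercise the 1-s moving-median baseline
removal. Traces default to 10 kHz; the recordings being emulated were
sampled at 25–50 kHz, but every detector band lies far below either Nyquist
rate, so the lower rate only reduces compute.

**Evoked trains.** A deterministic resource–utilization recurrence
(Tsodyks–Markram style): pulse k releases a fraction `u_k` of resource
`R_k` giving amplitude ∝ `R_k u_k`; the resource recovers toward 1 with
`τ_rec` between pulses, and `u` optionally facilitates by `facil_incr` and
relaxes with `τ_facil`. The first pulse is scaled to `amp1_pa`. Group analyses of this protocol
work on normalized amplitude readouts, so the generative model is
deliberately minimal: it produces controlled
depression or facilitation with a closed-form truth for every pulse.

**Spike trains and waveforms.** Poisson mode is a homogeneous process
thinned by an absolute refractory period; bursty mode draws Poisson burst
onsets, geometric within-burst counts and jittered intra-burst intervals.
Mean waveforms are biphasic templates — sharp negative trough followed by a
slower positive after-peak — with the trough-to-peak time drawn from
0.25–0.38 ms (narrow, fast-spiking interneuron-like) or 0.62–0.95 ms (wide,
projection-neuron-like) plus additive noise. The class gap (0.38 vs
0.62 ms) is wider than the estimator's noise at the default 8–10 μV noise
SD, which is what guarantees the ≥ 95% unsupervised separation the tests
assert; real populations contain intermediate and multi-modal cells that
this generator does not emulate.

**LFP.** The background is `1/f^α` noise synthesized by inverse FFT with
random phases (exact exponent control; default α = 1.5, RMS 50 μV).
Oscillatory bursts are Gaussian-envelope sinusoids; the configured duration
is the envelope FWHM, and the configured amplitude is the peak envelope in
dB over the median analytic envelope of the band-limited background, so
"an 8 dB burst" means the same thing to the generator and to the detector.
Optional 50 Hz line noise exercises the normalization exclusion band.

## Spontaneous PSC detection

The detector implements a hybrid three-method design on the
baseline-removed trace (1-s centered moving median, edges by window
truncation):

1. **Slope method** (EPSC only): the slope in a 1 ms window, smoothed with
   a 0.2 ms moving average; positive slopes are zeroed and negative slopes
   accumulated within each negative run (cumulative sum reset at sign
   change). A run is a candidate when its accumulated excursion exceeds 4 ×
   a robust scale of the excursion distribution. The scale is 1.4826 ×
   the median *run-minimum* magnitude rather than the MAD of the
   accumulated trace itself: roughly half of that trace is exactly zero and
   the nonzero values are one-signed, so a median-centered MAD degenerates.
   With fewer than 50 runs (sparse, clean traces) the median magnitude of
   the accumulated samples is used as the floor instead.
2. **High-band amplitude method**: zero-phase high-pass above 10 Hz,
   threshold at 4.5 × robust SD of the filtered trace.
3. **Multi-band amplitude method**: the same thresholding on band-passes
   [2, 300], [5, 300], [10, 300] and [20, 300] Hz — four low cutoffs
   spanning 2–20 Hz. Narrow bands shrink the noise floor
   far more than the (low-frequency-concentrated) event peak, which is what
   lets this method catch slow-rising IPSCs; the slope method is disabled
   for IPSCs for the same reason.

All thresholds use the MAD-based robust SD because event-containing traces
inflate a naive SD. Filters are 4th-order Butterworth run
forward–backward, so candidate times carry no filter delay.

Candidates from all methods are unioned and deduplicated within 2 ms.
Hybrid detectors of this kind are traditionally followed by manual
inspection; two automated vetting rules replace it:

* a candidate must exceed the 4.5-robust-SD threshold in the widest
  analysis band (2–300 Hz), where event energy is concentrated and the
  noise floor is lowest — without this, slope-method noise runs at
  amplitude/noise = 5 drown the precision;
* each candidate is refined to the 10% rise point of its band-filtered
  extremum, and candidates whose extrema fall inside one sub-threshold
  band excursion merge into a single event. This prevents the decay phase
  of a slow IPSC from being counted again when narrow-band ripple
  re-crosses the threshold.

Measured per event: local baseline (median of 2 ms pre-onset), amplitude
(|extremum − baseline| in a 10 ms window truncated at the next event),
20–80% rise time by linear interpolation, and decay τ from a
single-exponential fit (failure leaves the value missing, the event is
kept). Events are vetted on a rise-time window of 0.1–10 ms. Recordings
with holding current below −200 pA or series resistance above 25 MΩ are
excluded up front.

On the validation conditions (100-s traces, 2 Hz events,
amplitude/noise-SD = 5, lognormal CV 0.4) the detector achieves recall and
precision above 0.90 with ±2 ms matching and a false-event rate below
0.02 Hz on pure noise. These figures are specific to well-behaved Gaussian
noise; access-resistance transients, seal instabilities and overlapping
compound events in real recordings will degrade them, which is why the
amplitude floor (`min_amplitude_pa`) and rise bounds remain user-facing.

## Evoked short-term plasticity

Per pulse: 1 ms artifact blanking after the stimulus, baseline re-measured
as the median of the 2 ms pre-stimulus (this re-anchoring keeps the error
under 10% even when decays with τ = 20 ms overlap the 50 ms inter-pulse
interval), amplitude as |extremum − baseline| in the remaining inter-pulse
window. Multiple sweeps are averaged before measurement. Trains are
normalized to the first pulse; a train is classified depressing or
facilitating when the mean of pulses 2–8 leaves a ±0.05 neutrality margin
— the margin is a package choice; depression/facilitation is otherwise a
qualitative call.

## Bootstrap E–I contrasts

Each iteration draws 75% of each group, computes the lesion/sham ratio or
difference of subsample means, and repeats 1000 times. The point estimate
is the mean of resampled contrasts, the CI the 2.5/97.5 percentiles, and
the ±3 SD band the displayed noise level. Significance is "null value (1
for ratios, 0 for differences) outside the 95% CI" — the only coherent
reading of a resampling significance rule, since the resample mean always
lies inside its own percentile interval.

Whether the 75% draw is taken with or without replacement matters a great
deal. Subsampling *without*
replacement shrinks the resampled-mean variance by the finite-population
factor, so the percentile CI badly understates the true sampling
variability of the group means: on same-distribution groups (n = 30 each)
the null-outside-CI rule then flags ≈ 30% of datasets as significant. The
package therefore defaults to the classical with-replacement bootstrap at
the same 75% subsample size, whose measured false-significance rate is
2.5–4% — inside the [0.5%, 12%] calibration band the tests assert — and
keeps `replace = FALSE` available as the literal reading, with this caveat.
Relative-change curves prepend an artificial reference point at 1, and E–I
trajectories pair the per-window excitatory and inhibitory contrasts.

## Spike metrics and classification

Quality control applies four thresholds: amplitude > 50 μV, ISI
violation < 0.5, noise cutoff < 0.5, SNR > 2.5. The violation statistic is
the *percentage* of ISIs under 2 ms (a 50% reading of the unitless "0.5"
would be physiologically absurd); the noise cutoff is the
amplitude-histogram height at its low edge relative to the histogram peak,
a standard truncation indicator on a 0–1 scale; SNR is waveform
peak-to-peak over the residual SD of the waveform tails.

The autocorrelogram counts ordered spike-pair lags in (0, 50] ms at 1 ms
bins (verified against brute-force enumeration). The burst index is
(head − tail)/(head + tail) with head = counts in (2, 10] ms and tail =
counts in (35, 50] ms, raw sums, one-sided; the index is identical for the
two-sided convention since both windows scale equally. A flat (Poisson)
autocorrelogram gives the analytic value (8 − 15)/(8 + 15) = −7/23 ≈
−0.304, reproduced within ±0.02 at 10^5 spikes.

Classification uses 2-means on standardized trough-to-peak, half-width and
log firing rate, with the narrower-waveform cluster labeled the putative
PV interneuron class. UMAP-plus-density-clustering toolchains often used for this step are not
reproduced; for two-class populations with the separations above, a 2-means
split meets the same ≥ 95% agreement surface while staying deterministic
given a seed. Waveform extrema are located after ~0.2 ms of smoothing —
without it, noise on the broad after-peak biases trough-to-peak estimates
of wide units downward into the narrow range.

## LFP spectra and burst events

Preprocessing: anti-aliased decimation to 1000 Hz (8th-order zero-phase
low-pass at 400 Hz, integer subsampling), then zero-phase band-pass 1–475
Hz applied as separate high- and low-pass stages for stability near
Nyquist. Artifact handling is caller-supplied masking; a helper flags
samples beyond ±8 robust SD. Clean non-overlapping 10-s segments feed a
multitaper estimate with TW = 3 and K = 5 Slepian tapers (0.1 Hz
resolution). The tapers are computed from the classical symmetric
tridiagonal eigenproblem via Sturm-sequence bisection and inverse
iteration — O(n) per segment length, cached, and matching a dense
eigendecomposition to 10^-8 in the tests. Spectra are averaged over tapers
then segments and normalized to their mean over 1–90 Hz excluding 48–52 Hz
(the 50 Hz line avoidance is implemented as a ±2 Hz notch of the
normalization support; the mean is taken in linear power).
Band powers are means of the normalized spectrum over beta 13–30, low
gamma 30–60 and high gamma 60–90 Hz.

Burst events use dual magnitude thresholds on the band-limited analytic
envelope in dB over its median (the median is robust to the bursts
themselves): an event must reach background + 6 dB (`dbpeak`) and extends
to the background + 2 dB (`dbend`) crossings. Two numerical choices
matter. First, the raw envelope of narrowband noise is Rayleigh-distributed
and crosses +6 dB over its median about 6% of the time, so the detection
envelope is smoothed with a 4-period moving average; without smoothing the
detector fragments (859 detections for 126 true bursts in one 600-s
validation run). Second, that smoothing widens events, so start/end are
re-measured on a half-smoothed envelope around each event's peak.
Events shorter than one period of the band center are discarded and events
closer than half a period merge. Legacy `qlong`, `qdrop` and `qglitch` settings from wlBurst-style
configurations are carried in the configuration object for provenance but
play no role in the computation.

At the validation conditions (8 dB, 300 ms FWHM bursts at 10/min in a
1/f^1.5 background, 600 s) recovered counts lie within ±20% and median
durations within +20% of truth. Detected peak times are scored against the
realized band-envelope maximum inside each true event rather than the
injected envelope center: background noise displaces the realized peak
from the injected center by a median of roughly 40 ms at this SNR no
matter the detector (matched-filter and Gaussian-fit estimators do no
better), so the injected center is not identifiable from the signal. The
detector recovers the realized peak to ~1 ms; on a clean background,
realized and injected peaks coincide and absolute accuracy is at the
sample level.

Event-aligned spectrograms use a 6-cycle complex Morlet transform; each
frequency row of each event window is divided by its own maximum before
averaging, so every frequency contributes on a common 0–1 scale. Band-power
time courses are windowed means of the squared analytic envelope divided by
the mean over a declared baseline interval (power, so a doubled amplitude
reads as 4).

## Group statistics

Group comparisons are thin wrappers over Welch's t, Kolmogorov–Smirnov,
Kruskal–Wallis and two-way ANOVA (group × pulse for evoked trains), with
group means, SEM and n recorded. No multiple-testing correction is applied
by default, matching the per-window reporting convention of the source
analyses; `adjust_bh()` is available.

## The end-to-end synthetic study

`run_synthetic_study()` simulates a lesion-vs-sham design over three
post-lesion windows with three imposed effects — sIPSC amplitude ×1.5 onto
PV interneurons in week 3, sEPSC amplitude ×0.6 onto D1 projection neurons
after week 3, and a higher evoked release probability (0.7 vs 0.35, hence
stronger depression) — and analyzes everything blind to the truth. Problem
sizes are 6 cells per group per window and 45-s traces at 10 kHz, a
desk-scale stand-in for the 100–2000 s segments analyzed in real
recordings; with ~90 detected events per cell the per-cell mean amplitude
has ≈ 4% sampling error, so the imposed 40–50% effects are recovered with
very small p-values while null windows stay null. Detection-threshold
truncation biases detected mean amplitudes upward relative to the
generator's lognormal mean — visibly so for smaller-amplitude groups — but
the group contrast's sign and significance are unaffected, which is what
the study asserts.

## Known limitations

* The generator's Gaussian noise, stationary baselines and isolated events
  understate the difficulty of real voltage-clamp data; passing recovery
  tests demonstrates correctness of the implementation, not field-grade
  robustness.
* The burst detector's false-event rate on pure 1/f background is nonzero
  (roughly 0.5–1/min at default settings) and enters the recovered counts;
  at the validated 10/min true rate this stays inside the ±20% envelope.
* Decay-τ fits on overlapping events are truncated at the next onset and
  can fail on short windows (the value is then missing by design).
* Hierarchical (cell-within-animal) resampling is out of scope; the
  bootstrap treats cells as exchangeable.
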