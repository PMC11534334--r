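---
title: "Methods: detection, coupling and statistics in tmrsleep"
author: "tmrsleep maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection, coupling and statistics in tmrsleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tmrsleep` analyzes targeted-memory-reactivation (TMR) sleep-EEG
experiments: spoken cues are replayed during NREM sleep and the analysis
asks whether cue-evoked slow waves (SW) carry condition-dependent fast
spindle activity in their up-state, and whether behavior changes overnight.
This vignette documents the models and procedures, the tunable parameters,
the numerical choices, and what the synthetic validation does and does not
establish.

## Signal model and pipeline

The recorded EEG is treated as a superposition of

* an aperiodic 1/f^β background (NREM slopes β ≈ 2),
* cue-evoked slow waves: high-amplitude biphasic 0.5–3 Hz transients whose
  trough (down-state) is followed by a positive up-state deflection, and
* sleep spindles: transient 12–16 Hz bursts of 0.5–3 s whose envelope peak
  preferentially falls 0.3–0.8 s after a SW trough (up-state nesting).

The pipeline (`run_pipeline()`) chains: band-pass preprocessing → SW
detection (Cz) with top-30 % amplitude selection → spindle detection (Pz)
with per-subject thresholds → coupling classification → SW-trough-locked
Morlet power → cue-locked SW density → cluster-based group statistics →
signal-detection scoring of behavior. Every stage is exported and usable
alone.

## Filtering

All band-passes are zero-phase linear-phase FIR filters: Hamming
windowed-sinc designs with transition widths of 25 % of each corner
frequency (bounded below by 2 Hz and above by the corner itself), applied by
FFT convolution with the group delay compensated exactly. Measured
responses: a 10 Hz tone through 0.5–45 Hz passes at gain 0.998 with zero
lag; DC is suppressed below 1 % ; 60 Hz mains through the sleep band
(0.5–35 Hz) is attenuated by ~10⁻⁵; the 12–16 Hz spindle band passes its
center at gain 0.97.

Two numerical facts drove this choice over an IIR (Butterworth) design.
First, a narrow band-pass such as 0.5–3 Hz at a 500 Hz sampling rate places
IIR poles so close to the unit circle that forward–backward filtering
diverges numerically. Second, cascaded low-order IIR sections attenuate the
4-Hz-wide spindle band to roughly half its amplitude at center, which
destroys detector calibration. The FIR's flat passband preserves in-band
event amplitudes, which the per-subject SD thresholds rely on.

A consequence worth knowing: a single biphasic SW cycle at 0.75 Hz has
spectral content below the 0.5 Hz corner, so the 0.5–3 Hz filtered waveform
on which amplitudes are measured is attenuated relative to the raw injected
waveform (≈ 127 µV measured for a 160 µV raw trough-to-peak). Detector
tests therefore validate amplitudes against filtered-waveform oracles, not
against the raw injection value.

## Slow-wave detection

The Cz signal is band-passed to 0.5–3 Hz and all local extrema are
localized from sign changes of the first difference (plateaus resolve to
their midpoint). Every negative-valued minimum flanked by positive-valued
maxima is an event when the two positive peaks are 0.3–2 s apart; its
amplitude is trough → posterior positive peak. Detection runs on the
continuous filtered signal; each trough is assigned to the most recent cue
whose search window contains it, so overlapping cue windows (ISI can be
shorter than the 6-s window) never count a trough twice. The top
`ceiling(0.3 · N)` amplitudes per subject (ties: earlier trough wins) enter
all downstream analyses. Cz is the default detection site — central
electrodes are the conventional SW-scoring location — and is configurable.

Cue-locked density uses 0.5-s bins over −1.5–3 s, normalized per trial and
expressed as percent change against the mean of the −1.5–0 s baseline bins;
a zero baseline is flagged and raw densities returned instead. In the
pipeline the detection search window is extended to −1.5–6 s so the
baseline bins can be populated; the up-state analyses use the post-cue
events.

## Spindle detection

The Pz signal is band-passed to 12–16 Hz; the instantaneous amplitude is
the modulus of the FFT-based analytic signal, smoothed with a 200-ms moving
average. Smoothing is the package's interpretation of "the amplitude": an
unsmoothed envelope fragments events at single-sample dips, which makes
ground-truth recovery unstable; a 200-ms average matches the smoothing used
by established spindle detectors. Thresholds are individualized per
subject: mean and SD of the smoothed envelope over the concatenated −2–8 s
cueing windows; candidates exceed mean + 1.25 SD, boundaries extend to
where the envelope falls below mean + 0.75 SD, candidates closer than 0.1 s
merge, and only durations of 0.5–3 s survive. The event peak is the
envelope maximum; the amplitude is the mean absolute value of all local
extrema of the filtered trace within the event.

Because boundaries are threshold crossings, the "true" boundary of a
synthetic burst is the crossing of its noiseless smoothed envelope with the
same edge threshold — not the point where the Hann envelope reaches zero,
which no threshold detector can observe. Validation measures boundary
errors against that crossing oracle (mean error ≈ 50–70 ms at envelope
SNR 5). The same resolution limit means a sub-0.5-s burst of very high
amplitude can occasionally smear past the duration gate; at the validation
SNR the gate rejects 0.3-s bursts in ≈ 90 % of seeds.

## Coupling and SW-locked power

A spindle is SW-coupled when its peak lies in the closed window
[trough + 0.3 s, trough + 0.8 s] for at least one SW; when several qualify
the SW whose lag is nearest the window center (0.55 s) is recorded, so each
spindle counts once. The classifier is validated against a brute-force
double loop over all pairs.

SW-trough-locked power uses the top-30 % SW selection: segments of
± 2 s around each trough (cut wider internally so wavelet edge effects
never reach the output window), 7-cycle Morlet decomposition, and absolute
baseline subtraction over −2 to −1.5 s before the trough. The up-state
summary is the mean 11–14 Hz power 0.3–0.8 s post-trough over parietal
channels.

## Morlet time–frequency analysis

Complex Morlet wavelets with σ_t = n_cycles/(2πf), n_cycles = 7, sampled to
± 3.5 σ_t and normalized so that a pure sinusoid of amplitude a yields
power a² at its frequency (units µV², not dB). The full analysis grid is
1–45 Hz in 0.2 Hz steps at 10 ms resolution; validation uses coarser grids
(documented per test) since grid density does not change the algorithm.
Output samples closer than 2.5 σ_t to an epoch edge are flagged invalid
(NA) rather than zero-padded silently. Absolute baseline subtraction makes
trial-averaging and baseline correction commute; a test asserts this
identity. Wake analyses baseline-correct against −1 to −0.1 s pre-stimulus
and contrast later word presentations against the first.

## Cluster-based permutation statistics

For subject × channel × frequency × time arrays, pointwise t-tests
(dependent or pooled independent) are thresholded at the two-tailed
α = 0.05 quantile. Suprathreshold points cluster by adjacency: one grid
step in frequency or time within a channel, or a neighboring channel at the
same grid point, using a hand-built Delaunay-style neighbor list for the
19-channel 10-10 montage. Clusters spanning fewer than two
adjacency-connected channels are discarded — the cluster-level reading of
the minimum-channel rule — and the discard applies identically inside the
permutation loop. The max-sum statistic per polarity is compared against
its sign-flip (paired; full enumeration when 2^n ≤ n_perm) or label-shuffle
(unpaired) distribution; per-tail Monte-Carlo p-values (b + 1)/(n_perm + 1)
are doubled and capped at 1, so `p_mc < 0.05` is the two-tailed decision.
Calibration over 200 null datasets puts the empirical type-I rate at
0.025–0.055 for both designs, inside the 99 % binomial band around 0.05.

The pipeline's primary group inference is this cluster test over the
up-state box; the scalar t-test on mean up-state power is reported as the
post-hoc effect-size estimate, mirroring the two-step sensor-level
convention.

## Behavior and signal detection

The discrimination task: 160 artificial words (40 rewarded + 40 unrewarded
per phonotactic-probability condition), three presentations during encoding
(480 trials, randomized), and 160-trial memory tests before and after
sleep. Correct responses to rewarded words are hits; incorrect responses to
unrewarded words are false alarms. Rates of 0 and 1 are replaced by 0.5/n
and (n − 0.5)/n before the quantile transform. Timeout trials are excluded
and the category n reduced — the handling is configurable because
conventions differ. Money points default to ±10 and never enter the SDT
computations. Reported d′ rounds to two decimals, half away from zero.

The simulator draws per-trial Bernoulli responses with per-presentation,
per-condition accuracies; defaults make the easy (high-PP) condition
overtake the difficult one from the second presentation on, and give the
cued-easy condition a small post-sleep accuracy gain. Recovery tests show
the scorer returns the analytic d′ of the generating accuracy to within
0.1 across 200 simulated sessions.

## Synthetic-data generator: scope and limits

The generator reproduces the structure the analysis assumes — 1/f
background, cue trains at 8 ± 2 s, additive SW and Hann-windowed spindle
bursts with controlled coupling lags and amplitudes, Bernoulli behavior —
and is bitwise reproducible from its seed. It does not model
non-stationarity across the night, sleep-stage transitions, arousals,
ocular or muscle artifacts, spindle frequency drift, or phase-dependent
(rather than lag-dependent) coupling. Passing validation therefore
demonstrates that the implementation is correct under the stated signal
model, not that the detectors are optimal on real polysomnography.

Validation problem sizes are deliberately desk-scale: 60–220 s recordings,
1–4 channels for pipeline runs, 11–16 frequency bins, 500 permutations for
the type-I sweep, 6 subjects per simulated group. These sizes are the
package's validation choices; all defaults facing real data (500 Hz,
19-channel montage, full 0.2 Hz/10 ms grids, 1000 permutations) remain at
the field conventions.

## Degenerate inputs and tie-breaks

Flat signals yield empty event lists; an all-rejected artifact screen is an
error rather than an empty epoch set; a zero density baseline is flagged
instead of dividing by zero; zero-variance inputs to t-tests and
correlations are errors; empty score-session cells are omitted rather than
scored as zero. Ties in top-amplitude selection resolve to the earlier
trough; plateau extrema resolve to their midpoint sample; boundary hits of
the coupling window count as coupled.

## Known limitations

* EDF export writes a single data record; files beyond a few hours at high
  rates should use BrainVision instead.
* The spindle boundary resolution is limited by the 200-ms envelope
  smoothing; sub-0.5-s bursts of extreme amplitude can occasionally pass
  the duration gate.
* The cluster test's spatial step assumes the shipped 19-channel
  neighborhood; other montages need a user-supplied neighbor list.
* ICA-based ocular correction is out of scope; artifact handling is the
  deterministic peak-to-peak screen.
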