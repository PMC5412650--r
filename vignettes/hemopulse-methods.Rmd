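---
title: "Methods: transit-time blood pressure, MBLL oximetry and the synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transit-time blood pressure, MBLL oximetry and the synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemopulse)
```

# The measurement problem

In an MEG chamber, only non-magnetic, electrically non-conductive
instrumentation can sit near the subject, which rules out ordinary cuff or
volume-clamp blood-pressure devices. Fibre-optic accelerometers (ACMs) on
the chest and neck, and fibre-coupled NIRS optodes, work inside the
shielded room; this package implements the signal-processing chain that
turns those channels into continuous cardiovascular and hemodynamic
readouts, plus a synthetic generator that provides ground truth for
validating every stage.

# Transit-time blood pressure

## Model and assumptions

The arterial pulse wave travels faster when pressure is higher, so the
transit time (PTT) between a proximal cardiac timing event and the distal
carotid arrival varies inversely with blood pressure. We adopt the
monotone family

$$\mathrm{BP} = A \cdot \mathrm{PTT}^{-\alpha} + B, \qquad A > 0,\ \alpha > 0,$$

which is strictly decreasing and invertible on any positive PTT range.
Assumptions worth keeping in mind:

* the PTT–BP relation is treated as instantaneous and memoryless per beat;
* path length and vessel compliance are constant within a session (they
  enter through $A$ and $B$, which is why calibration is per subject and
  per sensor placement);
* without calibration only the *shape* of the BP oscillation is
  recoverable. `estimate_bp()` then returns the z-score of $-\mathrm{PTT}$
  — rising output for falling transit time — and the result carries no
  mmHg units by design.

`fit_calibration()` fits $(A, B)$ by least squares at fixed $\alpha$
(linear in $x = \mathrm{PTT}^{-\alpha}$), or profiles $\alpha$ over a log
grid refined by golden-section search for the three-parameter fit. A fit
whose slope comes out non-positive (pressure increasing with transit
time) is refused rather than returned, since it violates the model's
physiological direction.

## Beat detection

`detect_reference_peaks()` finds beats on the channel with the clearest
pulse: local maxima above an adaptive threshold, accepted
largest-amplitude-first under a refractory interval (`min_interval`,
default 0.4 s — just under the shortest plausible inter-beat interval).
The threshold is half the rolling 95th percentile over 10 s blocks,
computed on the median-centred signal so detection is invariant to
positive affine rescaling. The percentile window is long against a beat
(~10 beats) but short against slow amplitude drift.

`detect_peaks_guided()` then takes each reference beat and returns the
argmax of the distal channel inside the lag window
$[\mathrm{ref}+20\,\mathrm{ms}, \mathrm{ref}+400\,\mathrm{ms}]$ — bounds
wide enough for chest-to-neck transit in adults while excluding the next
beat. Ties resolve to the earliest sample, which keeps the operation
exactly reproducible by a brute-force windowed argmax (a property the
test suite checks literally). Windows falling outside the recording mark
the beat missing; nothing is fabricated.

Both detectors accept an optional zero-phase low-pass
(`smoothing_bandwidth`). A symmetric pulse keeps its peak position under
zero-phase smoothing, so this suppresses noise-driven argmax jitter
without biasing timing; the pipeline default is 15 Hz, comfortably above
the pulse wavelet bandwidth.

Manual visual vetting of beats is replaced by reproducible QC:
`qc_beat_series()` repairs impossible inter-beat intervals (< 0.3 s) by
dropping whichever of the two offending events leaves an interval closer
to the median, flags intervals beyond 1.75× the median as missed-beat
gaps, and `qc_ptt()` discards transit times beyond 5 scaled MADs from the
median.

## The MEG-proximal variant

MEG channels incidentally record the heart's electrical activity. Using
those artifact peaks as the proximal event and the neck ACM as distal,
`meg_ptt_bp()` estimates BP oscillations with a single ACM. The artifact
peak is not the chest-wall peak, so MEG-based PTT carries a constant
modality offset; relative mode absorbs any constant, which is why this
variant does not offer absolute calibration. Comparisons between the
chest-based and MEG-based series use `match_beats()` (nearest beat within
150 ms), because the two proximal timebases never agree exactly.

# NIRS and the modified Beer–Lambert law

`compute_delta_od()` forms $\Delta OD(t) = -\log_{10} I(t)/\bar I$
against the mean intensity over a baseline window (default the first
30 s). `mbll_inverse()` solves per sample the 2×2 system

$$\Delta OD(\lambda) = d \cdot \mathrm{DPF}(\lambda)\,
 [\varepsilon_{HbO}(\lambda)\,\Delta HbO + \varepsilon_{Hb}(\lambda)\,\Delta Hb]$$

for the two chromophores; $\Delta HbT = \Delta HbO + \Delta Hb$ is exact
by construction. Defaults: wavelengths 660/850 nm, source–detector
distance 3 cm, DPF 6.0 at both wavelengths (a common adult-head value;
the true DPF is wavelength- and tissue-dependent and fully configurable),
extinction coefficients from the Prahl compendium converted to
1/(µM·cm), no partial-volume correction (plain MBLL; an optional scalar
is exposed). The extinction matrix is checked for conditioning
(condition number ≤ 1e6) before inversion. Everything here is linear in
ΔOD and independent of the absolute baseline intensity, and both
properties are tested directly.

# Respiration and breath holds

Breathing appears on the chest ACM as slow chest-wall motion;
`extract_respiration()` is a zero-phase 4th-order Butterworth low-pass at
0.5 Hz (the conventional cutoff separating respiration from cardiac
content). `detect_breath_holds()` forms a rolling-SD envelope (5 s
windows), takes maximal runs below 0.25× the median envelope lasting at
least `min_duration`, and then expands each run to the half-median
envelope crossing. That last hysteresis step matters: a centred rolling
window smears the envelope by half its width, so without it onsets land
~2–3 s inside the true hold. Task markers, when available, should be
preferred over detection.

# Epoching and averaging

`epoch_series()` cuts −5…80 s windows (the defaults) around events.
Irregular per-beat series are first linearly interpolated onto a uniform
4 Hz grid — comfortably above beat rate, cheap to average; uniform
channels are epoched at native rate. Epochs extending past the recording
are dropped with a warning. `baseline_correct()` subtracts each epoch's
own full-window mean (idempotent; zero-mean epochs afterwards), and
`average_epochs()` reports the pointwise mean and *sample* standard
deviation (n−1 denominator; SD identically zero for a single epoch). An
`include` mask supports manual epoch exclusion — e.g. averaging 4 of 5
holds — without any hidden rejection heuristic.

# Device-compatibility analysis

`welch_psd()` implements the averaged-periodogram estimator: Hann-windowed
segments (default 10 s, 50% overlap), one-sided density scaling by
$f_s \sum w^2$. `welch_power()` integrates the PSD over a band; for a
long white-noise record the full-band integral approaches the variance
and a sinusoid of amplitude $a$ carries $a^2/2$, the two closed-form
oracles the tests use. `compare_conditions()` fits
`power_without ~ power_with` by ordinary least squares (with-device on
the x axis, matching the convention of the original comparison), and
reports Pearson $R^2$ and the intercept as a fraction of the mean
without-device power — a positive intercept is the signature of a small
uniform power loss when the extra hardware is attached.

# The synthetic testbed

## What it emulates

`simulate_ground_truth()` draws the latent state first:

* **BP(t)** = baseline (90 mmHg) + Mayer sinusoid (5 mmHg at 0.1 Hz) +
  hold responses (linear ramp to 10 mmHg over each 30 s hold, exponential
  relaxation with a 10 s constant afterwards);
* **HR(t)** = 60 bpm + band-limited Gaussian variability (low-passed
  white noise rescaled to 3 bpm SD) − 3 bpm during holds; beat times come
  from integrating the instantaneous rate to unit threshold, the standard
  inhomogeneous point-process construction;
* **true PTT per beat** = the inverse calibration map at the beat-time
  BP, with true coupling $A = 7.5$ mmHg·s, $\alpha = 1$, $B = 40$ mmHg —
  chosen so BP in 80–110 mmHg maps to PTT of roughly 110–190 ms, inside
  the physiological window;
* **respiration** = 0.25 Hz sinusoid, smoothly gated to zero during
  holds (2 s raised-cosine edges);
* **ΔHbO/ΔHb** = hold-locked transients (−1 µM dip and +0.2 µM rise at
  the gate), order-of-magnitude amplitudes chosen once since the
  motivating observations are qualitative.

Channels are rendered from that state: Gaussian pulse wavelets
(σ = 25 ms) at beat times on the chest, at beat + PTT on the neck, a
sharper artifact wavelet (σ = 15 ms) over 1/f-shaped background on the
MEG channel, and forward-MBLL intensities for NIRS; white measurement
noise per channel, everything at 1 kHz by default. The default task
schedule is five 30 s holds separated by 30 s of normal breathing.
`(config, seed)` fully determine all outputs.

## What it does not emulate — and what passing means

No motion artifacts, no sensor detachment or baseline wander, no
beat-morphology variability (every beat is the same wavelet), no
pulse-wave propagation physics (PTT is imposed through the calibration
map — so calibration recovery on simulated data is an inverse crime, and
is labelled as such in the tests), no superficial-layer contamination or
wavelength-dependent DPF error in NIRS, and no neural MEG content.
Passing the recovery suite therefore demonstrates that the *algorithms*
are correct and self-consistent at realistic SNR, not that the method
achieves any particular accuracy on human data.

## Numerical choices

* Wavelet trains place each impulse at the nearest sample before
  convolution, bounding timing error by half a sample (0.5 ms at 1 kHz).
* Very-low-frequency Butterworth designs (e.g. a 0.01–0.08 Hz band at
  1 kHz) are numerically singular in double precision, so `bandpass()`
  internally decimates to ~50× the upper cutoff (after an anti-alias
  low-pass), filters there, and linearly interpolates back — exact for
  output band-limited far below the original Nyquist.
* 1/f background is synthesized by spectral shaping of white noise
  (exponent 1 by default), with the DC bin zeroed.
* Degenerate inputs are defined, not errors: a flat signal detects no
  beats; an all-quiet respiration trace is one hold spanning the
  recording; zero optical density maps to zero concentrations.

# Problem sizes

The test suite validates recovery on 120 s sessions at 1 kHz (five seeds
for the headline correlations) and runs the full five-hold protocol on a
360 s session; oracle and property checks use seconds-long fixtures at
50–500 Hz. The acceptance script simulates five 120 s sessions. These
sizes give stable correlation estimates (≈120 beats per session) while
keeping the whole suite fast.

# Known limitations

Absolute BP requires an external reference for calibration and is not
validated against any clinical standard here; PTT timing is peak-based
(foot-of-wave timing is a possible extension); clock synchronization
across acquisition devices is assumed, not performed; EDF and vendor MEG
formats are out of scope — the delimited-text recording format plus
sidecar is the interchange surface.
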