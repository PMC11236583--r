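---
title: "Delta-band entrainment to prosodic contours: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta-band entrainment to prosodic contours: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(prosodent)
```

## The scientific question

When listeners are exposed to a repetitive prosodic rhythm — a pitch contour
repeated at a fixed rate in the delta band — cortical activity aligns to that
rate. `prosodent` implements a complete analysis pipeline for a paradigm that
probes three consequences of such entrainment:

1. **Entrainment proper.** During auditory exposure to three cycles of a
   delexicalized pitch contour (SLOW: 1,570 ms contour + 160 ms pause =
   1,730 ms cycle, ~0.6 Hz; FAST: 942 + 160 = 1,102 ms, ~0.9 Hz),
   pitch–MEG coherence should peak at the cycle rate of the presented
   condition, with a harmonic of the SLOW rate at 1.2 Hz.
2. **Sustained rhythm.** After the auditory rhythm stops and a visual
   sentence is presented word by word (314 ms/word), spectral power should
   continue to peak at the *preceding* contour rate for at least one cycle.
3. **Falsified predictions.** A SLOW rhythm spans five words plus a pause,
   biasing the reader toward a six-word (LONG) parse. When a five-word
   (SHORT) sentence ends where a sixth word was predicted, an omission
   evoked field should appear at the missing word's theoretical onset —
   only after SLOW contours.

Because no recorded dataset accompanies the design, the package carries a
first-class synthetic-data module that generates multichannel MEG-like
sessions in which all three effects are planted with known ground truth.
Every estimator in the pipeline is validated by parameter recovery against
that ground truth.

## Stimulus model

Contours are rendered from a fundamental-frequency (F0) track by harmonic
resynthesis: a sine at the F0 with cumulative phase
$\phi(t) = 2\pi\int_0^t f_0(u)\,du$, plus the second harmonic at 1/4 and the
third at 1/16 of the amplitude (`synthesize_purr()`). Cumulative phase, not
$\sin(2\pi f_0 t)$, is used so that pitch glides introduce no phase jumps.
The synthetic condition contour (`contour_f0()`) is a deterministic
declination-plus-accents shape rescaled to the reference voice statistics
(minimum 116 Hz, maximum 267 Hz, mean 191.5 Hz) and lowered by 55 Hz for
presentation. The declination component is made dominant on purpose: the
cycle-rate spectral line of the repeated contour comes from the sawtooth-like
once-per-cycle sweep, while the two accent oscillations contribute energy
near the first harmonic (for SLOW, ~1.2 Hz), giving the coherence spectrum
the fundamental-plus-harmonic signature expected of a cycle-locked but
non-sinusoidal response. Loudness normalization is peak-based
(`write_wav()` clips at ±1); absolute dB SPL has no software meaning.

Trial timelines (`make_trial_schedule()`) place three contour cycles, the
sentence words, the omission point (sentence onset + 5 × 314 ms, SHORT
trials only) and a jittered delay of 500 + U(0, 250) ms, quantized to the
250 Hz sample grid. The FAST entrainment phase is preceded by a lead-in
pause equal to the *total* duration difference (3 × 1,730 − 3 × 1,102 =
1,884 ms), which makes both entrainment phases last 5,190 ms; reading the
equalization pause as a single cycle-pair difference (628 ms) is available
via `fast_lead = "per_repetition"` but does not equalize totals. The FAST
entrainment epoch is taken as its computed duration 3 × 1.102 = 3.306 s.

## Synthetic sessions and the forward model

`build_sensor_model()` places 102 sensors on the upper unit hemisphere with
a 6-nearest-neighbour adjacency graph and 90 source nodes inside it, one
node per hemisphere for each labelled region (EAC, STG, IFG, FOP, BA4, BA6,
DLPFC, TPOJ) plus unlabelled fillers. The leadfield is an inverse-square
distance falloff with a fixed random source orientation per node; columns
are unit-normalized, the usual depth-bias control.

`simulate_subject()` plants:

* a **cycle-locked entrainment response** at the right EAC and STG nodes
  during contour presentation — the contour's own demeaned F0 modulation,
  repeated each cycle, so the response is periodic at the cycle rate but
  non-sinusoidal;
* a **sustained oscillation** at the left FOP and EAC nodes at the
  condition's cycle rate throughout the sentence phase;
* a **biphasic omission deflection** (early lobe peaking ~60 ms, late lobe
  ~400 ms after the omission point) at left DLPFC and right TPOJ nodes, in
  SHORT-after-SLOW trials only;
* optional word-onset evoked impulses (~3.18 Hz; disabled by default, the
  spectral-separation property is tested explicitly);
* 1/f (exponent 1) plus white sensor noise, unit standard deviation per
  channel. All amplitudes are expressed in noise-sd units.

Three variability parameters deserve comment, because they are what makes
the generator *recoverable* rather than merely decorative:

* `phase_jitter_sd` (0.4 rad): stimulus-locked jitter shared by a trial's
  generators; it attenuates but does not destroy trial-wise coherence.
* `node_phase_sd` (0.7 rad): **independent** per-node jitter. Distinct
  cortical generators are not perfectly mutually coherent; more
  consequentially, an adaptive beamformer *cancels* perfectly correlated
  sources, so a generator without inter-node variability produces data on
  which DICS recovery is impossible in principle.
* `sustain_phase_sd` (default `Inf`, i.e. uniform phase): the sustained
  rhythm keeps the contour *rate* but not a trial-consistent phase. Two
  estimator-level facts force this choice. First, with exact phase
  continuation the one-cycle target epoch has a fixed starting phase, and
  the Hann-tapered spectrum of a single period then has a phase-dependent
  argmax (for FAST it parks one bin above the true rate); only
  phase-diverse trial averages peak at the rate. Second, any trial-coherent
  sustained residual survives ERF averaging and — because the two
  conditions sustain *different* frequencies — leaks a systematic
  SLOW-vs-FAST difference into the omission window, so the omission
  contrast would reject its null without any omission source. Uniform
  phase is also neurophysiologically reasonable (endogenous oscillations
  slip phase over seconds) and consistent with the design logic that the
  sentence phase is analyzed with power, which is phase-insensitive,
  rather than stimulus-locked coherence. Gaussian drift of any sd remains
  selectable.

Default amplitudes (entrain 6, sustain 8, omission 6) were calibrated once
so that a 20-subject cohort shows all three effects at conventional
significance; they are simulation choices, not empirical claims.

## Spectral estimation

All sensor analyses run on a 0–3 Hz grid with 0.1 Hz spacing (31 bins),
obtained by Hann-tapering each epoch over its data length and zero-padding
to 10 s (20 s for source-space cross-spectra). Tapering precedes padding.
Epoch lengths are floored to the sample grid (5.19 s → 1,297 samples at
250 Hz) and epochs are demeaned per channel. The grid frequencies 0.6, 0.9
and 1.2 Hz are exactly representable on both padded grids, so no off-grid
interpolation ever occurs (asserted in tests).

Pitch–MEG coherence across K trials is magnitude-squared coherence,

$$C(f) = \frac{\left|\sum_k X_k(f)\overline{Y_k(f)}\right|^2}
              {\sum_k |X_k(f)|^2 \sum_k |Y_k(f)|^2},$$

with the interpolated repeated-contour F0 track, resampled to the MEG rate
and demeaned per epoch, as the reference. Its null expectation is 1/K,
which the tests calibrate explicitly. Power is the trial mean of
$|Y_k(f)|^2$. Both inherit the grid's leakage properties; with one-cycle
target epochs the Rayleigh width is comparable to the 0.3 Hz rate
difference, which is why the group-average peak location, not peak
sharpness, is the tested claim.

## Statistics

Sensor-level contrasts use the cluster-based sign-flip permutation test:
channel-wise paired t maps, a two-tailed cluster-forming threshold at
$\alpha = 0.05$, connected components over the sensor graph per polarity,
clusters below 3 channels discarded, cluster mass = summed t. The null
distribution of the maximal cluster mass is built **per polarity** from
within-subject sign flips (full enumeration whenever $2^n \le$ `n_perm`),
and each cluster's Monte-Carlo p is $(r+1)/(n_\mathrm{perm}+1)$ against its
own tail, compared to $\alpha/2$ per tail by default (the plain-$\alpha$
reading is available in `significant_clusters()`). Measured type-I error
over 500 null cohorts at these settings is ~0.05 and is asserted to lie in
[0.03, 0.08] by the test suite.

The rate-specific response index summarizes entrainment strength per
subject, region and hemisphere:

$$\mathrm{RSR} = (R_{0.6,\mathrm{SLOW}} - R_{0.6,\mathrm{FAST}})
             + (R_{0.9,\mathrm{FAST}} - R_{0.9,\mathrm{SLOW}}),$$

positive when responses follow the stimulation rate; it negates exactly
under condition-label swap. The condition-by-frequency interaction is
tested per region by the within-subject difference of differences under a
sign-flip permutation, with classical post-hoc 0.6-vs-0.9 paired t tests
within each condition. A mixed-effects model (random intercepts per
subject) answers the same question; the test suite cross-checks the
permutation contrast against `lme4` on synthetic tables but the permutation
route is the implementation.

## Beamforming on the toy model

DICS builds common spatial filters per analysis frequency from the
condition-pooled CSD, $w_j = (L_j^\top C^{-1} L_j)^{-1} L_j^\top C^{-1}$
with $C$ the real part of the sensor CSD plus $\lambda\,\overline{\mathrm{diag}}\,I$,
then applies them to per-condition CSDs (common-filter contract: identical
inputs give identical maps). Node power is $\mathrm{Re}(w C w^H)$;
node–reference coherence is $|w c_\mathrm{ref}|^2 / (P \cdot S_\mathrm{ref})$.
LCMV is the time-domain analog on the pooled SHORT-trial covariance,
applied to per-condition evoked averages and summarized over the 300–600 ms
window.

The DICS regularization default is $\lambda = 0.5$, an order of magnitude
above textbook practice, and deliberately so: a CSD estimated at a *single
frequency* from K trials has rank at most K, far below 102 channels at
realistic trial counts. At $\lambda = 0.05$ the adaptive filter all but
annihilates the sampled data subspace, and per-condition power becomes
small-sample structure — in ablation runs even pure-noise conditions showed
inverted power ratios, and the power-RSR sign flipped between cohorts.
At $\lambda = 0.5$ the planted left-hemisphere power pattern and the
right-temporal coherence pattern are stable across seeds. LCMV keeps
$\lambda = 0.05$ because its broadband covariance is well conditioned. Both
are exposed in `run_config()`.

ERF cluster contrasts use window-averaged amplitudes per channel
(space-only clustering) because the analysis windows (300–600 ms, 0–120 ms)
are fixed a priori. Cluster polarity is reported but never interpreted as
effect direction; direction is read from the condition means over the
cluster channels, since MEG polarity depends on source orientation.

## Quality control

`reject_trials_qc()` applies three rules per trial: an absolute-amplitude
bound (default 30 noise-sd units, the simulation analog of a ±6 pT bound on
physical magnetometers), a jump rule (robust max-z of the residual from a
9-sample running median above 75), and a muscle rule (robust max-z of the
110–124 Hz band signal above 20, with the band obtained by an ideal FFT
bandpass on the zero-padded epoch, replacing a recursive filter that is
marginal this close to Nyquist). Robust z uses median/MAD, so clean
Gaussian epochs sit near z ≈ 5–6 and the thresholds only catch gross
artifacts, as intended.

## Problem sizes and what the tests do (and do not) show

The default simulated study is 20 virtual subjects with 80 trials each
(40 per contour condition, 20 per condition-by-length cell); the packaged
acceptance script runs exactly this and reports the group-level spectral
peak locations. The test suite uses smaller cohorts (6–8 subjects, 16–40
trials) for end-to-end recovery, 500 null cohorts for type-I calibration at
`n_perm = 500`, and 20 seeds for beamformer recovery — sizes chosen so the
full suite completes in minutes while keeping every statistical claim a
measured one.

The generator emulates the *statistical structure* the analysis assumes:
linear mixing of a few delta-band sources into 1/f-plus-white noise,
trial-wise phase variability, and balanced designs. It does not emulate
real-MEG properties such as correlated sensor noise, head movement,
physiological artifacts beyond injected test cases, volume-conduction
physics, or inter-subject anatomical variability. Passing recovery tests
therefore validates the estimators and their implementation, not claims
about any particular recorded dataset.

## Known limitations

* One-cycle target epochs make the 0.6-vs-0.9 Hz comparison heavily
  leakage-coupled; all cross-condition power statements should be read at
  the group level.
* The toy leadfield is scalar (fixed orientation); dipole orientation
  fitting, realistic head models and coregistration are out of scope.
* The power measure is unnormalized squared magnitude, so power values
  scale with epoch length; within-condition contrasts and the RSR (which
  differences matched terms) are the supported uses.
* QC thresholds are calibrated for simulation units; on real data the
  amplitude bound must be re-expressed in physical units.
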