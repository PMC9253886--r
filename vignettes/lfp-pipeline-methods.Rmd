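---
title: "Methods: sleep staging, oscillation tracking and coupling analysis of two-site LFP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep staging, oscillation tracking and coupling analysis of two-site LFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lfprhythms` implements a complete analysis chain for long-duration
two-channel local field potential (LFP) recordings from ventral hippocampal
CA1 (vCA1) and medial prefrontal cortex (mPFC) in freely behaving mice:
vigilance staging, 1/f-whitened spectral-peak tracking with circadian sine
fits, theta–gamma cross-frequency coupling, inter-site delta-band phase
synchrony, sharp-wave-ripple (SPW-R) and spindle detection with coupling,
and a non-parametric effect-size statistics layer. Because the recordings
the methods were developed on are not publicly deposited, the package
includes a synthetic two-channel generator with per-second ground truth;
every stage is validated by recovering the generator's configured
parameters. This vignette explains each model, its assumptions, the
tunable parameters, and the numerical choices made where the methods left
the design open.

## Filtering and envelopes

All band isolation uses linear-phase (Type-I) FIR bandpass filters. The tap
count is tied to the band and sampling rate by

```
n = int(50 / (22 * (HF - LF) / SR)),  floored at 401, forced odd
```

where 50 is the stopband attenuation in dB and 22 the transition constant of
the Hamming design rule; `fir_num_taps()` implements this rule and
`filter_spec()` builds the Hamming-windowed design (via `signal::fir1`). The
odd length gives an integer group delay, which `bandpass()` compensates
exactly after reflect-padding by one filter length, so filtering introduces
no net phase shift — a property the phase-based analyses (Hilbert phases,
ISPC, PAC) depend on. Note that this rule produces deliberately gentle
filters: the theta filter's transition width is comparable to its bandwidth,
so a 2 Hz tone is attenuated to ~23% rather than to the 50 dB floor. Tests
therefore validate the realized attenuation against the designed frequency
response rather than against an idealized brick wall.

Default band edges are delta 0.5–4, theta 5–12, gamma 30–120, ripple
120–250 and spindle 10–30 Hz. Band envelopes for staging are root mean
square (RMS) values over 8 s windows stepped by 1 s (0.5 s optionally),
computed by `rms_envelope()`. Instantaneous amplitude and phase come from
the FFT-based analytic signal (`analytic_signal()`); the phase of a cosine
is 0 at its peaks, which fixes the phase origin of all coupling analyses at
the theta peak.

## Vigilance staging

Staging works on one channel (vCA1 by default) plus a per-second activity
trace, in 12 h blocks in production use (shorter blocks are accepted and
the tests use 2 h):

1. The per-second RMS(gamma)/RMS(delta) ratio (G/D) histogram is fit by a
   sum of two Gaussians (`fit_two_gaussians()`, nonlinear least squares via
   `minpack.lm`). The lower-mean component captures NREM sleep, where delta
   dominates.
2. Each second's NREM membership probability is a step function of G/D
   relative to that component: 1 up to mean + 1 SD, 0.397 to mean + 2 SD,
   0.067 to mean + 3 SD, 0 beyond. The 0.397 and 0.067 weights are fixed
   constants of the method (derived from the 68.27/95.45/99.73% normal
   coverage fractions) and are used verbatim, not recomputed — recomputation
   would give 0.398 and 0.063 and break replication. Probability beyond
   mean + 3 SD is 0, completing the step function.
3. A second is NREM iff the mean probability over the 8 s before it *or*
   the 8 s after it reaches 0.5 (`binary_nrem()`; flanks truncate at block
   edges).
4. Seconds outside NREM are split into REM and AWAKE at the intersection of
   a second two-Gaussian fit of the theta/delta ratio
   (`theta_delta_threshold()` solves the log-density quadratic; the root
   between the means is the threshold). A second is REM only if its
   non-NREM run touches an NREM run — REM is entered from NREM, never from
   prolonged wake. All threshold comparisons are strict, for deterministic
   tie-breaking.
5. The activity trace reclassifies in three passes
   (`reclassify_by_activity()`): active "REM" becomes AWAKE (activity above
   the pooled REM/AWAKE median), inactive "AWAKE" becomes REM (below the
   NREM median), and REM reached from AWAKE reverts to AWAKE.

One design point deserves emphasis. Because both ratio series are computed
in 8 s epochs, state edges are smeared by up to half a window: at a genuine
NREM-to-REM transition, one to three seconds typically fall below the REM
threshold and are provisionally AWAKE. A literal "REM preceded by AWAKE
reverts" rule would delete most true REM runs (measured: per-second
agreement drops from ~98% to ~89% on synthetic recordings). Pass 3
therefore looks through AWAKE gaps of up to 4 s — half the ratio window —
and reverts a REM run only when the state beyond the gap is still AWAKE.

Histogram fitting uses bins spanning the 0.1–99.9 percentile range (200
bins for large samples, proportionally fewer below 4000 values) and a small
multi-start over quantile pairs, because a single 25th/75th-percentile
start misses strongly skewed mixtures. A fit is declared failed — with a
single-Gaussian fallback and a flag — when the components do not separate,
when the fitted sum has no valley between the means (one mode split in
two), or when one component carries under 2% of the mixture mass (a
histogram-bin artefact). A failed theta/delta fit means no REM evidence in
the block; all non-NREM seconds stay AWAKE, with a warning.

`hourly_fractions()` tabulates percent AWAKE/NREM/REM per clock hour, the
quantity whose light/dark contrasts the statistics layer tests.

## Whitened spectral peaks and circadian structure

LFP spectra fall off as a "pink" 1/f^alpha trend; a band oscillation is
only meaningful relative to that trend. For each 8 s window (1 s steps,
Hann taper) `whitened_peak()` smooths the in-band log power (5-point moving
average), draws a straight line in log(f)–log(P) space between the band
edges, and takes the peak as the largest positive residual above the line.
Baseline anchoring averages 3 bins at each edge — a single noisy edge bin
would tilt the whole line. The peak is "present" only when its residual
exceeds 4x the median absolute residual of the remaining in-band bins;
this floor was calibrated on pink-noise and tone fixtures so that pure
power-law windows rarely report a peak (~10%) while in-band tones at
twofold power are always kept. Peak magnitudes are tracked but the
downstream analyses use only the frequencies, which are insensitive to
electrode impedance and placement.

Windows are assigned the vigilance state of the majority of their seconds
(ties to the earlier second), averaged per hour and state
(`hourly_state_peaks()`), and summarised by a fixed-period sine fit
`m + a*sin(2*pi*t/24 + phi)` (`fit_circadian_sine()`, linear in the
sin/cos parameterisation). Theta and gamma peak frequencies cycle in
counterphase over 24 h: theta is fastest mid-dark, gamma mid-light.
`ld_distributions()` compares light- vs dark-phase peak-frequency
distributions with a two-sample KS test at the 0.001 level used for all
distribution comparisons.

Rather than synthesizing multi-day continuous recordings (a 48 h sweep at
512 samples/s would be ~88 million samples), `synthesize_snippets()`
generates short recordings whose clock start times step through the sweep;
the circadian carriers are functions of clock time, so 48 snippets of 90 s
carry the full 24 h modulation at ~2% of the sample count. This is the
problem size used by the tests and the acceptance script.

## Theta–gamma coupling

Coupling strength is the modulation index (MI): gamma amplitude is binned
by theta phase (18 bins of pi/9), the bin means normalised to a
distribution P, and MI = KL(P || uniform)/log(18), so MI is 0 for
phase-independent amplitude and 1 when all mass falls in one bin
(`modulation_index()`). MI is invariant to amplitude scaling and to joint
phase rotation. Significance against zero uses 200 circular time-shift
surrogates of the amplitude series (`mi_surrogate_test()`); the method
itself prescribes no surrogate construction, and circular shifts preserve
both marginals while destroying the phase alignment.

Coupling epochs are 8 s windows of a single state (AWAKE or REM) in which
*both* theta and gamma show significant whitened peaks
(`select_coupling_epochs()`); matrices require at least 10 such epochs.

* `fac_matrix()` — frequency–amplitude coupling: MI for every
  theta-frequency (1 Hz bins, 5–12) x gamma-frequency (10 Hz bins) pair.
* `pac_matrix_cycles()` — phase–amplitude coupling, per-cycle method:
  theta cycles are delimited trough-to-trough from the analytic phase,
  divided into 18 equal time segments of pi/9, and each 10 Hz gamma
  sub-band's peak-to-peak amplitude per segment enters the matrix as a
  median over cycles.
* `pac_matrix_hilbert()` — continuous method: per-bin mean gamma Hilbert
  amplitude over the continuous theta phase. The two methods agree on the
  preferred phase within one bin on all synthetic suites.

Gamma rows use 9 non-overlapping 10 Hz bins spanning 30–120 Hz by default;
an alternative scheme with 14 overlapping 10 Hz-wide bins over the same
range is selectable (`gamma_bins("overlap14")`), and every matrix records
its scheme. Matrices are averaged, Z-scored over cells, and
bicubic-spline-upsampled for display (`average_zscore_smooth()`); maxima
are always read from the raw averaged matrix
(`max_coupling_coordinates()`, ties to the lowest gamma bin and earliest
column). `preferred_phase()` refines the phase estimate with an
amplitude-weighted circular mean of the phase profile. A preferred phase
of 0 rad (theta peak) reproduces the control phenotype; pi (trough)
reproduces the reversed coupling of the menopause model.

## Inter-site delta synchrony

Connectivity between the two sites during NREM (or running) is quantified
on the delta-filtered Hilbert phases by the intersite phase clustering

```
ISPC = | n^-1 * sum_t exp(i (phi_x(t) - phi_y(t))) |
```

(`ispc()`), the phase-locking value: 1 for a constant phase relation
(including any fixed offset), ~sqrt(pi/(4n)) in expectation for independent
phases. `sliding_ispc()` tracks it in 2 s windows stepped by 0.1 s.
`phase_diff_summary()` histograms the wrapped phase differences (72 bins of
pi/36), fits a single Gaussian to the mode, derives the compound mean
frequency as the average of the two sites' mean instantaneous frequencies,
and converts the mean offset to milliseconds via
`lag_ms = rad / (2*pi*f) * 1000` (`rad_to_ms()`). `segment_xcorr()` adds
the zero-lag Pearson correlation of the filtered segments, the statistic
used for group comparisons. `delta_synchrony()` bundles all of these for a
segment (default 120 s; 10–20 s segments are used for the correlation
tables), trimming 1 s from each end after filtering.

In the generator, channel-2 delta is channel-1 delta shifted by a
configurable phase lag plus smooth jitter; jitter SD s yields an expected
ISPC of about exp(-s^2/2), so target ISPC values map directly onto
configuration. With jitter and background noise disabled the recovered
ISPC is 1 to within 1e-6.

## Event detection

Both detectors share one scheme: bandpass, rectify (square then square
root), short RMS envelope, z-score against an NREM baseline, threshold.
The baseline is estimated iteratively: a first pass detects candidates, the
baseline is recomputed with the detected spans excluded, and events are
re-detected — so rare large events do not inflate the noise estimate.

* SPW-R (`detect_spwr()`, vCA1 channel): ripple band 120–250 Hz (a
  150–250 Hz preset can be passed for display conventions), 20 ms envelope
  window, threshold z >= 3 with event boundaries extended to where z
  returns to 0, events merged when closer than 30 ms. Candidate runs whose
  supra-threshold core is shorter than 25 ms (~4 ripple cycles) are
  discarded: calibration showed a pure-noise envelope crosses z = 3 about
  once per second, so precision >= 0.95 requires a duration criterion. The
  extended onset often reaches into preceding noise, so the detector also
  reports `core_onset_s` (first supra-threshold sample), the appropriate
  quantity for onset-accuracy checks. Each event carries its dominant
  ripple frequency from a zero-padded FFT of its bandpassed samples.
* Spindles (`detect_spindles()`, mPFC channel): 10–30 Hz band, 30 ms
  envelope window, threshold 5 SD above the envelope baseline, minimum
  duration 5 ms (configurable; the envelope dips at carrier zero crossings,
  so runs closer than 50 ms — more than a half-cycle at the band centre —
  are merged first).

`validate_spw_baseline()` implements the electrode-placement check: the
event-window mean must sit within one SD of the two flanking equal-length
segments. On synthetic recordings with a strong clean ~2 Hz delta this
criterion is conservative — the sinusoidal drift moves 100 ms window means
while contributing little to the flank SD — so the check is validated on
templates over a stationary broadband background; on real broadband LFP
the flank SD absorbs the slow drift.

`couple_events()` measures, for every ripple, the latency to the next
spindle onset; a ripple is "followed" when the latency is within the
coupling window (default 5 s, reported with every summary). Note that with
Poisson event trains a windowed fraction also counts spindles coupled to
*other* ripples, so it exceeds the per-event coupling probability; the
truth-train summary is the reference for recovery checks.
`burstiness_memory()` summarises inter-event intervals with
B = (SD - mean)/(SD + mean) (-1 regular, 0 Poisson, towards 1 bursty) and
M = correlation of consecutive intervals.

## The synthetic generator

`sim_config()`/`synthesize()` produce two channels (mV) with per-second
ground truth. The study conditions are the defaults:

* **Schedule** — an alternating-renewal chain (AWAKE -> NREM; NREM -> REM
  with probability 0.5, else AWAKE; REM -> AWAKE) with exponential dwells
  whose means switch with the light phase (light: AWAKE 140 s, NREM 175 s,
  REM 80 s; dark: 240/105/80 s), giving an NREM-dominant light phase, an
  AWAKE-dominant dark phase and roughly 10% REM, the structure of the
  published state-fraction tables. REM only ever follows NREM.
* **Oscillators** — delta near 2 Hz with slow drift (the published compound
  delta frequencies are 1.9–2.45 Hz); theta 7.5 +/- 0.4 Hz and gamma
  80 -/+ 8 Hz as counterphase 24 h sinusoids of clock time; state-dependent
  band amplitudes in the hundreds-of-microvolt range of the published
  peak-to-peak amplitude tables. Gamma amplitude is modulated as
  (1 + d*cos(theta_phase - preferred))/(1 + d), which makes the configured
  preferred phase analytic.
* **Two-site delta** — channel 2 delta is phase-lagged and jittered as
  described above; theta/gamma are shared at 0.6 gain (volume-conduction
  shorthand).
* **Events** — NREM-only Poisson insertion with a short dead time (ripples
  0.15 s; spindles, template + 0.2 s): overlapping truth templates are not
  individually recoverable by any detector, so the recovery guarantees
  presume separated events. Ripples: 50 ms Hann-windowed 180 Hz bursts at
  0.44/s riding on a zero-mean low-frequency deflection (so the placement
  criterion holds by construction), amplitude 6x the ripple-band background
  RMS. Spindles: 300 ms 15 Hz bursts on channel 2, 14% of ripples followed
  at a truncated-normal latency (2.2 +/- 1.5 s), amplitude 8x band RMS.
  The 5 SD spindle threshold sets a hard floor on detectable amplitude
  (about 5.5x band RMS with these envelope statistics), which is why the
  inserted spindles are configured above it.
* **Background** — 1/f^alpha noise (alpha 1.0) by spectral shaping of white
  Gaussian noise, 15 uV RMS per channel, independent across channels.
* **Activity** — lognormal per-second draws, high-mean for AWAKE seconds,
  low-mean for sleep; the classifier uses only medians and order
  statistics.

A fixed seed yields bit-identical output. The tests and the acceptance
script run at 512 samples/s with 2 h staging blocks, 600 s event
recordings, 120 s coupling recordings and the 48 x 90 s circadian sweep —
sizes at which every stage's recovery statistics are stable across seeds.
All analysis parameters derive from the sampling rate; nothing is
hard-coded to the 2048 samples/s hardware rate.

What the generator does *not* emulate: broadband non-Gaussian transients,
movement and chewing artefacts, electrode drift, volume-conduction phase
mixtures beyond the shared-gain shorthand, theta harmonics, and
state-transition dynamics faster than 1 s. Passing recovery tests
therefore demonstrate the correctness of the analysis chain under the
stated signal model, not robustness to every artefact of real recordings.

## Statistics layer

Group differences use the non-parametric battery as published: two-tailed
Wilcoxon–Mann–Whitney for unpaired and Wilcoxon signed-rank for paired
samples (exact p-values for small samples), Kruskal–Wallis across groups,
and KS for distributions (alpha 0.001; all others 0.05). Multiple
comparisons after a significant Kruskal–Wallis use the Dunn–Holland–Wolfe
construction for unequal sample sizes: pairwise mean-rank differences
against tie-corrected normal critical values with a family-wise
(Bonferroni-over-pairs) adjustment; calling it without a significant
omnibus test is refused, mirroring the published gating.

Effect sizes use Cohen's d exactly as printed,
`d = |M1 - M2| / sqrt((SD1^2 + SD2^2)/2)`, with the scale anchored at
small (d <= 0.2), medium (0.5), large (0.8) and very large (>= 1.2);
label boundaries are midpoints between anchors (0.35, 0.65, 1.2), since
the anchors themselves are points, not intervals. The package ships a
reference table of group means/SDs from the menopause-model study
(`reference_group_stats()`); `replicate_effect_sizes()` recomputes every
d from it. Rows whose printed d cannot be reproduced from its own printed
mean/SD pair (the running-wheel metrics, the spindle rate, and the
SPW-R rate, which is printed with a sign the |.| formula cannot produce)
are flagged `consistent = FALSE` and listed rather than matched.

## Reproducing the analyses

The `analysis/` scripts run the full chain on synthetic study-condition
recordings (`01_simulate.R` through `07_statistics.R`), writing tables
under `results/`. `scripts/acceptance.R` recomputes the headline
quantities from scratch with a supplied seed; see the README.

## Known limitations

* The staging classifier assumes the G/D histogram of a block is bimodal;
  blocks without sleep (or without wake) degrade to a flagged fallback.
* The sharp-wave placement check is conservative when slow oscillations
  dominate the within-event variance (see above).
* The 5 ms spindle duration floor is far below conventional spindle
  durations; it is implemented as printed and configurable.
* The "followed by a spindle" fraction depends on the coupling window and
  on the spindle base rate, not only on the per-ripple coupling
  probability; summaries always report the window.
* Segment lengths for the delta-synchrony tables (10, 20 or 120 s) are a
  configuration knob; defaults follow the published usage per statistic.
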