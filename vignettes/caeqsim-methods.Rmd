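---
title: "Methods: simulating distortion detection and audio quality in complex acoustic environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating distortion detection and audio quality in complex acoustic environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caeqsim)
```

## What the package simulates

Hearing-impaired listeners often cope well with degraded audio in quiet but
struggle as soon as interfering sources and reverberation are added. The
experimental paradigm this package implements probes that question with two
linked measurements: adaptive *detection thresholds* for four parametric
signal distortions, and MUSHRA-style *suprathreshold quality ratings* of the
same distortions, both obtained in auralized rooms with configurable masker
layouts. Because every stage — stimuli, rooms, hearing-loss compensation,
adaptive procedure, listeners — is synthesized, the full pipeline runs at
desk scale with no human data and no external recordings.

The simulation chain is: calibrated target and masker signals → parametric
distortion → binaural room auralization → NAL-R compensation → a simulated
psychometric listener driving a 1-up/2-down 3-AFC staircase or a 0–100
rating session → threshold, reliability, SDDR and correlation analyses.

## Signals and calibration

All stimuli are mono or stereo waveforms at 44.1 kHz wrapped in
`audio_signal`, which carries a calibration constant: a full-scale sinusoid
corresponds to 100 dB SPL. The constant is arbitrary — every level in the
experiments is relative (targets and maskers at 63 dB SPL, comfort offsets
of ±5 dB) — but it is carried explicitly so that `set_level()` and
`measure_level()` round-trip exactly. The digital headroom of the original
stimuli is not documented anywhere, so any fixed convention is equally
valid; 100 dB SPL leaves the 63-dB working range far from clipping.

Two target generators are provided. `generate_pink_noise()` shapes white
Gaussian noise in the FFT domain with a $1/\sqrt{f}$ magnitude between
10 Hz and Nyquist, giving the stationary 1/f-power target; the test suite
checks per-octave energy flatness to within 1 dB. The speech target of the
original paradigm was a German female recording that is not distributable;
`generate_speech_surrogate()` stands in for it with a band-limited
(100 Hz–8 kHz, −6 dB/oct above 500 Hz) noise carrier modulated by a
positive envelope whose modulation spectrum peaks near 5 Hz — the two
properties (narrowband spectrum, slow ~5 Hz envelope) that drive masking
and distortion audibility in this paradigm. It does *not* reproduce
phonetic structure, pitch contours or pauses, so conclusions about
speech-specific cues (e.g. fundamental-frequency segregation) are outside
what passing tests can show. The maskers are surrogates in the same
spirit: `generate_masker("speech")` for the nonsense-speech masker and
`generate_masker("music")` — broadband noise with slow ~2-Hz modulation —
for the pop-music excerpt.

Trial timing follows the experimental procedure: in rating mode maskers
lead the target by 0.5 s (2.5-s maskers around a 2-s target); in detection
mode all onsets are simultaneous; 10-ms raised-cosine ramps shape every
stimulus. Detection-trial targets are 1-s segments drawn
seed-deterministically from a 2-s parent signal.

## The four distortions

* **Spectral ripple** (`apply_spectral_ripple`): a zero-phase filter whose
  log-magnitude is sinusoidal in log2-frequency, ten periods between 50 Hz
  and 16 kHz (≈1.2 ripples/octave, `ripple_density_per_octave()`), with
  peak-to-valley depth in dB as the amount. The ripple phase is a cosine
  with its maximum at 50 Hz and the out-of-band gain is unity; neither is
  documented for the original filter, so both are fixed conventions here.
* **Nonlinear saturation** (`apply_saturation`): the memoryless cubic
  $y = x - \alpha x^3$, clipped for $|x| > x_c = 1/\sqrt{3\alpha}$ to the
  stationary value $\tfrac{2}{3}x_c$ (complete, "soft" saturation; the
  published input-limit expression is typographically corrupted, and
  $1/\sqrt{3\alpha}$ is the unique point where the cubic's slope reaches
  zero).
* **Intensity** (`apply_intensity`): a pure broadband gain in dB.
* **Spatial** (`render_scene` at a nonzero target azimuth): the target is
  re-rendered at an offset azimuth instead of 0°, leaving the signal
  itself untouched.

The MUSHRA-style anchor (`make_anchor`) cascades an 8th-order Butterworth
low-pass at 3.5 kHz (order chosen to make the band limitation clearly
audible; only the cutoff is documented), saturation at $\alpha = 0.55$,
and rendering at 40° azimuth.

### THD metrology and the calibrated peak amplitude

The printed saturation amounts pair each $\alpha$ with a "THD at the peak
of the reference signals" in percent, but the underlying signal peak is
unstated. `thd_at_peak()` drives the clipper with a steady sinusoid and
measures harmonics from an exact single-cycle Fourier analysis
($2^{14}$ points, 64 harmonics); `calibrate_peak_amplitude()` then inverts
one or more (α, THD) pairs for the single shared amplitude $A^*$. Two THD
conventions are computed: fundamental-referenced (harmonic RMS over
fundamental RMS, IEC style) and total-referenced. The fundamental-referenced
convention is the primary one because, with one shared amplitude
($A^* \approx 1.99$ full-scale), it reproduces all seven printed pairs to
within 0.5 percentage points (the test suite asserts this); the
total-referenced variant cannot match the high-α pairs with any shared
amplitude. In the weakly nonlinear regime ($\alpha A^2 \ll 1/3$) the
implementation agrees to three significant figures with the closed-form
cubic expansion $\mathrm{THD} = 100\,\frac{\alpha A^2/4}{1 - 3\alpha A^2/4}$,
which the tests use as an independent oracle.

## Rooms and binaural auralization

Two shoebox rooms are modelled: `room_lrl()` (4.97 × 3.78 × 2.71 m, 51 m³,
target T60 0.5 s) and `room_large()` (7.5 × 4.52 × 3 m, ≈100 m³, T60
1.5 s). `scene_placement()` reconstructs the study geometry from the
printed quantities — target distances 2.55 m (LRL) and 2 m (Large), maskers
at ±45° and 1.59 m/2 m, heights 1.05/1.10/1.02 m and 1.7 m. Exact
coordinates were never published; the receiver faces the long axis with a
0.3-m lateral offset from the centreline, which realizes the documented
asymmetric arrangement. In the LRL the separated maskers are attenuated by
the inverse-distance ratio 1.59/2.55 so that they present approximately
the level of a 2.55-m source, the documented intent ("approximately the
same level"); the exact gain the original used is unknown.

`synthesize_brir()` builds each binaural room impulse response in three
parts:

1. **Early reflections**: image sources up to order 3 with a uniform,
   angle-independent wall reflection coefficient
   $\sqrt{1-\bar\alpha}$, where $\bar\alpha$ solves Eyring's formula
   $\bar\alpha = 1 - e^{-0.161 V / (S\,T_{60})}$ for the target T60. The
   published rooms specify only volume and average T60, so a uniform
   broadband absorption is the minimal model consistent with them.
2. **Late tail**: an 8-line feedback delay network (delays staggered
   around the room's mean free path $4V/S$, Householder feedback, per-line
   gains $10^{-3 d_i/(f_s T_{60})}$), with decorrelated left/right output
   taps, starting at the third-order reflection horizon. Its overall
   energy is set by the diffuse-field balance
   $E_{rev}/E_{dir} = 16\pi r^2 / A$ with the Eyring equivalent absorption
   area $A = S\bar\alpha/(1-\bar\alpha)$, minus the reverberant energy the
   explicit image sources already carry. This makes the T60 of the
   synthesized response exact by construction and the
   direct-to-reverberant ratio physically plausible without free knobs.
3. **Binaural cues**: a spherical-head model — Woodworth ITD
   $\tau = \frac{a}{c}(\varphi + \sin\varphi)$ with head radius
   $a = 8.75$ cm, and a first-order head-shadow shelf per image source
   (high-frequency gain $1 \pm \sin\varphi$, corner at $2c/a$). This
   replaces the measured-HRTF rendering of the original room simulator,
   so the printed per-ear DRR values are *not* reproduction targets; the
   package asserts only the qualitative facts that survive the model
   change: T60 within 15% of target, ITD signs matching azimuth signs,
   and the LRL's frontal-target DRR exceeding the Large room's. That last
   ordering emerges from the geometry: at the printed ~1.05-m heights the
   LRL's floor reflection arrives ~2.3 ms after the direct sound and is
   folded into the ±2.5-ms direct window of `compute_drr()`, whereas in
   the Large room (1.7-m heights, shorter target distance) it falls well
   outside.

`estimate_t60()` uses Schroeder backward integration with a T30 line fit
(−5 to −35 dB, extrapolated to 60 dB) averaged over ears, and refuses
responses whose decay range is insufficient.

## Hearing loss, NAL-R and PTA

Audiograms cover 125 Hz–6 kHz. The two impaired cohorts follow the
standard N1 ("very mild") and N3 ("moderate") prototype profiles from the
standard-audiogram literature (Bisgaard et al. 2010), embedded as fixtures
because the study's own audiograms are only published as figures;
`generate_audiogram()` jitters them by ±5 dB per ear and frequency,
clamps interaural asymmetry to ≤10 dB (the cohorts are symmetric by
inclusion criterion) and rounds to 5 dB as in clinical audiometry.

`nal_r_gains()` implements the linear NAL-R prescription
$IG_f = X + 0.31\,H_f + k_f$, $X = 0.05 (H_{500}+H_{1000}+H_{2000})$, with
the standard Byrne & Dillon (1986) constants $k_f$ (−17, −17, −8, +1, −1,
−2, −2, −2 dB from 125 Hz to 6 kHz; the 125-Hz entry extends the 250-Hz
constant since the prescription tables start at 250 Hz), floored at 0 dB.
Note one consequence faithfully kept: a flat 0-dB-HL audiogram prescribes
+1 dB at 1 kHz, not exactly zero. `apply_compensation()` realizes the
table as a 1024-tap minimum-phase FIR (log-frequency interpolation,
real-cepstrum minimum phase); probe tones verify the realized gain within
±1 dB at the audiometric frequencies. The comfort offset is the ±5/0 dB
broadband adjustment listeners chose relative to the NAL-R level; cohort
generation draws it with the observed 14:8:2 proportions.
`pta_better_ear()` is the better-ear mean over 0.5/1/2/4 kHz.

## The adaptive procedure

`run_staircase()` implements the transformed up-down track: 3-AFC,
1-up/2-down (70.7% point, `staircase_convergence_probability()`), additive
steps in the printed units with the four printed schedules
(`standard_staircase()`): start/initial/minimum = 30/5/1.5 dB (ripple),
0.82/0.2/0.035 (α), 8/2/0.4 dB (intensity), 28/4/0.5° (spatial). The
original procedure names only initial and minimum steps; this
implementation halves the step at each reversal until the minimum is
reached — the default behaviour of the AFC framework family it follows —
and then collects exactly six reversals, whose mean is the run threshold;
the reversal at which the step first *becomes* minimal is not collected.
Two independent runs are averaged (test–retest). Amounts are floored at 0,
and a 400-trial cap guards non-converging observers, returning the partial
track with a warning.

The simulated observer answers correctly with probability
$$p(x) = \gamma + (1-\gamma-\lambda)\,F\!\Big(\frac{g(x)-g(t)}{\sigma} + c_0\Big),$$
with guess rate $\gamma = 1/3$, lapse $\lambda \le 0.05$, logistic $F$,
and $g = \log$ for the ratio-like amounts (ripple depth, α) or the
identity for the dB/degree amounts. The offset $c_0$ is chosen so that
$p(t) = 2^{-1/2}$ exactly: the configured threshold *is* the 70.7% point
the track estimates, which is what makes parameter-recovery checks
well-posed. Psychometric spreads are free parameters (none are published);
the defaults are 0.25 log-units for ripple/saturation, 0.8 dB for
intensity and 2° for spatial. For the convergence checks the observer's
spread is set to one minimum step of the schedule under test — steep but
realistic for these highly discriminable cues, and it keeps the six
measured reversals inside the psychometric function's dynamic range. The
simulation sizes used by the tests and the acceptance script (200–400
tracks per estimate) were chosen so that Monte-Carlo error is a fraction
of a minimum step.

## Simulated listeners, ratings and SDDR

`generate_cohort()` builds listeners per group (YNH / ON1 / ON3) from
group-level mean thresholds per distortion and context
(`default_threshold_table()`), with 15% lognormal individual scatter and,
in the masked context, a coupling of thresholds to the individual
better-ear PTA. The table encodes the qualitative pattern of the study —
masked thresholds ON3 > ON1 for every distortion, saturation thresholds
strongly increasing with hearing loss, near-equal unmasked ripple and
intensity thresholds for the two impaired groups — with effect sizes that
are free parameters of the generator, *not* reproductions of the published
group data (human results are outside what this artifact can or should
reproduce). Test and retest are independent seed streams.

`simulate_rating()` maps an item's perceived distance
$d = \max(0, \log_2 \mathrm{SDDR})$ (doublings above the individual
threshold) to a score $100 - s\,d$ with slope $s = 18$ per doubling, plus
a group-dependent masker term — for YNH/ON1 a partial-masking release
$+m(1-2^{-d})$ that raises scores of distorted items only, for ON3 a flat
penalty on every masked item including the hidden reference — plus
Gaussian noise (sd 5), clipped to integers in [0, 100]. The anchor's
distance adds a fixed two-doubling excess for its low-pass and spatial
stages on top of its α = 0.55 saturation. These constants were chosen once
to satisfy the scale-anchoring constraints (hidden reference ≥ 95 without
maskers; anchor lowest in the session for ON1; maskers dissociate ON1 and
ON3 in opposite directions) and are configurable per listener.

`sddr()` is the signal distortion-to-detection ratio — applied amount over
individual threshold, 1 at threshold. `sddr_rating_summary()` assembles
the group × room × kind × level table of mean SDDR against mean rating
score; on default cohorts the rank correlation across cells is strongly
negative, the construction behind the threshold-vs-quality linkage.
`test_retest_pcc()` and `threshold_pta_correlation()` are thin, validated
wrappers around Pearson correlation (with a two-sided t-test and .05/.01
stars, no multiple-testing correction, matching the reporting convention
of such tables); degenerate inputs (zero variance) raise errors rather
than silently returning 0.

## Numerical choices and degenerate inputs

* All random generation is seed-deterministic; functions restore the
  caller's RNG state, and nested structures (cohorts, sessions) derive
  child seeds below $2^{31}$.
* Spectral shaping, ripple filtering and convolution are FFT-domain and
  zero-phase where a filter is conceptually a transfer magnitude;
  compensation uses a causal minimum-phase FIR because it models a
  hearing-aid-like device.
* `set_level()`, `snr_db()` and `measure_level()` reject all-zero signals
  (undefined gain); ramps longer than half the signal, negative ripple
  depths, non-positive α, amounts or thresholds, missing audiometric
  frequencies, out-of-room sources, insufficient decay ranges and
  malformed rating item sets all raise immediate errors with specific
  messages.
* `compute_drr()` caps the degenerate all-direct case at +60 dB instead of
  returning infinity.

## Limitations

The speech and music surrogates capture envelope and spectral statistics,
not linguistic or musical structure; the spherical-head model has no
pinna cues, so elevation and front/back effects are out of scope and
published per-ear DRR values are matched only in ordering; the rating
model is a descriptive construction whose group effect sizes are
assumptions, so simulated rating magnitudes carry no empirical weight —
only the procedural machinery (scales, anchoring, reliability statistics,
SDDR logic) is validated. Octave-band-resolved absorption and
frequency-dependent T60 targets are not modelled because the study
specifies a single average T60 per room.
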