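---
title: "Transdermal spatiotemporal multispectral features: models, parameters and design choices"
author: "tstms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TSTMS methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the forward model behind the synthetic data, the signal-processing and
classification procedure, the tunable parameters with their defaults and
rationale, the numerical choices, and the limits of what the synthetic
validation can show about real recordings.

## 1. The physiological signal and its optical model

Cardiac pulsation changes arterial volume, which changes the optical path
length light travels through skin before diffuse reflection. With a
constant specular term $R_S$ and Beer–Lambert attenuation, a reflective
camera pixel sees

$$I_\lambda(x,y,t) \;=\; R_S + A_\lambda(x,y)\,
  e^{-\alpha_\lambda\, z(x,y,t)}, \qquad
  z(x,y,t) = z_0 + \Delta z(x,y)\,\frac{1+\sin(2\pi f t + \phi(x,y))}{2},$$

where $f$ is the heart rate, $\alpha_\lambda$ the wavelength-dependent
absorption (hemoglobin peaks at blue/green: the package enforces
$\alpha_B \ge \alpha_G > \alpha_R$, with NIR intermediate), and
$\Delta z$ the pulsatile path-length modulation. Two identities anchor
everything downstream: at a pixel's pulse peak and trough,

$$I_{AC} = I_{max}-I_{min} = A e^{-\alpha z_0}(1 - e^{-\alpha \Delta z}),
\qquad
I_R = \ln\frac{I_{max}}{I_{min}} = \alpha\,\Delta z \quad (R_S = 0).$$

$I_R$ cancels the static tissue factor $A e^{-\alpha z_0}$; $I_{AC}$ is
invariant to additive offsets but not to gain, and $I_R$ the reverse —
this asymmetry is asserted in the test suite. The thermal (LWIR) channel
carries no pulsatile term, only a slow drift
$T(x,y,t) = T_0 + r(x,y)\,t$; that matches the empirical finding that
thermal video lacks usable heart-rate frequency content.

## 2. What the simulator emulates — and what it does not

`renderRecording()` draws the face as an ellipse (semi-axes 18 rows × 10
columns, centered at (27, 18) on the 50 × 35 analysis grid, reaching into
the bottom rows so chin-mask handling is exercised) on a cooler, darker
background, applies the forward model above on the grid, upsamples each
frame to the native sensor resolution (bicubic), adds Gaussian sensor
noise, and quantizes reflective channels to 8 bits. Class identity enters
only through a `ClassTemplate`: a face-wide baseline modulation
$\Delta z$ = 0.15 depth units plus a class-specific regional boost of
0.25 — amusement on the cheeks, disgust on the forehead, fear on the
mouth, sexual arousal on the eye region plus a +0.3 Hz heart-rate offset,
neutral nothing (smallest template energy by construction). Temperature
drifts of ±0.02 °C/s follow the same regions. No quantitative
per-emotion effect sizes are available for real faces, so these
magnitudes are free parameters exposed through
`defaultClassTemplates(strength=)`; `strength = 0` produces the
negative-control cohort whose labels carry no signal.

Two simulator parameters deserve explanation because they are not part of
the optical model:

* `phaseAmplitude` (default 0.3 rad): a smooth spatial phase field
  mimicking pulse-transit-time variation across the face. At 0, every
  pixel pulses in phase and the discrete sampling grid hits the analytic
  extremes exactly — the *exact-oracle mode* used by the Beer–Lambert
  equivalence tests (closed forms to 1e−9 unquantized, ±1 gray quantized).
* `ampJitterSd` (default 0.2, log scale): a per-trial multiplicative
  factor on $\Delta z$, emulating vasomotor-tone variation between
  trials. Without it the synthetic classes are separable by a *single
  pixel*, gradient-boosting importance collapses onto one arbitrary
  column, and spatial localization analyses are vacuous. With it, single
  pixels overlap between classes while the joint spatial pattern remains
  informative — qualitatively the regime real data live in.

Subject-level parameters (resting heart rate uniform in 0.9–1.9 Hz, skin
baselines, 33–36 °C skin temperature, the phase field) are drawn once per
subject and shared across trials. Native resolutions default to 200 × 140
(RGB) and 100 × 70 (NIR, LWIR) — each dimension at least twice the
analysis grid, preserving the RGB > NIR ≈ LWIR ordering of real rigs at
tractable cost; the analysis operates on the common 50 × 35 grid, so the
native scale matters only through the pooling-noise statistics.

Not emulated: facial structure and expression, head motion, blinking,
illumination changes, melanin/skin-tone diversity, camera vignetting.
Consequently, a green test suite demonstrates that the *pipeline*
recovers what the forward model puts in — it does not demonstrate that
real faces carry class-discriminative transdermal patterns, nor that the
classifier would reach any particular accuracy on human data.

## 3. Preprocessing

Trials are sliced to their initial 120 frames (4 s at 30 fps; shorter
trials are excluded with a logged reason). Temporal slicing precedes
spatial downsampling; the order is mathematically immaterial and fixed
for reproducibility. Reflective channels are cropped to the face (an
explicit box bypasses the pluggable detector — always the case for
synthetic data; the bundled default detector is an Otsu-threshold
bounding box). The thermal channel is segmented by Otsu thresholding
followed by zeroing everything below 30 °C. Downsampling is two-stage:
non-overlapping block means (10 × 10 for R, G, B; 5 × 5 for NIR, LWIR;
frames sliced to a whole number of blocks), then bicubic resampling to
50 rows × 35 columns. Both stages are linear, so they are composed into
one per-axis operator and applied to all frames as two matrix products.
Grid orientation: 50 = rows = face height, origin top-left. Channels are
registered only through this shared resolution — no subpixel alignment.

Bicubic interpolation is the separable Keys kernel ($a=-0.5$,
Catmull–Rom), pixel-center aligned with edge clamping; its weight rows
sum to one for any phase (constants are preserved exactly, linear ramps
reproduced) — both properties are unit-tested. No installed package
provides bicubic resampling, hence the 15-line implementation.

## 4. Heart-rate estimation (F8)

Green channel only. Each pixel's 120-sample series is band-pass filtered
at 0.75–4 Hz with a Butterworth of design order 6, applied
forward–backward (zero phase, so event timing is unshifted, and DC is
removed exactly). Two numerical choices matter:

* **Second-order sections.** The order-12 band-pass polynomial that
  `signal::butter` returns is numerically degenerate in a direct-form
  recursion at double precision — the upper stop band simply does not
  materialize in the time domain. The filter is therefore refactored into
  biquads (poles paired with one $z=+1$ and one $z=-1$ zero each) and run
  as a cascade with per-section steady-state initial conditions and
  odd-reflection padding. Stop-band contracts (> 20 dB one octave outside
  the band) are asserted on the frequency response; on 120-sample windows
  the forward–backward edge transient makes time-domain stop-band
  measurements unreliable for any implementation.
* **Band edges.** 0.75–4 Hz (45–240 bpm) is the default; the lower edge
  is configurable because published descriptions of this procedure vary
  between 0.75 and 0.8 Hz.

The per-pixel dominant positive-frequency FFT argmax (resolution
$fs/T$ = 0.25 Hz) forms a 2-D frequency map; alongside it the package
records the spectral magnitude at that argmax. The map is blurred with a
uniform 5 × 5 kernel (replicated edges; a Gaussian would behave
equivalently at this scale), binarized by Otsu, opened with a 5 × 5 box,
and the mask multiplies the frequency map. The binarization runs on the
*peak-magnitude* map: skin pixels concentrate spectral energy at the
heart rate while background pixels spread theirs, so Otsu's upper class
is the pulsatile region for any in-band heart rate. (Binarizing the
frequency *values* instead fails whenever the heart rate lies below the
background's mean argmax of ≈2.4 Hz — the mask inverts; this was
verified on simulation and is why the magnitude map is the basis. Given
a bare matrix of frequencies the function falls back to keeping the
threshold class with the smaller within-class variance.) F8 is the
median of the masked non-zero frequencies; for an even count the median
is the mean of the two central values. Recovery is within one FFT bin
for ≥95% of simulated subjects across 0.9–1.9 Hz.

## 5. Pulse events and the pulse-frame stacks

Peaks are detected per pixel on the min–max normalized band-passed
series — the prominence thresholds (0.4 for G and NIR, 0.2 for R and B)
are only meaningful on a normalized scale — with minimum separation
$\lceil 0.75\, fs / hr \rceil$ frames (three quarters of a cardiac
cycle). Prominence is topographic (height above the lowest contour
enclosing only that peak); candidates failing prominence are removed
first, then closer-than-minimum pairs are resolved in favor of the higher
peak. Troughs are peaks of the negated series under the same thresholds.
Note one edge effect inherent to topographic prominence: an extremum
within a quarter-cycle of the series end has its prominence capped by the
short tail and can fall just under threshold — zero padding absorbs the
resulting variation in event counts.

Each peak is paired with the nearest *following* trough (the same
cardiac cycle; a trailing unmatched peak is dropped). A pair whose
intensities are inverted or negative (a noise artifact, not a pulse) is
skipped — this is what makes $I_{max} \ge I_{min} \ge 0$ hold wherever
pairs exist. The first five pairs populate pulse indices 1–5; fewer are
zero-padded, more are truncated — the printed 5 × 50 × 35 dimensionality
is fixed. Intensities are read from the band-passed series with the
pixel's temporal mean restored: band-limiting rejects noise spikes while
the restored DC keeps $\ln(I_{max}/I_{min})$ well-defined and preserves
amplitude information. Pixel-level event times are not aligned across
pixels; the pulse index is ordinal (first beat, second beat, ...), which
is also why F1's five thermal samples — the 0.75 Hz-low-passed LWIR
series sampled every $fs/1.5$ = 20 frames — are treated as an
independent five-sample axis rather than as simultaneous with the pulse
frames (they cannot be, exactly).

## 6. Features, flattening, chin mask

F1–F7 assemble exactly as in the README table, with a uniform zero guard:
divisions by zero, logs of non-positive values and padded entries all
yield 0, the same "no signal" code the zero padding already uses. The
chin mask (default: bottom 6 of 50 rows, configurable; the extent of a
chin-mount obstruction is rig-specific) zeroes F1–F7 but never shortens
the vector, keeping 8750 parameters per feature; masks covering more than
30% of the grid are rejected as suspicious. Flattening is F1..F7 in
(pulse, row, col) raster order followed by the scalar F8 — 61,251 values
— with an invertible index map (`featureIndexMap()`). Cross-wavelength
features at other channel pairs are deliberately not in the default
vector; the B/R pair carries the largest absorption contrast.

## 7. Classification and evaluation

One-vs-one gradient boosting: $k(k-1)/2$ binary xgboost models
(`binary:logistic`), each trained on its two classes with per-sample
weights $w_i = n/(k\,n_i)$ computed from the full training distribution —
balanced classes give unit weights, the rarest class the largest.
Coupling: per class, average the pairwise probabilities in its favor over
the $k-1$ pairs involving it, then renormalize rows to sum to one.
Defaults (`boostParams()`): 60 rounds, depth 3, learning rate 0.3,
`colsample_bytree` 0.3, single-threaded with a fixed seed. Column
subsampling is essential at $p \gg n$ with strongly correlated pixel
columns: it regularizes, and it spreads split gain across an informative
*region* instead of crediting one arbitrary member pixel — without it the
spatial importance maps degenerate to single points.

Evaluation is leave-one-subject-out: folds iterate subjects in sorted
order; the held-out subject's trials are undersampled (seeded) to its
smallest class so that chance levels are exactly 0.2 (subset accuracy)
and 0.5 (AUC); training is never undersampled — imbalance is handled by
the loss weights. Reported: fold-averaged one-vs-rest ROC AUC per class
(folds lacking both classes for a given AUC are omitted from that
average), fold-averaged balanced accuracy (mean of one-vs-rest
sensitivity and specificity of the final decisions), overall subset
accuracy, and the elementwise median of per-fold confusion matrices,
row-normalized to 100%.

## 8. Importance analysis

`lfcImportance()` scores each of the 61,251 parameters. The native mode
sums the boosting backend's loss-reduction (gain) over the ensemble's
binary models — a parameter no tree uses scores exactly zero, which is
also why chin-masked (constant) columns always carry zero importance. The
permutation surrogate measures the increase in multiclass log-loss when a
column is permuted (seeded; negatives clipped), with a slab mode that
permutes whole (feature, pulse) planes when per-column cost is
prohibitive. Both normalize to percent, summing to 100 with the F8 share.
Aggregations: per-feature spatial maps (sum over pulse frames) and their
mean summary; per-pulse-frame temporal profile; independent binary
retrainings per class pair (pairwise maps — retraining, not reusing the
multiclass submodels, so each map reflects only its pair); ROI means with
SDs across folds and a seeded bootstrap (10⁴ resamples over folds,
two-sided) for ROI-vs-rest comparisons — chosen because the available
summary structure of such analyses is mean ± SD across cross-validation
iterations; and per-group reruns (e.g. gender). Default ROIs (forehead,
eyes, cheeks, mouth) coincide with the simulator's template regions,
which is what makes localization testable: over seeded cohorts with a
cheek-modulated class against neutral, the mean importance inside the
true region must exceed outside with a permutation p < 0.05 in at least
9 of 10 cohorts. Two aspects of that check are deliberate. First, the
"true region" is the template support dilated by the downsampling kernel
radius (about 7 grid pixels): the two-stage downsampling spreads a
modulated region's signal into a halo, and at the halo's rim sits a
*detection cliff* — pixels where one class's bled-through pulse crosses
the peak-detection threshold and the other class's does not, which makes
them extremely informative. Importance landing there is correct
localization at the pipeline's spatial resolution, so the reference
region must include it. Second, per-cohort maps are averaged over the
LOOCV fold models before testing, as the method's spatial analyses
average over cross-validation iterations; a single model's gain can
concentrate on two or three pixels, where a pixel-permutation test has
essentially no power regardless of how well the region was found.

## 9. Validation scale and reproducibility

The problem sizes used by the shipped validation were chosen once, as a
balance between statistical resolution and the cost of rendering
multispectral video in a test run: the end-to-end classification
criterion uses 10 subjects × 5 classes × 6 trials (300 trials; macro
one-vs-rest AUC ≥ 0.90 expected under strong templates, subset accuracy
tested against 0.2 by a binomial test at p < 0.01), the negative control
5 subjects × 5 × 2 with null templates (must stay inside the central 99%
binomial band around 0.2), heart-rate recovery 20 subjects spanning
0.9–1.9 Hz, and importance localization 10 cohorts of 4 subjects × 2
classes × 3 trials. The acceptance script re-simulates smaller cohorts
(8 × 5 × 4; 6 localization cohorts) under its own seed. Every stochastic
step — cohort draws, per-trial rendering, undersampling, training,
permutation and bootstrap resampling — is seeded, and identical seeds
reproduce recordings, feature matrices and metrics bit-for-bit.

## 10. Known limitations

* The synthetic faces are optically ideal ellipses; none of the
  photometric confounds of real faces (motion, expression, specular
  highlights, skin-tone diversity) are modeled, so synthetic accuracy
  says nothing quantitative about human-data accuracy.
* Pulse-frame alignment is ordinal; beats are not synchronized across
  pixels or with F1's thermal samples.
* The frequency map's 0.25 Hz resolution bounds heart-rate accuracy; no
  interpolation between FFT bins is attempted.
* Gain-based importance is attribution within one fitted ensemble, not a
  causal statement; the permutation surrogate shares the usual caveat
  about correlated columns (permuting one leaves its correlates in
  place).
* CatBoost-style ordered boosting is not available in this environment;
  xgboost's gradient boosting stands behind the same module surface.
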