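# tstms

Remote emotional-state classification from multispectral face video,
driven by transdermal spatiotemporal multispectral (TSTMS) features.

Emotional states modulate autonomic physiology — blood volume, hemoglobin
concentration, skin temperature — and those changes are visible to cameras
at different wavelengths: pulsatile intensity fluctuations in RGB and
near-infrared (remote photoplethysmography, rPPG), and slow temperature
changes in long-wave infrared (LWIR). `tstms` implements a complete
pipeline that turns synchronized RGB + NIR + LWIR face recordings into an
emotion classification (amusement **A**, disgust **D**, fear **F**, sexual
arousal **S**, neutral **N**) with spatial, temporal and per-wavelength
feature-importance maps. Because raw human recordings of this kind are not
publicly deposited, the package ships a first-class synthetic
multispectral video simulator with known ground truth, used to exercise
and validate every stage end to end.

## The method

Each ≥4 s trial is sliced to its initial 120 frames (30 fps), the face is
localized per channel (explicit boxes or a pluggable detector for the
reflective channels; Otsu thresholding plus a 30 °C rule for the thermal
channel), and all five channels are downsampled in two stages —
block-mean pooling (10×10 for R, G, B; 5×5 for NIR, LWIR) then bicubic
interpolation — onto a common 50 × 35 grid.

The heart rate (feature **F8**, `HR^G`) comes from the green channel: each
pixel's series is band-passed (0.75–4 Hz, 6th-order Butterworth, zero
phase), the per-pixel dominant FFT frequency forms a 2-D frequency map,
which is blurred (5×5), Otsu-binarized, cleaned by a 5×5 morphological
opening, and F8 is the median of the masked non-zero frequencies.

Per pixel and reflective channel, pulse peaks and troughs are detected on
the min–max normalized band-passed series with a minimum separation of
`ceil(0.75 · fs / hr)` frames and topographic prominence ≥ 0.4 (G, NIR) or
0.2 (R, B); the first five peak/following-trough pairs form the
pulse-frame stacks `Imax`, `Imin` (zero-padded). Writing
`I_AC^λ = Imax − Imin` and `I_R^λ = ln(Imax / Imin)` (a Beer–Lambert
absorption measure), the features are

| feature | definition | carries |
|---|---|---|
| F1 | `TMP^LWIR` — thermal series low-passed at 0.75 Hz, resampled at 1.5 Hz | temperature drift |
| F2–F4 | `I_AC^R`, `I_AC^G`, `I_AC^B` | pulsatile amplitude |
| F5 | `I_AC^B / I_AC^R` | cross-wavelength amplitude dissimilarity |
| F6 | `abs((I_R^R − I_R^B) / (Imax^R − Imax^B))` | baseline-adjusted absorption difference |
| F7 | `I_AC^NIR` | NIR pulsatile amplitude |
| F8 | `HR^G` | estimated heart rate (Hz) |

F1–F7 each live on a 5 × 50 × 35 (pulse, row, col) grid — 8750 parameters
per feature — and flatten with F8 into a 61,251-value vector per trial.

Classification is one-vs-one gradient boosting (10 binary models for 5
classes) under leave-one-subject-out cross-validation: training uses
inverse-frequency class weights
`w_i = n_samples / (n_classes · n_samples_i)` in the loss; each held-out
subject's trials are randomly undersampled to its smallest class before
scoring. Reported metrics: per-class one-vs-rest ROC AUC, per-class
balanced accuracy, overall subset (exact-match) accuracy, and the
row-normalized elementwise median of the per-fold confusion matrices.
Per-parameter importance (native gain or a seeded permutation surrogate)
is aggregated into per-feature spatial maps, a per-pulse-frame temporal
profile, pairwise-classifier maps, region-of-interest statistics and
grouped (e.g. per-gender) analyses.

## Worked example

```r
library(tstms)

co  <- makeCohort(6, trialsPerClass = 3, seed = 11)   # 6 subjects x 5 x 3
fm  <- cohortFeatureMatrix(co)                        # 90 x 61,251
rep <- evaluateLoocv(fm$x, fm$meta, seed = 5)
rep
#> MetricsReport | LOOCV over 6 subjects
#>   macro ROC AUC: 0.990 | subset accuracy: 0.922
round(rep@aucPerClass, 3)
#>     A     D     F     N     S
#> 1.000 1.000 0.993 0.984 0.972
```

With the default (strong, disjoint) class templates the classifier
separates the five synthetic classes far above the 0.2 subset-accuracy /
0.5 AUC chance levels; the residual confusion sits against neutral — the
template with no added modulation — exactly where the simulated effect
is smallest. Importance maps recover each class's modulated facial
region:

```r
model <- trainOvo(fm$x, fm$meta$classLabel, seed = 5)
sm    <- spatialMaps(lfcImportance(model, method = "native"))
roiStats(sm$summary)           # per-region means; cheeks light up for A
```

A single trial can be inspected stage by stage:

```r
p    <- subjectProfile("S1", heartRateHz = 1.25, phaseMapSeed = 42)
rec  <- renderRecording(p, defaultClassTemplates()$A, defaultOptics(),
                        seed = 7)
cube <- preprocessRecording(rec)     # (5, 120, 50, 35)
estimateHrCube(cube)$hr
#> [1] 1.25                           # one 0.25 Hz FFT bin resolution
```

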