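---
title: "ERGdx: methods and design notes"
author: "ERGdx authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ERGdx: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ERGdx)
```

This vignette documents the models, conventions and design choices behind
ERGdx: a pipeline from averaged photopic full-field ERG waveforms to
PhNR-based statistics and time-series classification of optic neuropathy,
validated end-to-end on a synthetic cohort generator with known ground
truth.

## The data model and time convention

A recording is an averaged, device-filtered photopic ERG trace: by default
430 uniformly spaced samples spanning 220 ms with the flash at 100 ms.
ERGdx fixes the convention that sample $i$ (0-based) occurs at
$t_i = i \cdot \Delta t$ with $\Delta t = \mathrm{duration}/n$. Two
candidate conventions exist ($\Delta t = D/n$ vs $D/(n-1)$); both put 11
consecutive samples near the conventional ~5.6 ms trough-averaging span
(5.63 vs 5.64 ms), and ERGdx fixes $D/n$ as canonical. Times map back to
indices by nearest-sample lookup with ties resolved toward the smaller
index and clamping at the record end, so $t = 220$ ms maps to index 429.
The stimulus time is a per-record field rather than a constant so other
protocols can be represented; analysis code never hard-codes 100 ms.

Cohorts are held in an `ERGRecordingSet`, a `SummarizedExperiment` whose
assay is the timepoint-by-recording potential matrix (µV) and whose
`colData` carries subject/eye/visit identity, the diagnosis label, the eye
class (acute or chronic optic neuropathy; fellow-eye, patient or healthy
control), and optional clinical covariates with `NA` for absent values —
never numeric sentinels. Validity checks enforce label/eye-class agreement.
Waveform tables serialize to a long-form CSV (one row per sample) and a
compact JSON dialect; both write numbers with 17 significant digits so a
write–read–write cycle is byte-identical.

## Feature extraction

All features are computed on the detrended trace, in a fixed order:
detrend, baseline, b-peak, a-trough, fixed-latency PhNR, trough-averaged
PhNR, ratios, QC.

**Detrending.** The ordinary-least-squares line over the entire record is
subtracted, absorbing the steady drifts common in skin-electrode
recordings. Whether drift removal should use the whole record or only the
pre-stimulus segment is genuinely open; full-record fitting is the default
(matching common practice for this kind of trace) and a pre-stimulus-only
option is exposed (`extractionConfig(detrend = "prestimulus")`). Full-record
detrending has a knowable cost: because the waveform's own slow components
tilt the fitted line, extracted amplitudes are shrunk relative to the
underlying component amplitudes (quantified below).

**Landmarks and amplitudes.** The baseline is the mean of samples strictly
before the stimulus. The b-wave peak is the maximum within a configurable
post-stimulus window, default stimulus to stimulus + 150 ms — restricted
because an unrestricted maximum could select pre-stimulus artifact. The
a-wave trough is the minimum between stimulus and b-peak. All argmax/argmin
ties resolve to the earliest sample, for determinism. Amplitudes are
signed: $a = V_{trough} - V_0$, $b = V_{peak} - V_{trough}$,
$\mathrm{PhNR}_{72} = V(t_{stim} + 72\,\mathrm{ms}) - V_0$ (a single sample
read, no interpolation), and $\mathrm{PhNR}_{min}$ is the mean of 11
samples (~5.6 ms) centred on the minimum within an inclusive ±10 ms window
around the 72 ms latency, minus baseline. Negative PhNR values mean the
trace lies below baseline; this sign convention makes published group means
(e.g. −2.8 vs −3.7 µV) and the $-\mathrm{PhNR}/b$ numerator of the P-ratio
mutually consistent. If the 11-sample span would cross a record boundary it
is clipped and the record flagged.

**Ratios.** $P = -\mathrm{PhNR}/b$ and $W = (b - \mathrm{PhNR})/(b - a)$,
evaluated exactly with signed inputs. Which PhNR variant enters the ratios
is configurable; the trough-averaged variant is the default, as the primary
measure throughout the analyses. Ratios are undefined (NA, QC-flagged) when
$b \le 0$ or, for W, when $b = a$.

**Quality control.** Published analyses of this kind excluded outlier
tracings and tracings "without a defined b-wave peak" by manual review;
ERGdx automates this with three rules — b-amplitude must exceed
$\max(k \cdot \mathrm{SD}_{pre}, b_{min})$ with $k = 2$ and
$b_{min} = 0.5$ µV (the absolute floor catches drift-only records whose
pre-stimulus variance is negligible); no detrended sample may exceed 200 µV
in magnitude; the trough-averaging window must not be clipped — plus an
explicit per-record exclusion list to mimic manual review. The default
$k = 2$ rejects flat and drift-only records but deliberately does not
reject pure-noise traces, whose spurious peak-to-trough span is several
noise SDs; raising `qc_prominence_sd` to ~8 catches those, at the price of
rejecting genuinely low-amplitude recordings.

Visual acuity converts to logMAR as $\log_{10}(X/20)$ for Snellen "20/X"
(metric "6/X" analogously), with count fingers, hand motions and no light
perception assigned 2, 3 and 6.

## Group statistics: linear GEE

Eye-level features violate independence — two eyes per subject, repeated
recordings — so group comparisons use linear generalized estimating
equations with subjects as clusters and robust (sandwich) covariance.
The exchangeable working correlation is the default (a natural model for
two eyes); independence is available, and inference remains valid under
working-correlation misspecification because only the sandwich covariance
is used for tests. Wald tests use two-sided normal reference with no
small-sample correction. Missing covariates are removed listwise per
model, which is why per-model n varies. The solver is implemented in the
package (iterated GLS with moment estimates of the scale and exchangeable
correlation); tests pin it to two independent references — ordinary least
squares (independence, singleton clusters) and the cluster-robust HC0
covariance from the sandwich package — and verify by simulation that the
exchangeable correlation is recovered and that the ON-status Wald test
holds its nominal level.

Three model families mirror the clinical analyses: each feature on an
optic-neuropathy indicator (optionally age-adjusted — only age, since no
other adjustment set is specified); control-source contrasts among control
eyes (fellow vs other controls, healthy vs other controls); and
structure–function regressions of each feature on visual-field mean
deviation or OCT thickness, with acute eyes excluded from the OCT fits
because acute disc swelling inflates structural measures.

## Diagnostic evaluation

ROC curves are empirical, over midpoints between consecutive distinct
scores plus the ±∞ endpoints, so the trivial corners are always present
and the construction is deterministic. AUC is the trapezoidal area, which
tests verify equals the tie-corrected rank (Mann–Whitney) statistic. The
operating point maximises the Youden index with ties resolved to the
smallest cutoff. Per-feature evaluation averages recordings to eye level,
keeps one eye per subject (OD unless only OS is available), and chooses
the score orientation on the data so AUC ≥ 0.5, recording the choice.
A severity-restricted variant (e.g. visual-field mean deviation below
−5 dB) is a filter on the same pipeline, not a separate code path.

Confusion metrics are reported in two modes. The standard mode uses the
usual precision = TP/(TP+FP) and F1 = 2pr/(p+r). The "paper-variant" mode
applies, verbatim, the metric definitions printed in the study this
package reproduces: precision := TN/(TN+FP) (numerically the
specificity), recall := TP/(TP+FN) (the sensitivity), and
F1 := p·r/(p+r) without the factor of 2. That literal reading is the only
one that reproduces all four published F1 values from their own
sensitivity/specificity pairs, so it is kept as an explicit reproduction
mode — a perfect classifier scores 0.5 in it, which the tests assert to
expose the missing factor. Two published Youden entries differ by 0.01
from sensitivity + specificity − 1 of their own rows (0.23 vs 0.24, 0.20
vs 0.21), presumably rounding of unrounded underlying values; the two
self-consistent rows serve as checks and the discrepancy is documented,
not corrected. Likewise the published table heading maps precision to
sensitivity while the formula TN/(TN+FP) is the specificity; the
contradiction is preserved as-is in reproduction mode.

## The classification benchmark

The benchmark treats each full waveform (length $T = 430$) as the input
$x$ with labels $y \in \{-1, +1\}$ (ON_POS = +1). The split assigns whole
subjects to train/validation/test by a seeded greedy pass (largest
subjects first, randomised order), with penalties on the count scale for
deviation from the target fractions and from the overall positive-label
proportion; it retries with derived seeds and errors if the proportion
tolerance is infeasible. The default fractions (0.44, 0.27, 0.29) follow
the published 258/161/172-waveform split; the exact published assignment
is not recoverable, so they are defaults, not constraints. Waveforms from
both eyes of a subject are treated as independent training examples (their
counts imply the published benchmark did the same).

**DTW.** Dynamic time warping uses the step set {(1,0), (0,1), (1,1)} and
local cost $|x_i - y_j|$ (squared-cost variant exposed; series are not
z-normalised by default, with normalisation config-exposed). An optional
Sakoe–Chiba band constrains $|i-j|$. The dynamic program is in C; a
*separate* exhaustive path-enumeration routine serves as its oracle, and
the acceptance suite checks every unordered pair of series of length ≤ 5
over a 3-symbol alphabet (66,066 pairs). 1-NN prediction breaks distance
ties by the smallest training index.

**Time-series forest.** Each of 100 trees samples $\lfloor\sqrt{T}\rceil$
random intervals (minimum length 3, start and length uniform), summarises
each by mean, SD and OLS slope, and grows a binary tree minimising binary
cross-entropy; prediction is majority vote with exactly even votes
resolved to the negative class. Interval counts and the length-3 minimum
follow the method's conventional description, since no counts are fixed by
the source. The forest is seeded and invariant to training-row order.

**Standard learners.** Linear/RBF SVMs (e1071), random forest
(randomForest) and gradient boosting with binomial deviance (xgboost,
depth 3, learning rate 0.1 — the conventional boosting defaults) back the
remaining kinds at the contract level, with the reference hyperparameters
as defaults: C = 1.5 and γ = 1/(n_features · var X) for the RBF SVM, 200,
100 and 100 estimators for RF, GB and TSF. The LSTM (3 layers × 16 hidden
units, batch 6, dropout 0.6, Adam at 0.001, 100 epochs) is a compact
implementation in R with full backpropagation through time; it is fully
seeded and deterministic, but slow at the full configuration, so tests and
example pipelines reduce `n_epochs`.

Model selection uses validation-set F1 in the paper-variant mode (the
selection criterion is not otherwise specified); the test set is evaluated
once, and the harness exposes a label-access hook with which the tests
audit that test labels are read only at the final evaluation step.

## The synthetic cohort generator

The generator exists so that every module can be validated without
clinical data; it emulates the structure of the study cohort rather than
retinal biophysics. A clean waveform is the sum of three post-stimulus
Gaussian pulses — a-wave (default −2 µV at +15 ms, width 4 ms), b-wave
(+10 µV at +32 ms, width 9 ms) and a slow PhNR (at +72 ms, width 25 ms) —
gated to zero before the flash, plus a constant offset, a linear drift and
white noise. Real ERG components are asymmetric, but the extractor uses
only extrema, means and latencies, so symmetric pulses suffice; a skewed
variant is exposed. The a- and b-wave defaults are chosen as plausible
skin-electrode photopic magnitudes with cleanly separated landmarks.

Cohort structure follows the clinical sample: subjects are ON with
probability 0.57; 24/63 of ON subjects are unilateral, contributing a
fellow-eye control; control subjects split 64:20 healthy:patient; ON eyes
split acute/chronic 33:76. The planted PhNR component is drawn per eye
with the published group moments (ON −2.8 ± 1.5 µV, control −3.7 ± 1.8 µV)
on a standardized latent scale shared within subject at correlation 0.5 —
a bivariate-normal construction on the latent amplitude, not on the noise,
so the GEE's exchangeable working-correlation assumption is met exactly by
design. Recordings of one eye share component amplitudes and differ in
drift, offset and noise (defaults 0.01 µV/ms, 0.5 µV, 0.5 µV — modest
values consistent with device-averaged traces), mirroring repeated
100-flash recordings within a session. Group-wise clinical covariates
(age, visual-field mean deviation, OCT thicknesses) are drawn from the
published group summaries so downstream models have realistic inputs; no
structure–function link is built in — recovery tests plant their own.

**Ground-truth semantics.** The truth table records both the raw component
parameters and *planted effective features*: the features of the
continuous noiseless drift-free waveform, computed on a 0.02 ms grid
through the same mathematical definitions (detrend included). Extraction
from the 430-sample grid then differs from the planted values only by
discretization, noise and drift — which is exactly what
`truthRecoveryReport()` quantifies. The distinction matters because
full-record detrending and pulse overlap shift extracted amplitudes
relative to the component amplitudes themselves (at the defaults, the
extracted b-amplitude sits ~5% above the component value and the
trough-averaged PhNR is attenuated by the detrend line); the published
group moments are treated as the planted trough-component distribution,
an approximation the calibration checks target directly. Noise produces a
further, real effect the recovery report makes visible: argmax/argmin
landmarks on noisy traces have an extreme-value bias of order one noise SD,
so the extracted b-amplitude is biased upward at higher noise even though
the zero-noise bias is below 0.01 µV.

What passing tests on this generator do **not** show: robustness to
asymmetric or multi-peaked morphologies, electrode artifacts, device
filtering effects, latency shifts correlated with disease, or real
between-visit drift; conclusions about such data require clinical
recordings.

## Numerical choices and problem sizes

Tie-breaks are uniformly "earliest/smallest wins" (landmarks, Youden
cutoff, nearest-neighbour index, validation selection). Window bounds are
inclusive, with a 10⁻⁹ ms slack against floating-point boundary error.
GEE iteration stops at a 10⁻¹⁰ relative coefficient change (25 iterations
maximum) and the exchangeable correlation is clamped to its feasible
range. Text serialization uses 17 significant digits for exact double
round-trips. The single pipeline seed fans out to fixed per-stage offsets
so stages are independently reproducible.

The validation studies in the test suite use sizes chosen to make their
statistical bounds sharp while keeping a full run in minutes: 1,000
replicates of a 109-subject null cohort for the type-I error of the
ON-status Wald test (observed 0.050 at the suite's seeds), 200 replicates
of the calibrated two-eye cohort for power (observed 0.955), 500 subjects
for moment calibration, 60 ordered pairs of two-eye clusters for
coefficient coverage, and cohorts of 40–150 subjects for the classifier
sanity and permutation-null checks. Statistical calibration studies run on
planted feature values rather than full waveform extraction, which tests
the estimator itself and keeps a thousand replicates tractable; the
extraction step's fidelity is established separately by the recovery
checks.

## Known limitations

- The GEE solver supports identity-link linear models with independence or
  exchangeable working correlation only — sufficient for these analyses,
  not a general GEE replacement.
- The LSTM is a faithful but compact implementation; at the full reference
  configuration it is slow in R, and no GPU path exists.
- Paper-variant metrics are for reproduction; new analyses should read the
  standard-mode columns, which are always computed alongside.
- The generator's Gaussian components cannot probe morphology-driven
  failure modes of the landmark detectors.
- ROC confidence intervals and curve-comparison tests are out of scope.
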