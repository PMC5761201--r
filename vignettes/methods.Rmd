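---
title: "Methods: simulating, featurizing and classifying progressive central hypovolemia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, featurizing and classifying progressive central hypovolemia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cvreserve` implements a complete desk-scale pipeline for studying
machine-learning detection of progressive central hypovolemia from
non-invasive hemodynamic waveforms. This vignette is the package's own
account of the underlying model and of every place where a methodological
choice had to be made.

## 1. The experimental paradigm being emulated

Lower body negative pressure (LBNP) sequesters blood in the legs and
pelvis, reducing venous return and central blood volume much like
hemorrhage does, while leaving the subject instrumented and safe. A typical
protocol is: supine rest (the final segment of which is the *baseline*), a
single-step application of negative pressure, and termination at
*pre-syncope* — operationally, systolic pressure below 80 mmHg, a rapid
systolic/diastolic pressure fall, or a sudden heart-rate drop.

The classification target is deliberately artificial: class 0 is baseline,
class 1 the first 75% of the LBNP period, class 2 the last 25%
("end-stage"). The classes do not delimit physiological states; they
discretize a continuum so that per-beat classifiers and their probability
estimates can be used as a progression index.

## 2. The synthetic cohort generator

Because no public dataset accompanies this type of protocol, the package
ships a generator (`simulate_subject()`, `simulate_cohort()`) whose
defaults *are* the study conditions for all tests.

**Pulse template.** Each heartbeat of the arterial pressure (and cerebral
flow velocity) wave is rendered from a four-segment parametric template:
a cosine-ease upstroke from the foot (diastolic value) to the systolic
peak, a cosine descent to the dicrotic notch (a genuine local minimum), a
sinusoidal dicrotic wave, and a normalized exponential decay to the next
beat's foot. The template parameters — foot value, peak value, interbeat
interval, peak time (0.34 × LVET) and notch time (LVET = 0.35 √IBI, a
Bazett-style systolic interval) — are stored per beat as ground truth.
This is the central design trick: the landmark detector can be tested
against analytically known landmark positions, to one sample.

**Trajectories.** During baseline all per-beat parameters are constant in
expectation. During LBNP they drift monotonically in expectation: heart
rate up, stroke volume / pulse pressure / cerebral flow velocity down,
thoracic impedance up, end-tidal CO₂ down, oxygenated hemoglobin down and
deoxygenated up. Defaults (fractional change from baseline to the end of
the compensated phase) are: SV −40%, PP −35%, mean flow velocity −25%,
ETCO₂ −15%, TI +5%, O₂Hb −6 µmol/L, HHb +3 µmol/L. These magnitudes are
in the range reported for presyncopal-limited LBNP in healthy adults; they
are set once in `cohort_config()` and never tuned against test outcomes.
`cohort_config_strong()` is a separate, documented preset (SV −50%,
PP −45%, low noise) representing the well-separated regime used for
parameter-recovery checks.

**Phenotypes.** Half of the subjects (configurable mixture weight) are
*resistance-dominant* compensators — diastolic pressure rises (+8%),
tachycardia is modest (+20%) — and half *heart-rate-dominant* — flat
diastolic pressure, strong tachycardia (+55%). Inter-individual variance
in LBNP tolerance is emulated by drawing each subject's LBNP duration
uniformly from a configurable range.

**Terminal collapse.** The final 5% of the LBNP period carries a vasovagal
collapse: systolic pressure is compressed toward 74 mmHg (crossing the
80 mmHg abort criterion) and heart rate falls by 22%. Pre-syncope is always
the end of the recording; optional non-fainting subjects (protocols ended
at a time limit without symptoms) are *not* emulated — every downstream
stage assumes a pre-syncope mark exists.

**Noise.** Per-beat multiplicative jitter (2% SD) on intervals and
amplitudes, additive white measurement noise on the fast channels
(0.4 mmHg / 0.4 cm/s), AR(1) noise on slow channels, and a shared
Mayer-band oscillation (sinusoids at 0.08/0.10/0.12 Hz, 1.5 mmHg) that is
transferred into the flow-velocity wave with a configurable gain
(0.9 (cm/s)/mmHg). The Mayer component is what gives the transfer-function
analysis coherent low-frequency power to work with.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: baroreflex dynamics and genuine
autoregulation (the pressure–flow relation is a fixed linear transfer, not
a regulated one), respiration beyond noise, arrhythmia and ectopy,
measurement artifacts (probe movement, cuff recalibration steps), LBNP box
pressure dynamics, and NIRS path-length physics (concentrations are
generated directly in µmol/L). Classifier performance on these cohorts is
an upper bound: the synthetic classes are more learnable than human data,
where published sensitivities for the end-stage class are far lower.

## 3. Waveform landmarks

`detect_beats()` thresholds the first derivative of a lightly smoothed
copy of the signal (40 ms moving average; threshold 0.25 × the 98th
percentile of positive slopes) to find upstrokes, then localizes each foot
as the latest minimal raw sample in the 0.3 s preceding the steepest
point. Smoothing is used only for detection; landmark values are read from
raw samples so the noise-free recovery oracle stays exact. Successive
onsets are constrained to interbeat intervals of 0.25–2.5 s. A constant
signal yields no beats; sampling below 50 Hz is refused.

`parametrize_pulse()` marks A (foot, first sample), B (steepest upstroke
between A and C), C (systolic peak), D (dicrotic notch), E (next foot).
D is the most prominent local minimum in (C, E); when hypotension renders
the notch shallow and no local minimum exists, the point of maximal second
derivative on the decay is used instead. Degenerate pulses (no peak above
the foot, or failed notch search) raise an error; `beat_landmark_table()`
catches these and linearly interpolates the beat from its neighbours —
the automated analogue of manual removal and interpolation of invalid
beats — and the final, open-ended beat is dropped.

The 15-entry curve-dynamics vector is, in fixed order: `t_AB, t_AC, t_AD,
t_AE, h_B, h_C, h_D, slope_I, slope_II, slope_III, area_sys, area_dia,
area_total, h_D/h_C, area_sys/area_total`. The exact composition of such
curve-parameter sets varies between laboratories and full definitions are
often relegated to supplementary material; this package's set is a
*reconstruction* constrained by the five landmark points, the three
tangent lines (derivative at B; least-squares slopes C→D and D→E), the
shaded areas (trapezoidal, above the foot value, split at the notch), and
the fixed count of 15. Whether ratio features belong in the canonical set
is not decidable from available descriptions; the two ratios were included
to reach 15 while covering all information classes. The count and order
are contracts enforced by tests.

## 4. Per-beat hemodynamics

- SAP = value at C, DAP = value at A, MAP = time-average over the beat,
  PP = SAP − DAP, IBI = time to next foot, HR = 60/IBI.
- LVET is operationalized as the foot-to-notch time, the standard
  systolic-interval surrogate available from pressure landmarks.
- Stroke volume uses the Liljestrand–Zander pulse-contour form
  SV = k·PP/(SAP + DAP). Proprietary pulse-contour algorithms are
  unpublished, so this documented stand-in is used; `k` is calibrated per
  subject so the baseline mean SV equals a configurable value (85 mL).
  What matters downstream is the qualitative SV–PP coupling, not absolute
  accuracy. CO = SV·HR/1000 (L/min); TPR = MAP/CO (mmHg·min/L).
- Flow-velocity quantities (SFV, DFV, MFV, pulse height, beat area and the
  15 FV curve features) are computed on the flow-velocity wave's own beats
  and linearly interpolated onto the pressure beat grid, so each row of
  the beat table describes one pressure beat.
- Slow channels are linearly interpolated at beat times;
  `interpolate_slow_channel(envelope = TRUE)` first reduces a raw
  capnogram to its breath-wise end-tidal peaks (local maxima in the upper
  half of the signal range). The generator emits the end-tidal envelope
  directly, so the pipeline default is plain interpolation.

**Trends and variances.** For each of SAP, DAP, HR, PP, SV (and the five
flow-velocity analogues) and each window length 30/60/90/120 s, the
ordinary-least-squares slope (units/s) and the sample variance are
computed over the beats in `(t − w, t]`, at *every* beat including
baseline. Restricting the windows to the LBNP period would encode the
class boundary into the features themselves (label leakage), so
right-aligned windows run over the whole recording. "Variation" is taken
as the variance (squared units) rather than SD or CV — consistent with
reporting errors on a squared scale — and windows with fewer than 3 beats
or covering less than half their nominal span fall back to the longest
valid shorter window, else 0, with a missingness flag kept out of the
feature count.

**Transfer-function autoregulation.** Both beat series are resampled to a
uniform 4 Hz grid, linearly detrended per 3-min moving window, and
cross/auto spectra are Welch-averaged (100-s cosine-tapered segments, 50%
overlap). Gain |S_xy|/S_xx and phase arg(S_xy) are averaged over the
0.06–0.15 Hz bins with magnitude-squared coherence ≥ 0.5; windows with no
qualifying bin are flagged missing and carried forward (carried back
before the first complete window). The resampling rate, segment length
and taper are not dictated by the paradigm and follow standard cerebral
autoregulation practice; they are recorded in the run manifest as assumed
values. Phase is averaged as returned by `Arg()` (wrapped); in the
0.06–0.15 Hz band with physiological delays the phase stays far from ±π,
so wrapping is immaterial here. The sign convention makes a pure delay of
flow velocity by τ give phase +2πfτ.

## 5. The nine feature sets

| model | content | features |
|---|---|---|
| 1 | 10 basic hemodynamics + 15 BP curve + 40 trend/variance | 65 |
| 2 | #1 + end-tidal CO₂ | 66 |
| 3 | #1 + thoracic impedance | 66 |
| 4 | #1 + 5 oxygenation (O₂Hb, HHb, tHb, 2 ratios) | 70 |
| 5 | #1 + 60 flow-velocity block | 125 |
| 6 | #1 + mean flow velocity | 66 |
| 7 | #1 + flow-velocity pulse height | 66 |
| 8 | 10 basic hemodynamics | 10 |
| 9 | SAP, DAP, MAP, HR | 4 |

The 60-feature flow-velocity block of model 5 is decomposed as 15 FV curve
features + 3 FV scalars (SFV, DFV, MFV) + 40 FV trend/variance + gain +
phase. The published counts fix 60 but not its split; pulse height enters
through the trend/variance series rather than as a fourth scalar, and the
fifth trend/variance series is the FV beat area (a beat-flow surrogate).
The binding constraint — 60 added features, 125 in total — is unit-tested.

Labeling assigns the boundary instant at exactly 75% of LBNP to class 2
(half-open intervals): deterministic, and consistent with "the last 25%".
Classes are left imbalanced (roughly 1/3 baseline on typical protocols);
no rebalancing or class weighting is applied.

Normalization divides each feature by its within-subject baseline mean
(relative change from rest); features whose baseline mean is below 1e−9 in
magnitude — trends, which hover at zero at rest — are mean-subtracted
instead, since division would amplify noise without bound. Min–max scaling
to [0, 1] is then fit on the *pooled training cohort* (not per subject:
per-subject scaling would erase exactly the inter-subject contrast the
classifier must generalize over) and applied to the held-out subject with
clipping; zero-range features map to 0.5. Downsampling keeps every 10th
row per subject (stride decimation, offset 0) — the stated purpose of the
factor-10 reduction is computation time, which implies decimation, not
smoothing.

## 6. Classification protocol

The classifier is a soft-margin SVM with Gaussian kernel
k(u,v) = exp(−γ‖u−v‖²), one-vs-one multiclass, and pairwise-coupled
sigmoid probability estimates — the libsvm scheme, used here through
`e1071`. The probability-calibration cross-validation draws from R's RNG,
so a seed makes training bit-reproducible; the scheme is recorded in the
run manifest. Predicted class is the argmax of the probability triplet
(ties toward the lower class), not the raw one-vs-one vote.

The evaluation protocol is leave-one-subject-out with random training
subsets: for each test subject, `n_train` subjects are drawn uniformly
without replacement from the rest (fresh draw per subject), the scaler and
SVM are fit on their pooled rows, and every row of the held-out subject is
predicted. With cohorts of more than 30 other subjects `n_train` is 30;
smaller synthetic cohorts use ⌊0.7(N−1)⌋, recorded in the run. The
hyperparameter grids are 8 log-spaced values each, C ∈ [10⁻², 10²] and
γ ∈ [10⁻³, 10⁰]: this reconstruction is justified by the fact that all
published optimal (C, γ) values for this analysis lie on these grids to
printed precision. The search shares the random subject subsets across all
64 configurations (variance reduction; whether the original analysis did
so is unknown) and scores each configuration by the mean over tested
subjects of Σ_classes (sensitivity + specificity), with ties broken toward
smaller C, then smaller γ.

## 7. Evaluation methods

1. **One-vs-all sensitivity/specificity** per class from the 3×3 confusion
   matrix, summarized across subjects as median [25%; 75%] (type-7
   linear-interpolation quantiles). Metrics with empty denominators (a
   class absent from a short test subject) are flagged undefined and
   excluded from the medians.
2. **Model error**: per class, the mean squared error between the true
   class value and the centered, edge-truncated moving average of the
   predictions; the total is the sum over the three classes (published
   totals are consistent with sums, not means). The window is not dictated
   by the paradigm; the default is 31 samples (~30 beats after
   downsampling) and every report names the window used.
3. **Log-odds-ratio cutoffs**: LOR = ln(max(p₂, ε)/max(p₀, ε)) with
   ε = 10⁻⁶; two cutoffs (low < high) map LOR to classes 0/1/2, chosen to
   maximize the summed one-vs-all sensitivity + specificity on a grid of
   step 0.01 spanning the observed LOR range. The step size is a package
   choice ("stepwise incremental thresholds" leaves it open) — finer than
   any plausible decision boundary at LOR scale. The objective decomposes
   exactly into a low-only plus a high-only term, so the optimizer is
   linear in the grid; tests verify it against brute-force pair
   enumeration at step 0.1. Cutoffs are optimized pooled across the cohort
   by default (per-subject optimization is available via
   `per_subject_cutoffs = TRUE`).

## 8. Numerical and testing choices

- Determinism contracts (same config + seed ⇒ identical recordings, runs,
  reports) are tested bit-for-bit; RNG state is saved and restored around
  all seeded internals.
- Test problem sizes are chosen for a laptop-class budget: short
  recordings (1–5 min baseline, 2–8 min LBNP) for unit tests, and a
  12-subject strong-effect cohort for the parameter-recovery suite. These
  sizes are the package's own choices for a fast, deterministic suite; the
  code runs unchanged at 42-subject scale with `run_pipeline()`.
- The acceptance script (`scripts/acceptance.R`) recomputes the labeling
  rule's structural constant — the end-stage share of uniformly sampled
  LBNP time — from a fresh simulation at every invocation.

## 9. Known limitations

- The generator's linear pressure–flow transfer means transfer-function
  gain/phase carry little class information in synthetic cohorts; model 5
  exercises plumbing and contracts, not the physiological value of
  autoregulation features.
- Synthetic class separability is optimistic; the pipeline's numbers on
  these cohorts should be read as recovery checks, not performance claims
  for human data.
- The stroke-volume stand-in preserves coupling, not calibration; TPR
  inherits this.
- Cutoff optimization on pooled LOR values implicitly assumes comparable
  probability calibration across subjects.
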