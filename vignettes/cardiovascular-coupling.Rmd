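---
title: "Methods: cardiovascular coupling analysis and risk stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiovascular coupling analysis and risk stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvcoupling)
```

# Overview

`cvcoupling` analyses the coupling between heart period and blood pressure
from beat-aligned series: the beat-to-beat interval (BBI, ms), the per-beat
end-systolic pressure (SBP, mmHg) and the end-diastolic pressure (DBP,
mmHg). The motivating clinical problem is noninvasive risk stratification in
dilated cardiomyopathy: patients at high risk of sudden cardiac death show a
gradual loss of heart rate variability together with increased blood
pressure variability and altered directed cardio-vascular interactions,
while the classical linear HRV indices alone discriminate poorly. The
package therefore combines nonlinear coupling descriptors — joint symbolic
dynamics, segmented Poincaré analysis, frequency-domain directed coupling —
with standard variability indices and a baroreflex sequence method, and
feeds them into a screened, cross-validated SVM cascade that assigns one of
three labels: control (CON), low-risk patient (IDC_LR), high-risk patient
(IDC_HR).

Because clinical recordings of this kind are not freely redistributable, the
package ships a seeded generator of coupled synthetic cohorts with
group-dependent variability and coupling structure, so every stage is
testable end to end.

# Preprocessing

**Artifact filtering.** Ectopic beats and movement artifacts appear as
isolated outliers in all three channels. `filter_artifacts()` flags a beat
when it deviates from the trailing-window median by more than
`lambda_sd` (default 3) times the trailing MAD plus a basic-variability
floor of `base_frac` (default 0.05) of the running level, then replaces
flagged beats by linear interpolation between the nearest clean neighbours.
Robust location/scale were chosen deliberately: a mean/sd recursion with
feedback (replacing flagged beats by the running mean) can enter a runaway
regime on high-variability recordings — once the working mean goes stale and
the running sd collapses, every subsequent beat is flagged. The median/MAD
form is pointwise in the raw data, immune to that cascade, and makes the
flag count provably monotone in `lambda_sd`. On clean synthetic records the
false-positive rate is below 1%; injected ectopy at 2% of beats is recovered
within about one percentage point. Recordings with more than 5% flagged
beats are excluded from cohort tables (`cohort_features()`), the
conventional rejection threshold for this kind of study.

**Resampling and normalization.** Beat times are reconstructed from the
cumulative BBI (the n-th beat at the sum of the first n intervals). For
spectral and directed-coupling analysis each channel is linearly
interpolated onto a uniform 2 Hz grid (`resample_2hz()`), giving
`floor(duration × 2) + 1` samples. Coupling analysis additionally
z-normalizes each channel to exactly zero mean and unit variance
(`znormalize()`, population-sd convention with divisor N so the unit
variance contract is exact); descriptive indices such as sdNN keep the
sample convention (N − 1), which is the HRV standard.

# Joint symbolic dynamics

Increments between successive beats are coded into symbols. The binary
variant codes 1 for a strictly positive increment and 0 otherwise. The
high-resolution (ternary) variant introduces an equilibrium band of width
±l: symbol 0 for a decrement below −l, 1 inside the band, 2 for an increment
above +l, with default thresholds l = 5 ms (BBI) and 1 mmHg (pressures) —
values established for this family of methods. Words of length 3 are taken
with stride 1 from both channels simultaneously, giving an 8 × 8 joint word
matrix for the binary alphabet and a 27 × 27 matrix (729 cells) for the
ternary one.

Because most of the 729 ternary word combinations are too rare to estimate
stably on a 30-minute recording, the 27 word types are grouped into eight
pattern families describing qualitative 3-beat behaviour: the constant words
E0 ("000"), E1 ("111"), E2 ("222"); low increasing LU1 and low decreasing
LD1 (8 words each); fast alternation LA1 ("020", "202"); peak-like P
("120", "201", "210") and valley-like V ("021", "102", "012"). The family
matrix (8 × 8 = 64 cells), its 8 + 8 marginals and the Shannon entropy of
the 64-cell distribution give 81 indices per channel pair; the three pairs
are cardio-systolic (cs), cardio-diastolic (cd) and diastolic-systolic (ds).
A note on symbol semantics: the coding follows the threshold rule above
(0 = decrement, 2 = increment); descriptions of E0 as "decreasing patterns"
follow from that convention.

# Segmented Poincaré plot analysis

The Poincaré plot of a series against its one-beat successor summarises
short- and long-term variability through the dispersion across (SD1) and
along (SD2) the identity line: SD1 = sd((y−x)/√2), SD2 = sd((y+x)/√2).
`sppa_analyze()` rotates the cloud by 45° about its centroid so the major
axis is horizontal, then partitions it with a 12 × 12 grid adapted to the
cloud: 12 columns of width SD2/2 (span ±3 SD2) and 12 rows of height SD1/2
(span ±3 SD1). Each cell's occupancy probability (percent of points) plus
the row and column sums quantify where the dynamics concentrate; points
beyond ±3 SD accumulate in an out-of-grid remainder (≈0.3% per Gaussian
axis tail). Cells are half-open `[low, high)`, so boundary points land in
the higher-index cell; row 1 is the bottom row and column 1 the left one.
The cell size (half an SD per cell, ±3 SD span) follows the originating
segmented-Poincaré literature. Because the grid is SD-adaptive, the probabilities are
invariant to shifting and rescaling both channels.

For cross-signal plots the first channel at beat n is paired with the
second at beat n + 1, mirroring the univariate construction and the
direction of interest (lag 0 available via `lag = 0`). This lag-1 pairing is
an interpretation, not a convention fixed by the method's literature.

# Directed coupling: normalized short-time partial directed coherence

All three z-normalized 2 Hz channels enter one trivariate autoregressive
model, so each pairwise coupling is assessed with the third channel as
covariate. Per sliding window (default 600 samples = 5 min, shift 300,
i.e. 50% overlap — window defaults chosen, not prescribed), `fit_mar()`
estimates least-squares coefficients for candidate orders 1..p_max on a
common effective sample and selects the order minimizing Schwarz's Bayesian
Criterion. The partial directed coherence of the selected model is the
column-normalized spectral coefficient ratio
π_{i←j}(f) = |Ā_ij(f)| / sqrt(Σ_k |Ā_kj(f)|²), which satisfies
Σ_i π_{ij}² = 1 per source column and frequency.

Averaging π over all windows and frequencies in each direction gives the
directional means ā (forward) and b̄ (backward); these are also reported as
the area coupling strengths in [0, 1] (the mean convention guarantees the
bounds; on a uniform frequency grid a trapezoid integral differs only by a
constant). The coupling factor ā/b̄ is quantized into the normalized factor
NF: ±2 for a dominant direction with ratio above 5, ±1 for ratios in (2, 5],
0 otherwise, with negative signs marking the second channel as driver; both
means zero is flagged "no coupling", equal positive means "equal influence".
Frequencies are integrated over 0 to the Nyquist frequency (1 Hz at 2 Hz
sampling).

Two numerical properties of this pipeline are worth knowing. First,
off-diagonal PDC has a noise floor (~0.05–0.15 at these window lengths) from
finite-sample coefficient estimation. Second, interpolating all channels
onto one 2 Hz grid from a shared beat grid injects genuine
cross-predictability into the cardiac channel — the pressure series carries
beat-timing information — so the apparent pressure→cardiac flow never drops
to zero even for a purely cardiac-driven construction. Consequently a
strongly baroreflex-driven system is recovered as NF < 0 essentially always,
while the reversed construction shows the flipped asymmetry in the area
strengths (forward > backward) but a quantized NF of mostly 0/+1. Tests
assert exactly these two behaviours.

# Dual sequence method (baroreflex sensitivity)

`detect_sequences()` scans for runs of at least three beats in which SBP
changes progressively by more than 1 mmHg per beat and, with a one-beat
delay, BBI changes by more than 5 ms per beat in the same direction.
Bradycardic runs (both increasing) express the classical spontaneous
baroreflex; tachycardic runs (both decreasing) complement it. Each
sequence's slope is the least-squares regression of the BBI run on the SBP
run (ms/mmHg); `brs_indices()` reports the mean slope per recording
(`bslope`, `tslope`), with `slope_agg = "max"` available since the
literature's phrasing ("the highest slope of every sequence") is ambiguous —
the mean matches the standard sequence method. No within-sequence
correlation gate is applied by default (`min_r` optional). On synthetic
subjects with a memoryless cardiac channel the recovered bslope matches the
injected gain within 15%.

# Standard HRV/BPV indices

Per channel (BBI, SYS, DIA): meanNN, sdNN (N−1), rmssd, pNN50 (proportion
of successive differences above 50 channel units — applied literally to the
pressure channels too, as in the defining work; configurable), and Welch
band powers over VLF 0.0033–0.04 Hz, LF 0.04–0.15 Hz, HF 0.15–0.4 Hz with
LF/HF, plus normalized LFn/HFn as supplementary outputs. The Welch estimator
uses 256-sample Hann-windowed, mean-detrended segments at 50% overlap — a
reproducibility choice; the exact estimator is not prescribed by the method
definitions. The 21 core indices (7 × 3 channels) match the standard index
set; VLF/LFn/HFn are labelled supplementary.

# Screening and classification

`mwu_screen()` applies the two-sided Mann-Whitney test per index (exact
null when both groups have ≤8 untied values, otherwise the tie-corrected
normal approximation) and assigns tiers at p ≤ α (0.01), p ≤ α/10 and the
Bonferroni cut p ≤ α/m with m the number of indices actually tested — the
cut is computed, not hard-coded. `correlation_prune()` then removes, among
significant indices, the worse member (larger p, name as deterministic
tie-break) of every pair with |Spearman ρ| ≥ 0.7, processing pairs in
descending |ρ|; rank correlation is used for consistency with the
rank-based screen.

Surviving indices are used **in pairs** to train soft-margin SVMs with
Gaussian, Laplace or ANOVA kernels. Both the standard Laplacian
exp(−‖x−y‖/σ) and the Gaussian-shaped variant exp(−‖x−y‖²/2σ) sometimes
printed under the Laplace name are available (`laplace`,
`laplace_printed`). Features are standardized with training-fold statistics
only — the per-fold scaler is refit inside every leave-one-out fold, so no
information leaks from the held-out subject. The dual problem is solved by
an in-package SMO (maximal-violating-pair selection, KKT tolerance 1e−6),
which is deterministic and fast enough for exhaustive LOOCV grids over
pairs × kernels × C; its solutions agree with an interior-point QP solver to
1e−4 in dual objective on small instances. Grid selection maximizes LOOCV
accuracy with ties broken by AUC and then lexical configuration order; AUC
is the rank statistic of pooled held-out decision values, with the
higher-risk group as positive class.

The cascade classifier mirrors the clinical situation where a subject's
status is unknown: stage 1 separates controls from patients; subjects
predicted as patients are passed to stage 2 (low vs high risk). A stage-1
control verdict is terminal, so the three-class accuracy can never exceed
the stage-1 control-vs-rest accuracy; `cascade_loocv()` refits both stages
with each subject held out.

# The synthetic cohort generator

The generator is a linear stochastic difference-equation model — the
minimal structure carrying the directed couplings the estimators target,
with analytically recoverable parameters:

- SBPₙ = μ_s + a_s (SBPₙ₋₁ − μ_s) + g_m (BBIₙ₋₁ − μ_b) + A_r sin(2π f_r tₙ) + ε_s
- BBIₙ = μ_b + a_b (BBIₙ₋₁ − μ_b) + g_b (SBPₙ₋₁ − μ_s) + ε_b
- DBPₙ = μ_d + c (SBPₙ − μ_s) + ε_d

with g_b the baroreflex arm (ms/mmHg), g_m the mechanical arm (mmHg/ms),
respiratory modulation at 0.25 Hz so HF-band power exists, and ectopy
injected by halving randomly chosen intervals. The innovation variances are
not free parameters: they are solved from the discrete Lyapunov equation so
that the *stationary* BBI and SBP standard deviations equal the profile
targets; infeasible combinations (gains too strong for the requested
variances) and unstable recursions (spectral radius ≥ 1) raise errors.

The shipped profiles take channel means and sds at the magnitudes reported
for such cohorts (BBI mean ≈ 884/907/828 ms and sd ≈ 48/37/33 ms for
CON/LR/HR) and couple them so that HRV (sdNN, rmssd) decreases and
short-term systolic variability increases with risk, the baroreflex gain
decreases (5 / 3.5 / 0.8 ms/mmHg) and the cardiac→pressure arm strengthens
(0.004 / 0.012 / 0.05 mmHg/ms) toward high risk. Two calibration notes: the
feasibility constraint above caps the baroreflex gain well below textbook
sensitivity values once the observed sds are fixed — the gains are generator
defaults, not physiological measurements; and the high-risk profile uses a
higher beat-to-beat AR coefficient (0.8) because the low-risk group's
baroreflex arm shifts BBI variance into slow pressure-driven components,
and without the compensation the declared rmssd ordering would invert.
Between-subject heterogeneity is a 5% lognormal jitter on sds and gains
(2.5% on means), shrunk deterministically toward the base profile if a draw
would break feasibility.

What the generator does *not* emulate: nonlinear/saturating baroreflex
dynamics, respiratory sinus arrhythmia as a separate cardiac input,
non-stationary state changes, waveform-level morphology, or realistic
overlap between patient groups. The shipped profiles are intentionally
well-separated, so the pipeline-level classification accuracies measured on
them (LOOCV ≥ 90% for HR vs LR, cascade ≥ 85%) demonstrate that the chain
of estimators preserves the injected group structure — they say nothing
about attainable accuracy on real patients.

# Numerical choices and degenerate inputs

- Population sd (divisor N) wherever a unit-variance contract is exact;
  sample sd (N−1) for descriptive indices.
- Zero-variance channels: `znormalize()` and the Poincaré geometry error
  out rather than emitting NaN; constant indices screen to p = 1.
- `nf_quantize(a, 0)` with a > 0 returns NF = 2 (ratio treated as +∞).
- Word counting excludes nothing: stride-1 overlapping words, total =
  length − k + 1.
- SBC is computed on a common effective sample (the first p_max samples are
  presample only), so criteria are comparable across orders.
- Per-window MAR failures inside `tvpdc()` skip the window and record it;
  an all-window failure is an error.
- Seeds: every stochastic routine takes an explicit seed and restores the
  caller's RNG state; per-subject seeds derive deterministically from the
  cohort master seed.

# Problem sizes used in the shipped checks

The default verification runs use a 20/20/20-subject cohort of 1800 beats
(seed 42) for pipeline-level checks, 100 replicates at n = 4000 for
autoregressive order selection, 10 gain levels × 8 subjects × 900 beats for
the coupling dose-response, and n ≤ 20 instances for exact QP
cross-checks — sizes chosen so the full suite completes in about two
minutes while keeping every statistical margin comfortable.

# Known limitations

- The 2 Hz joint-resampling floor on pressure→cardiac PDC described above.
- The quantized NF discards the magnitude of near-threshold ratios;
  area strengths carry the graded information.
- The SPPA cross-signal lag convention (lag 1) is an interpretation.
- pNN50 on pressure channels with a 50 mmHg threshold is essentially always
  zero on physiological data; it is emitted for completeness.
- The generator's linearity means surrogate-data tests for nonlinearity
  will find nothing to detect in synthetic cohorts.
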