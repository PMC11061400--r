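---
title: "Multimodal upper-limb stroke assessment: models, indices and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal upper-limb stroke assessment: models, indices and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokesyn)
```

## The problem

After a stroke, upper-limb motor function is scored in the clinic with the
Fugl-Meyer upper-limb scale (FMul, 0-66), an observer-rated instrument.
`strokesyn` implements a quantitative counterpart built from three
physiological signal streams recorded while a subject performs isometric
elbow flexion against a strap dynamometer: surface EMG of five arm muscles
(anterior/posterior deltoid, biceps, triceps, brachioradialis), the force
trace itself, and 24-channel fNIRS over premotor (PMC), primary motor (M1)
and somatosensory (S1) cortex of both hemispheres.

The protocol is block-structured: after three maximal voluntary contractions
(MVC), each block holds six trials of 15 s intermittent contraction at 30%
of the mean MVC, paced at 0.5 Hz, followed by 25 s rest; one block per arm.
Each 15 s task window contains a sequence of brief force "lifts" whose
trapezoidal profiles the dynamometer records at 10 Hz, synchronized with the
sEMG at 1925.9 Hz.

## Muscle synergies

A lift's preprocessed sEMG forms a matrix $X_{p\times q}$ ($p = 5$ muscles,
$q = 50$ time-normalized samples) factorized as

$$X = V\,T + E,$$

with non-negative base vectors $V$ (columns unit-norm) and time profiles
$T$.  The factorization is computed by MCR-ALS: alternating exact
non-negative least squares, initialized deterministically from SIMPLISMA
pure variables (purity = column SD over column mean plus a 5% offset,
subsequent picks down-weighted by their projection onto already-picked
columns).  Determinism is the point: randomly initialized NMF can land in
different local optima on repeated runs, which is fatal for a stability
index.  Goodness of fit is

$$\mathrm{VAF} = 1 - \frac{\lVert X - VT\rVert^2}{\lVert X - \mathrm{mean}(X)\rVert^2},$$

where $\mathrm{mean}(X)$ holds each column's mean (the across-muscle mean at
each time sample).  The synergy count is the smallest $n$ for which a strict
majority of subjects in *each* group exceeds VAF 0.80; on both the
generator's output and in the motivating use case this yields $n = 1$.

Three indices summarize the decomposition per subject and arm:

* **SSI** — mean Pearson correlation of $V$ over all ordered pairs of lifts;
  stability of the muscle weighting across repetitions.
* **C_V** — cosine similarity between a lift's $V$ and a baseline $V_B$
  averaged over healthy controls (computed separately for dominant and
  non-dominant hands); how healthy-like the muscle weighting is.
* **C_T** — maximum over circular lags of the normalized circular
  cross-correlation between $T$ and the control baseline $T_B$; timing
  similarity irrespective of phase.

C_V and C_T are deliberately defined as cosine similarity and max-lag
normalized circular cross-correlation: for non-negative inputs these are
the readings bounded in [0, 1], with 1 meaning identity, which is what an
interpretable closeness score requires.

## sEMG preprocessing choices

All offline filters are zero-phase (forward-backward) Butterworth: bandpass
20-450 Hz (4th order), rectification, 5 Hz low-pass envelope (4th order).
Zero-phase filtering is a deliberate choice — phase handling is a free
choice here — because envelope lag against the 10 Hz force clock would bias
lift segmentation.  Segmentation itself runs on the force trace: baseline =
median force over rest periods, onset = crossing of baseline + 5% of target,
window prepended by two dynamometer samples (0.2 s), and a lift is excluded
if its cycle exceeds 3 s or its plateau (mean of samples above 50% of
target) deviates from the target by more than 15%.  The 5% onset threshold
and the 50% plateau definition are the package's operational choices for
making those two exclusion rules computable on a sampled trace.

Amplitude normalization is per-muscle min-max over the *whole block
envelope*, which includes the three MVC contractions at the start of the
recording.  This matters: on an exactly low-rank envelope, per-muscle
min-max over task data alone would map every muscle's task maximum to the
same value and erase the synergy vector.  Anchoring each muscle's maximum in
the MVC segment makes min-max equivalent to MVC normalization, the standard
practice, and keeps $V$ recoverable.  Lifts are time-normalized to $q = 50$
samples by linear interpolation.

## fNIRS pipeline

Per channel and wavelength (830/704 nm): optical density
$-\ln(I/\bar I)$; kurtosis-based wavelet motion-artifact correction
(Daubechies-5, 5 levels: any detail level whose coefficient kurtosis exceeds
3.3 has its largest coefficients zeroed until it complies); zero-phase
3rd-order Butterworth bandpass 0.01-0.08 Hz; modified Beer-Lambert law with
source-detector distance 30 mm, DPF 6.0 and tabulated extinction
coefficients (all exposed as parameters — every validation is a round-trip,
so the specific table never decides a result); and a GLM per channel whose
task regressor is the event boxcar convolved with a canonical double-gamma
HRF (peak 6 s, undershoot 16 s, ratio 1/6) and band-passed identically to
the data, so the passband restriction does not bias $\beta$.  HbR is
produced by the MBLL but consumed by nothing downstream; all analyses use
HbO.  The wavelet family and depth are fixed design choices.

Laterality per region is

$$LI = \frac{\bar\beta_C - \bar\beta_I}{\bar\beta_C + \bar\beta_I},$$

with contralateral/ipsilateral resolved **relative to the moving arm**, after
orientation normalization that mirrors the beta maps of left-lesion patients
(and, by the package's own extension, left-dominant controls) so the right
hemisphere always plays the affected/non-dominant role.  The default
24-channel map (3 regions x 2 hemispheres x 4 channels, mirror pairs 12
apart) is a documented stand-in — exact probe coordinates are
montage-specific — and can be replaced by YAML.  An LI with a vanishing
denominator is reported missing; with mixed-sign betas it may leave [-1, 1]
and is then flagged rather than clipped.

## Group statistics

Comparisons are assumption-gated: Shapiro-Wilk per sample and Levene across
samples, both at $\alpha = 0.05$; only if all pass are t-tests used,
otherwise Mann-Whitney U / Wilcoxon signed-rank.  The two-way group x arm
analysis under non-normality uses the Scheirer-Ray-Hare extension of
Kruskal-Wallis, implemented in-repo: joint mid-ranks, two-way sums of
squares on the ranks, $H = SS_{\text{effect}} / MS_{\text{total}}$ with
$MS_{\text{total}} = SS_{\text{total}}/(N-1)$, referred to $\chi^2$ at the
effect's df.  Mid-ranks already deflate the total rank variance under ties,
so no extra tie correction is applied.

## FMul regression

The feature table holds 21 predictors: six laterality indices (3 regions x 2
moving arms), six synergy indices (SSI, C_V, C_T x 2 arms), their six
unaffected/affected ratios, age, days post stroke, and the MVC force ratio
$F_r$.  The ratio direction is unaffected/affected by default (a config switch
exists because the opposite convention also appears in this literature).  All $\binom{21}{4} = 5985$ four-predictor OLS
models are fitted on patient rows only — the healthy controls are
out-of-sample and are scored by the winning model afterwards — and the model
with maximum adjusted $R^2$ wins, ties resolved by lexicographic enumeration
order.  No multiple-testing correction is applied across the 5985 fits
by design; the winning model's p-values should
be read with that caveat.  Missing data are handled by listwise deletion per
fit.

## The synthetic cohort generator

Because no subject-level data are released, validation rests on a generator
that emulates the acquisition with known ground truth.  Its defaults *are*
the protocol: 15 s task / 25 s rest, six trials per block, 0.5 Hz cue (one
2 s lift slot per cue, 7 lifts per 15 s window — the per-trial lift count is
not printed anywhere, so it is configurable), 30% MVC trapezoids with 3%
plateau jitter, sEMG at 1925.9 Hz, force and fNIRS at 10 Hz, 24 channels at
830/704 nm.

Severity maps are *declared, not estimated*; they exist to make recovery
testable:

* Per-arm synergy vector: $V = \mathrm{normalize}((1-s)V_{\text{healthy}} +
  s V_{\text{abnormal}})$ plus per-subject and per-lift perturbations.
  $V_{\text{healthy}}$ is biceps-dominant; $V_{\text{abnormal}}$ recruits
  anterior deltoid and brachioradialis strongly
  ($\cos(V_h, V_a) \approx 0.55$).  The wide separation is intentional: the
  feature C_V-r = C_V-un/C_V-af enters the planted score, and with a narrow
  separation the ratio is numerically indistinguishable from its linear
  span in C_V-af and C_V-un, making the planted predictor subset
  unidentifiable for *any* selection method.  Patients additionally carry an
  independent unaffected-arm deficit (uniform 0-0.5 mixing), which gives the
  ratio genuinely independent variation.
* Laterality: per region, $LI$ falls linearly with severity during
  affected-arm movement (slopes 0.8/0.7/0.3 for PMC/M1/S1) and rises
  slightly (0.1) during unaffected-arm movement; $\beta_{C}, \beta_{I}$ are
  reconstructed from $LI$ and a total activation of 0.8 µM.
* MVC: unaffected ~ N(200, 30) N; the affected arm loses up to 50% with
  severity, with log-normal noise; $F_r$ is their ratio.
* The planted score is $\mathrm{FMul} = \mathrm{round}(\theta_0 + \theta_1
  C_{V\text{-af}} + \theta_2 LI_{PMC\text{-un}} + \theta_3 F_r + \theta_4
  C_{V\text{-r}} + \varepsilon)$ clipped to [10, 66], with default
  $\theta = (33, 60, 18.7, -11.2, -29.9)$ and $\sigma_\varepsilon = 3$.
  These are not the published coefficients: with the declared severity maps
  the published signs on $F_r$ and C_V-r would make the score *increase*
  with severity.  The defaults were chosen once so the deterministic part
  spans about [12.5, 63.5] (clipping is rare; clipped rows would break the
  linearity that the recovery oracle relies on) and falls with severity.

The sEMG carrier is envelope-modulated Gaussian noise bandpassed 20-450 Hz —
enough to exercise the preprocessing meaningfully, with no claim of
biophysical realism.  fNIRS noise holds cardiac (~1 Hz), respiratory
(~0.3 Hz) and Mayer-wave (~0.1 Hz) sinusoids, linear drift, white noise and
exponential motion spikes injected in OD space; intensity is generated by
the exact inverse of the analysis MBLL.  What the generator does *not*
emulate: volume conduction and crosstalk between muscles, non-stationary
EMG spectra, superficial/systemic fNIRS physiology that correlates with the
task, optode-scalp coupling drift, or behavioural variability in lift
timing.  Passing recovery tests therefore demonstrates correctness of the
analysis chain, not clinical validity on real recordings.

## Numerical choices

* MCR-ALS: convergence when the relative VAF change drops below 1e-8
  (500-iteration cap); NNLS subproblems are solved exactly by support
  enumeration (at most $2^5-1$ supports), so the objective is monotone
  non-increasing by construction.  The synergy-count scan over $n = 1..5$
  uses a 1e-5 / 50-iteration setting — VAF is only compared against 0.80.
* The wavelet transform is an orthonormal periodized filter bank after
  symmetric padding to a multiple of $2^5$; reconstruction is exact to
  machine precision.
* An LI denominator below 1e-12, a constant matrix in VAF, a zero vector in
  any cosine, or fewer than two lifts for SSI each produce a typed error or
  a flagged missing value rather than NaN.
* Ties in the exhaustive search resolve to the first subset in
  `utils::combn` order; ranks use mid-ranks.

## Problem sizes used in the shipped checks

The package's own test battery runs the full chain on a 4-subject mini
cohort with 2 trials per block (the other protocol constants unchanged),
100 planted rank-1 decompositions, 2000 null replicates for the rank test's
calibration, and 20 seeded 30-patient cohorts for planted-subset recovery at
score noise 0.25 and index measurement noise 0.001 — the generator's
"low-noise" validation condition, chosen once.  Full-protocol simulations
(six trials, 15 + 15 subjects) run with the same code paths and defaults.

## Known limitations

* $n = 1$ synergy is assumed by the index layer (SSI with $K > 1$ would
  need column matching across lifts, which is out of scope).
* The Scheirer-Ray-Hare implementation targets crossed two-factor layouts
  with observations in every cell; unbalanced designs use unweighted
  marginal means on ranks.
* The default region map is a stand-in; real montages must supply their own
  channel-to-region YAML.
* Simple regressions of single predictors are supported
  (`fit_linear_model` with one column) but the search is deliberately
  limited to OLS — no cross-validation or regularization.
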