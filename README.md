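# strokesyn

Multimodal assessment of upper-limb motor function after stroke from
force-gated surface EMG, fNIRS and dynamometry, with a fully synthetic
cohort generator for end-to-end validation.

## What it does

During bilateral isometric elbow-flexion blocks (15 s task / 25 s rest, six
trials per block, lifts paced at 0.5 Hz against a 30% MVC force target),
three signal streams are analysed:

* **sEMG muscle synergies.** Each force lift yields a matrix
  `X (5 muscles x 50 samples)` factorized as `X = V T + E` by MCR-ALS —
  alternating exact non-negative least squares from a deterministic
  SIMPLISMA pure-variable initialization — with goodness of fit
  `VAF = 1 - ||X - VT||^2 / ||X - mean(X)||^2`. Per subject and arm the
  package computes the synergy stability index *SSI* (mean pairwise Pearson
  correlation of `V` across lifts), *C_V* (cosine similarity to a healthy
  control baseline `V_B`) and *C_T* (max normalized circular
  cross-correlation to the baseline time profile `T_B`).
* **fNIRS laterality.** 24-channel dual-wavelength (830/704 nm) intensity is
  converted to optical density, motion-corrected by a kurtosis-gated wavelet
  filter (db5, k = 3.3), band-passed 0.01–0.08 Hz, converted to HbO/HbR by
  the modified Beer–Lambert law, and fitted per channel with a GLM whose
  regressor is the task boxcar convolved with the canonical double-gamma
  HRF. Per region (PMC, M1, S1) the laterality index is
  `LI = (bC - bI) / (bC + bI)` over mean betas contralateral/ipsilateral to
  the moving arm, after lesion-orientation normalization.
* **Statistics and regression.** Group x arm comparisons are gated by
  Shapiro–Wilk and Levene tests and fall back to rank tests including an
  in-package Scheirer–Ray–Hare two-way rank test. A 21-predictor feature
  table (six LI, six synergy indices, six unaffected/affected ratios, age,
  days post stroke, MVC ratio `F_r`) feeds an exhaustive best-subset search:
  all C(21, 4) = 5985 four-predictor OLS models of the Fugl-Meyer
  upper-limb score (FMul), selected by adjusted R².

Because no subject-level recordings are publicly deposited, the package
ships a synthetic cohort generator (`simulation_config()`,
`generate_cohort()`, `simulate_emg_session()`, `simulate_fnirs_session()`)
that emulates the acquisition with known ground truth for every downstream
quantity, so the whole chain is testable by parameter recovery. See the
methods vignette (`vignettes/multimodal-stroke-assessment.Rmd`) for the
models, assumptions and design choices.

## Worked example

Generate a 30-patient / 15-control cohort, build the feature table from the
generator's ground-truth indices, and fit the best four-predictor model:

```r
library(strokesyn)

cfg <- simulation_config(n_patients = 30, n_controls = 15, seed = 42)
coh <- generate_cohort(cfg)
tab <- build_feature_table(true_indices_table(coh, measurement_sd = 0.001))
m <- fmul_lm(tab)           # exhaustive search over 5985 subsets
summary(m)
#> Best-subset linear model of FMul
#>              term       B beta_std  p_value
#>       (Intercept)   2.143       NA 8.99e-01
#>         LI_PMC_un  32.063    0.103 3.70e-03
#>            C_V_af  77.974    0.661 7.97e-09
#>             C_V_r -34.112   -0.401 1.86e-05
#>  days_post_stroke  -0.005   -0.079 1.26e-02
#> R^2 = 0.980, adjusted R^2 = 0.977, F = 311.08, p = <2e-16, n = 30

predict(m, tab[tab$group == "control", ])$n_above
#> [1] 9
```

The model is fitted on patients only; applying it to the held-out controls
counts how many healthy subjects score above 60 — here 9 of 15. The winning
subset contains three of the four planted predictors (`C_V_af`,
`LI_PMC_un`, `C_V_r`); at the default score noise (SD 3 points) the search
occasionally swaps a weak planted predictor for a correlated column, which
is the expected behaviour of best-subset selection at this sample size. At
the generator's low-noise validation setting the planted subset is
recovered in 20 of 20 seeds (see below).

To run the full signal-level pipeline instead of using ground-truth
indices:

```r
sessions <- simulate_sessions(coh)    # sEMG + fNIRS for every subject-arm
res <- run_pipeline(list(subjects = coh$subjects, sessions = sessions))
res$indices        # SSI, C_V, C_T, LI per subject and arm
res$synergy_count  # VAF-based synergy count (n = 1 here)
```

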