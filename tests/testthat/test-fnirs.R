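# fNIRS chain: optical density, wavelet artifact correction, bandpass, MBLL
# and per-channel GLM.

test_that("optical density follows -ln(I/mean I) and rejects bad intensity", {
  x <- matrix(runif(200, 0.5, 2), 2, 100)
  od <- intensity_to_od(x)
  expect_equal(od, -log(x / rowMeans(x)))
  expect_equal(intensity_to_od(matrix(1.7, 1, 50)), matrix(0, 1, 50))
  bad <- x; bad[2, 10] <- 0
  expect_error(intensity_to_od(bad), class = "strokesyn_domain_error")
})

test_that("wavelet correction is near-identity on Gaussian series", {
  changes <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rnorm(2400)
    y <- kurtosis_wavelet_correct(x)
    mean((y - x)^2) / mean(x^2)
  }, numeric(1))
  expect_lt(mean(changes), 0.01)
})

test_that("wavelet correction removes a spike without disturbing the baseline", {
  tt <- seq(0, 240, length.out = 2400)
  base <- 0.5 * sin(2 * pi * 0.05 * tt)
  x <- base; x[1200] <- x[1200] + 4
  y <- kurtosis_wavelet_correct(x)
  expect_lte(abs(y[1200] - base[1200]), 0.2 * 4)   # spike reduced >= 80%
  keep <- setdiff(seq_along(x), 1150:1250)
  expect_lt(sqrt(mean((y[keep] - base[keep])^2)) / sqrt(mean(base^2)), 0.05)
  expect_equal(kurtosis_wavelet_correct(rep(0, 640)), rep(0, 640))
  expect_error(kurtosis_wavelet_correct(rnorm(8)), class = "strokesyn_wavelet_error")
})

test_that("hemodynamic bandpass keeps the task frequency and rejects cardiac", {
  bf <- signal::butter(3, c(0.01, 0.08) / 5, type = "pass")
  h <- signal::freqz(bf, Fs = 10)
  gain2 <- function(f) abs(h$h[which.min(abs(h$f - f))])^2   # zero-phase = squared
  expect_gte(-20 * log10(gain2(1.0)), 40)
  expect_lte(-20 * log10(gain2(0.033)), 3)
  # constant input is removed
  y <- bandpass_hemo(rep(3, 1200), fs = 10)
  expect_lt(max(abs(y[100:1100])), 1e-6)
  expect_error(bandpass_hemo(rnorm(100), fs = 0.1), class = "strokesyn_rate_error")
})

test_that("MBLL inverse and forward compose to the identity", {
  set.seed(12)
  hbo <- matrix(rnorm(24 * 100), 24)
  hbr <- matrix(rnorm(24 * 100), 24)
  od <- mbll_forward(hbo, hbr)
  hemo <- mbll_convert(od)
  expect_lt(max(abs(hemo$hbo - hbo)), 1e-9)
  expect_lt(max(abs(hemo$hbr - hbr)), 1e-9)
  # zero OD maps to zero concentrations
  z <- mbll_convert(array(0, c(24, 2, 10)))
  expect_equal(z$hbo, matrix(0, 24, 10))
  # doubling the DPF halves the recovered concentrations
  h2 <- mbll_convert(od, dpf = 12)
  expect_equal(h2$hbo, hbo / 2, tolerance = 1e-9)
  expect_error(mbll_convert(od, extinction = matrix(1, 2, 2)),
               class = "strokesyn_mbll_error")
})

test_that("the GLM recovers an exact planted coefficient and flags bad designs", {
  ev <- data.frame(onset_s = c(20, 60, 100), duration_s = 15,
                   kind = "task")
  ns <- 1400
  reg <- bandpass_hemo(strokesyn:::task_regressor(ev, ns, 10), fs = 10)
  hbo <- rbind(2.5 * reg + 7, -1.2 * reg + 3)
  bm <- fit_glm(hbo, ev, fs = 10)
  expect_equal(bm$beta, c(2.5, -1.2), tolerance = 1e-9)
  expect_error(fit_glm(hbo, data.frame(onset_s = 1, duration_s = 5, kind = "rest"),
                       fs = 10), class = "strokesyn_glm_error")
})

test_that("GLM betas on pure noise are statistically null", {
  ev <- data.frame(onset_s = seq(20, 220, by = 40), duration_s = 15, kind = "task")
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    bm <- fit_glm(matrix(rnorm(1, sd = 0) + rnorm(2400), 1), ev, fs = 10)
    if (abs(bm$beta) < 3 * bm$se) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("noiseless simulated sessions round-trip through the chain", {
  coh <- mini_cohort(seed = 3)
  cfg <- coh$config
  cfg$cardiac_amp <- 0; cfg$resp_amp <- 0; cfg$mayer_amp <- 0
  cfg$drift_amp <- 0; cfg$white_sd <- 0; cfg$spike_rate <- 0
  coh$config <- cfg
  sess <- simulate_fnirs_session(coh, "S01", "affected")
  # OD recovered exactly up to the per-channel reference constant
  od <- intensity_to_od(sess$intensity)
  ns <- dim(od)[3]
  reg <- strokesyn:::task_regressor(sess$events, ns, sess$fs)
  tr <- coh$truth[["S01"]]
  # lesion side decides which anatomical hemisphere holds the contra beta
  side <- strokesyn:::arm_side(coh$subjects$lesion_side[1], NA, "affected")
  contra <- if (side == "left") "right" else "left"
  rm <- default_region_map()
  beta_true <- vapply(1:24, function(ch) {
    role <- if (rm$hemisphere[ch] == contra) "contra" else "ipsi"
    tr$beta$affected[[rm$region[ch]]][[role]]
  }, numeric(1))
  hbo_planted <- outer(beta_true, reg)
  hbr_planted <- -0.3 * hbo_planted
  od_planted <- mbll_forward(hbo_planted, hbr_planted)
  ctr <- function(a) a - array(rep(apply(a, c(1, 2), mean), times = dim(a)[3]), dim(a))
  expect_lt(max(abs(ctr(od) - ctr(od_planted))), 1e-10)
  # GLM beta within 2% per channel without artifacts or noise
  fp <- fnirs_pipeline(sess)
  expect_lt(max(abs(fp$beta_map$beta - beta_true) / abs(beta_true)), 0.02)
})

test_that("planted betas survive the full chain at default noise", {
  coh <- mini_cohort(seed = 5)
  sess <- simulate_fnirs_session(coh, "S02", "unaffected")
  fp <- fnirs_pipeline(sess)
  tr <- coh$truth[["S02"]]
  side <- strokesyn:::arm_side(coh$subjects$lesion_side[2], NA, "unaffected")
  contra <- if (side == "left") "right" else "left"
  rm <- default_region_map()
  beta_true <- vapply(1:24, function(ch) {
    role <- if (rm$hemisphere[ch] == contra) "contra" else "ipsi"
    tr$beta$unaffected[[rm$region[ch]]][[role]]
  }, numeric(1))
  rel_rmse <- sqrt(mean((fp$beta_map$beta - beta_true)^2)) / sqrt(mean(beta_true^2))
  expect_lt(rel_rmse, 0.1)
})

test_that("laterality indices never consume HbR", {
  coh <- mini_cohort(seed = 3)
  sess <- simulate_fnirs_session(coh, "S03", "affected")
  fp <- fnirs_pipeline(sess)
  bm <- fit_glm(fp$hemo$hbo, sess$events, fs = sess$fs)
  expect_identical(bm$beta, fp$beta_map$beta)   # beta depends on HbO alone
  li1 <- laterality_index(fp$beta_map$beta, moving_arm = "affected")
  # perturbing HbR cannot change any LI because no LI input touches it
  fp$hemo$hbr <- fp$hemo$hbr * 10
  li2 <- laterality_index(fp$beta_map$beta, moving_arm = "affected")
  expect_identical(li1$li, li2$li)
})
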