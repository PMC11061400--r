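# The synthetic cohort generator: profiles, ground truth, determinism and
# recovery of planted quantities through the analysis chain.

test_that("cohort shape, inclusion rules and determinism", {
  cfg <- simulation_config(n_patients = 15, n_controls = 15, seed = 7)
  coh <- generate_cohort(cfg)
  s <- coh$subjects
  expect_equal(nrow(s), 30L)
  expect_equal(sum(s$lesion_side != "none"), 15L)
  pat <- s[s$group == "patient", ]
  expect_true(all(pat$fmul_true >= 10 & pat$fmul_true <= 66))
  expect_true(all(pat$severity >= 0.1 & pat$severity <= 0.9))
  expect_true(all(s$severity[s$group == "control"] == 0))
  # identical seed and config give identical ground truth
  coh2 <- generate_cohort(simulation_config(n_patients = 15, n_controls = 15, seed = 7))
  expect_identical(coh, coh2)
  expect_error(simulation_config(n_patients = 0), class = "strokesyn_config_error")
  expect_error(simulation_config(target_fraction = 1.2), class = "strokesyn_config_error")
  expect_error(simulation_config(emg_fs = -1), class = "strokesyn_config_error")
})

test_that("zero score noise makes FMul the clipped planted linear form", {
  cfg <- simulation_config(n_patients = 12, n_controls = 2, seed = 11,
                           fmul_noise_sd = 0)
  coh <- generate_cohort(cfg)
  th <- cfg$theta
  for (id in coh$subjects$subject_id[coh$subjects$group == "patient"]) {
    tr <- coh$truth[[id]]
    raw <- th[1] + th[2] * tr$c_v[["affected"]] + th[3] * tr$li$unaffected[["PMC"]] +
      th[4] * tr$f_r + th[5] * (tr$c_v[["unaffected"]] / tr$c_v[["affected"]])
    expect_equal(tr$fmul_true, min(max(round(raw), 10), 66))
  }
})

test_that("implied true affected-arm laterality decreases with severity", {
  cfg <- simulation_config(seed = 1)
  cfg$li_subject_sd <- 0       # isolate the severity map
  li_of <- function(sev) cfg$li_healthy[["PMC"]] - cfg$li_slope_af[["PMC"]] * sev
  sev <- seq(0, 1, by = 0.05)
  expect_true(all(diff(li_of(sev)) < 0))
  # and the generator's stored truth obeys the same map
  coh <- generate_cohort(cfg)
  for (id in coh$subjects$subject_id) {
    tr <- coh$truth[[id]]
    expect_equal(tr$li$affected[["PMC"]],
                 unname(clamp(li_of(tr$severity), -0.95, 0.95)))
  }
})

test_that("the planted synergy vector survives the full sEMG pipeline", {
  cfg <- simulation_config(n_patients = 1, n_controls = 1, seed = 13,
                           trials_per_block = 2L, trial_noise_sd = 0)
  coh <- generate_cohort(cfg)
  ctl <- coh$subjects$subject_id[coh$subjects$group == "control"]
  es <- simulate_emg_session(coh, ctl, "affected")
  expect_equal(sum(es$events$kind == "task"), 2L)
  pre <- semg_preprocess(es)
  expect_gt(length(pre$lifts), 0)
  v_true <- coh$truth[[ctl]]$V$affected
  coss <- vapply(pre$lifts, function(l) {
    m <- mcr_als(l$X, 1)
    sum(m$V[, 1] * v_true)
  }, numeric(1))
  expect_true(all(coss >= 0.99))
  expect_error(simulate_emg_session(coh, "nope", "affected"),
               class = "strokesyn_domain_error")
})

test_that("six trials yield six task windows and zero jitter hits the target", {
  cfg <- simulation_config(n_patients = 1, n_controls = 1, seed = 3,
                           force_jitter_sd = 0)
  coh <- generate_cohort(cfg)
  es <- simulate_emg_session(coh, "S01", "unaffected")
  expect_equal(sum(es$events$kind == "task"), 6L)
  # every lift plateau sits exactly on the target, 30% of the mean MVC trial
  task <- rep(FALSE, length(es$force))
  tf <- (seq_along(es$force) - 1) / es$force_fs
  for (k in which(es$events$kind == "task"))
    task <- task | (tf >= es$events$onset_s[k] & tf < es$events$onset_s[k] + es$events$duration_s[k])
  plateau <- es$force[task & es$force > 0.99 * es$target_force]
  expect_true(all(abs(plateau - es$target_force) < 1e-9))
  expect_equal(max(es$force[task]), es$target_force, tolerance = 1e-9)
  expect_equal(es$target_force, 0.30 * mean(es$mvc_trials), tolerance = 1e-12)
})

test_that("symmetric planted betas give zero laterality downstream", {
  coh <- mini_cohort(seed = 17)
  cfg <- coh$config
  cfg$cardiac_amp <- 0; cfg$resp_amp <- 0; cfg$mayer_amp <- 0
  cfg$drift_amp <- 0; cfg$white_sd <- 0; cfg$spike_rate <- 0
  coh$config <- cfg
  # force bilateral symmetry for one subject: contra = ipsi in every region
  for (r in c("PMC", "M1", "S1"))
    coh$truth[["S01"]]$beta$affected[[r]][] <- 0.4
  sess <- simulate_fnirs_session(coh, "S01", "affected")
  fp <- fnirs_pipeline(sess)
  li <- laterality_index(fp$beta_map$beta, moving_arm = "affected")
  expect_lt(max(abs(li$li)), 1e-6)
})

test_that("sessions are reproducible and channel-mismatched maps are rejected", {
  coh <- mini_cohort(seed = 23)
  e1 <- simulate_emg_session(coh, "S02", "affected")
  e2 <- simulate_emg_session(coh, "S02", "affected")
  expect_identical(e1, e2)
  f1 <- simulate_fnirs_session(coh, "S02", "affected")
  f2 <- simulate_fnirs_session(coh, "S02", "affected")
  expect_identical(f1, f2)
  bad_map <- default_region_map()[1:20, ]
  expect_error(simulate_fnirs_session(coh, "S02", "affected", region_map = bad_map),
               class = "strokesyn_regionmap_error")
})
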