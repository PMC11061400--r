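# Independent oracles and small fixture builders used across the suite.

# Pearson correlation from first principles (no stats::cor)
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# SSI by explicit double loop over ordered pairs
ssi_oracle <- function(V_list, K = 1) {
  i <- length(V_list)
  tot <- 0
  for (l in seq_len(i)) for (q in seq_len(i)) if (l != q)
    tot <- tot + pearson_oracle(V_list[[l]], V_list[[q]])
  tot / (K^2 * i * (i - 1))
}

# C_T by explicit scan over all circular lags
ct_oracle <- function(ti, tb) {
  q <- length(ti)
  best <- -Inf
  for (tau in 0:(q - 1)) {
    s <- 0
    for (m in 1:q) s <- s + ti[m] * tb[((m - 1 + tau) %% q) + 1]
    best <- max(best, s)
  }
  best / sqrt(sum(ti^2) * sum(tb^2))
}

# Frobenius-norm VAF from first principles
vaf_oracle <- function(X, M) {
  mu <- matrix(colMeans(X), nrow(X), ncol(X), byrow = TRUE)
  1 - sum((X - M)^2) / sum((X - mu)^2)
}

# a unit-norm non-negative 5-vector and a bell profile
unit_nonneg <- function(seed, p = 5) {
  set.seed(seed)
  v <- abs(rnorm(p)) + 0.05
  v / sqrt(sum(v^2))
}
bell50 <- function(q = 50) sin(pi * seq(0, 1, length.out = q))^2

# emg_session whose force trace holds the given trapezoid lifts inside one
# task window; envelope-level tests do not need realistic sEMG, so the
# carrier is plain noise
force_fixture_session <- function(lift_levels, lift_durations, target = 60,
                                  force_fs = 10, emg_fs = 2000) {
  gap <- 1.5
  task_len <- sum(lift_durations) + gap * (length(lift_levels) + 1)
  rest_len <- 10
  total <- task_len + rest_len
  nf <- round(total * force_fs)
  force <- numeric(nf)
  t0 <- gap
  for (i in seq_along(lift_levels)) {
    d <- lift_durations[i]
    # rectangular pulses: every in-lift sample sits exactly on the plateau,
    # so the 15% deviation rule sees the intended level
    idx <- (floor(t0 * force_fs) + 1):floor((t0 + d) * force_fs)
    force[idx] <- lift_levels[i]
    t0 <- t0 + d + gap
  }
  events <- data.frame(onset_s = c(0, task_len),
                       duration_s = c(task_len, rest_len),
                       kind = c("task", "rest"))
  n_emg <- round(total * emg_fs)
  emg <- matrix(rnorm(5 * n_emg, sd = 1), 5L)
  emg_session(emg = emg, emg_fs = emg_fs, force = force, force_fs = force_fs,
              muscle_names = c("DA", "DP", "BI", "TI", "BIO"),
              mvc_trials = rep(target / 0.3, 3), events = events,
              target_force = target)
}

# small cohort + sessions, shared by io/pipeline tests
mini_cohort <- function(seed = 7, trials = 2L, n_pat = 2L, n_ctl = 2L) {
  cfg <- simulation_config(n_patients = n_pat, n_controls = n_ctl, seed = seed,
                           trials_per_block = trials)
  generate_cohort(cfg)
}
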