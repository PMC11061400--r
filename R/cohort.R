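# Synthetic cohort generator.  Emulates the acquisition protocol -- 15 s
# isometric elbow-flexion task / 25 s rest per trial, six trials per block,
# one block per arm, 30% MVC trapezoid force lifts at the 0.5 Hz cue cadence,
# sEMG at 1925.9 Hz with a synchronized 10 Hz dynamometer, and 24-channel
# dual-wavelength fNIRS at 10 Hz -- with known ground truth for every
# downstream quantity (planted synergy vectors, per-region GLM betas, MVC
# values, implied indices and the planted FMul linear form).

#' Simulation configuration
#'
#' Defaults encode the acquisition protocol (task/rest timing, trial count,
#' 30% MVC target, cue rate, sampling rates) and the generative choices of
#' the simulator (noise levels, severity-to-physiology maps, planted FMul
#' coefficients).  The severity maps are declared, not estimated: they exist
#' so that recovery of every planted quantity is testable.
#'
#' @param n_patients,n_controls cohort sizes (positive).
#' @param seed integer RNG seed; every random draw derives from it.
#' @param task_s,rest_s task and rest durations per trial (s).
#' @param trials_per_block trials per block (one block per arm).
#' @param cue_hz auditory cue rate; with the 2/4 beat one lift per two cues.
#' @param lifts_per_trial lifts within each 15 s task window (the protocol
#'   implies about 7 at 0.5 Hz; not printed, hence configurable).
#' @param target_fraction task target as a fraction of mean MVC.
#' @param emg_fs,force_fs,fnirs_fs sampling rates (Hz).
#' @param force_jitter_sd per-lift plateau jitter (fraction of target).
#' @param trial_noise_sd per-lift perturbation of the synergy vector.
#' @param emg_noise_floor additive envelope noise floor (fraction of the MVC
#'   envelope amplitude).
#' @param cardiac_amp,resp_amp,mayer_amp,drift_amp,white_sd fNIRS
#'   physiological noise amplitudes (micromolar) at ~1, ~0.3, ~0.1 Hz,
#'   linear drift over the recording, and white noise.
#' @param spike_rate motion-artifact spike rate (events per second per
#'   channel-wavelength); \code{spike_amp_od} their optical-density amplitude.
#' @param theta planted FMul coefficients (intercept, C_V-af, LI_PMC-un,
#'   F_r, C_V-r); \code{fmul_noise_sd} the additive score noise.
#' @param severity_range patients' severity is drawn uniformly from this
#'   interval (0 = healthy-like).
#' @return validated list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_patients = 15L, n_controls = 15L, seed = 1L,
                              task_s = 15, rest_s = 25, trials_per_block = 6L,
                              cue_hz = 0.5, lifts_per_trial = 7L,
                              target_fraction = 0.30,
                              emg_fs = 1925.9, force_fs = 10, fnirs_fs = 10,
                              force_jitter_sd = 0.03, trial_noise_sd = 0.03,
                              emg_noise_floor = 0.01,
                              cardiac_amp = 0.20, resp_amp = 0.10,
                              mayer_amp = 0.15, drift_amp = 0.30,
                              white_sd = 0.10, spike_rate = 0.02,
                              spike_amp_od = 0.05,
                              theta = c(33, 60, 18.7, -11.2, -29.9),
                              fmul_noise_sd = 3,
                              severity_range = c(0.1, 0.9)) {
  cfg <- as.list(environment())
  if (cfg$n_patients < 1L || cfg$n_controls < 1L)
    stop_strokesyn("cohort counts must be positive", "strokesyn_config_error")
  if (any(c(task_s, rest_s, emg_fs, force_fs, fnirs_fs, cue_hz) <= 0))
    stop_strokesyn("rates and durations must be positive", "strokesyn_config_error")
  if (trials_per_block < 1L || lifts_per_trial < 1L)
    stop_strokesyn("trials_per_block and lifts_per_trial must be >= 1",
                   "strokesyn_config_error")
  if (target_fraction <= 0 || target_fraction >= 1)
    stop_strokesyn("target_fraction must lie in (0, 1)", "strokesyn_config_error")
  if (length(theta) != 5L)
    stop_strokesyn("theta must have 5 entries", "strokesyn_config_error")
  # fixed physiology maps (unit-norm synergy vectors; healthy lift is biceps-
  # dominant, the abnormal pattern recruits anterior deltoid and
  # brachioradialis more strongly)
  v_h <- c(DA = 0.25, DP = 0.10, BI = 0.85, TI = 0.08, BIO = 0.45)
  v_a <- c(DA = 0.75, DP = 0.30, BI = 0.10, TI = 0.25, BIO = 0.50)
  cfg$v_healthy <- v_h / sqrt(sum(v_h^2))
  cfg$v_abnormal <- v_a / sqrt(sum(v_a^2))
  cfg$subject_v_sd <- 0.02          # per-subject-arm deviation of the planted V
  cfg$unaffected_spread <- 0.50     # patients' independent unaffected-arm deficit (uniform max)
  cfg$li_healthy <- c(PMC = 0.45, M1 = 0.50, S1 = 0.40)
  cfg$li_slope_af <- c(PMC = 0.80, M1 = 0.70, S1 = 0.30)  # LI drop per unit severity
  cfg$li_slope_un <- 0.10           # LI gain on unaffected-arm movement
  cfg$li_subject_sd <- 0.05
  cfg$region_activation <- 0.8      # beta_contra + beta_ipsi (micromolar)
  cfg$mvc_mean <- 200; cfg$mvc_sd <- 30          # N, elbow flexion
  cfg$mvc_deficit <- 0.5            # affected-arm MVC loss per unit severity
  cfg$mvc_noise_sd <- 0.05          # log-scale MVC ratio noise
  cfg$unaffected_severity <- 0.15   # fraction of severity expressed on the unaffected arm
  cfg$muscles <- c("DA", "DP", "BI", "TI", "BIO")
  class(cfg) <- "simulation_config"
  cfg
}

# internal: deterministic stream seed below 2^31
derive_seed <- function(seed, subject_idx, arm = "none", stream = "cohort") {
  armcode <- match(arm, c("none", "affected", "unaffected"))
  streamcode <- match(stream, c("cohort", "emg", "fnirs"))
  as.integer((as.numeric(seed) * 100003 + subject_idx * 1009 +
                armcode * 101 + streamcode * 7) %% 2147483647)
}

# internal: anatomical side of a moving arm
arm_side <- function(lesion_side, dominant_hand, arm) {
  other <- function(s) if (s == "left") "right" else "left"
  if (lesion_side == "none") {
    if (arm == "affected") other(dominant_hand) else dominant_hand
  } else {
    if (arm == "affected") other(lesion_side) else lesion_side
  }
}

# internal: should this subject's beta map be hemisphere-mirrored so the
# right hemisphere plays the affected / non-dominant role?
needs_flip <- function(lesion_side, dominant_hand) {
  if (lesion_side == "left") return(TRUE)
  if (lesion_side == "none" && identical(dominant_hand, "left")) return(TRUE)
  FALSE
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws subject profiles (patients with severity ~ Uniform over
#' \code{severity_range}, controls at severity 0) and the per-subject ground
#' truth every simulator and index consumes: planted per-arm synergy vectors,
#' MVC values, per-region contralateral/ipsilateral betas for both moving
#' arms, implied true indices, and the planted FMul score
#' \code{round(theta0 + theta1 C_V-af + theta2 LI_PMC-un + theta3 F_r +
#' theta4 C_V-r + noise)} clipped to [10, 66].
#'
#' @param config \code{simulation_config}.
#' @return object of class \code{"cohort"}: \code{config}, \code{subjects}
#'   (profile data.frame), \code{truth} (named list per subject).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, 0L))
  n <- config$n_patients + config$n_controls
  ids <- sprintf("S%02d", seq_len(n))
  group <- c(rep("patient", config$n_patients), rep("control", config$n_controls))
  lesion <- ifelse(group == "patient",
                   sample(c("left", "right"), n, replace = TRUE), "none")
  dominant <- ifelse(group == "control",
                     sample(c("left", "right"), n, replace = TRUE, prob = c(0.1, 0.9)),
                     NA_character_)
  age <- round(runif(n, 30, 85))
  days <- ifelse(group == "patient", round(runif(n, 7, 730)), NA_real_)
  severity <- ifelse(group == "patient",
                     runif(n, config$severity_range[1], config$severity_range[2]), 0)
  sex <- sample(c("Male", "Female"), n, replace = TRUE, prob = c(0.65, 0.35))

  truth <- vector("list", n); names(truth) <- ids
  fmul <- rep(NA_real_, n)
  regions <- names(config$li_healthy)
  for (i in seq_len(n)) {
    set.seed(derive_seed(config$seed, i))
    sev <- severity[i]
    # patients express part of the deficit on the unaffected arm too, with an
    # independent subject-specific component (bilateral involvement varies)
    u_dev <- if (group[i] == "patient") runif(1, 0, config$unaffected_spread) else 0
    sev_arm <- c(affected = sev,
                 unaffected = config$unaffected_severity * sev + u_dev)
    V <- list(); li <- list(); beta <- list()
    c_v <- c(); ssi <- c(); c_t <- c()
    for (arm in c("affected", "unaffected")) {
      s <- sev_arm[[arm]]
      mix <- (1 - s) * config$v_healthy + s * config$v_abnormal
      mix <- mix + rnorm(5, 0, config$subject_v_sd)
      mix <- pmax(mix, 0)
      V[[arm]] <- mix / sqrt(sum(mix^2))
      c_v[arm] <- sum(V[[arm]] * config$v_healthy)
      ssi[arm] <- clamp(0.97 - 0.30 * s + rnorm(1, 0, 0.02), -1, 1)
      c_t[arm] <- clamp(0.99 - 0.08 * s + rnorm(1, 0, 0.01), 0, 1)
      li_arm <- c(); b_arm <- list()
      for (r in regions) {
        li_true <- if (arm == "affected")
          config$li_healthy[[r]] - config$li_slope_af[[r]] * sev
        else
          config$li_healthy[[r]] + config$li_slope_un * sev
        li_true <- li_true + rnorm(1, 0, config$li_subject_sd)
        li_true <- clamp(li_true, -0.95, 0.95)
        A <- config$region_activation
        b_arm[[r]] <- c(contra = A * (1 + li_true) / 2, ipsi = A * (1 - li_true) / 2)
        li_arm[r] <- li_true
      }
      li[[arm]] <- li_arm; beta[[arm]] <- b_arm
    }
    mvc_un <- rnorm(1, config$mvc_mean, config$mvc_sd)
    mvc_un <- max(mvc_un, 60)
    mvc_af <- mvc_un * (1 - config$mvc_deficit * sev) * exp(rnorm(1, 0, config$mvc_noise_sd))
    f_r <- mvc_un / mvc_af
    trial_sd <- config$trial_noise_sd
    th <- config$theta
    if (group[i] == "patient") {
      raw <- th[1] + th[2] * c_v[["affected"]] + th[3] * li$unaffected[["PMC"]] +
        th[4] * f_r + th[5] * (c_v[["unaffected"]] / c_v[["affected"]]) +
        rnorm(1, 0, config$fmul_noise_sd)
      fmul[i] <- clamp(round(raw), 10, 66)
    }
    truth[[i]] <- list(V = V, li = li, beta = beta, c_v = c_v, ssi = ssi,
                       c_t = c_t, mvc = c(affected = mvc_af, unaffected = mvc_un),
                       f_r = f_r, severity = sev, trial_noise_sd = trial_sd,
                       fmul_true = fmul[i])
  }
  subjects <- data.frame(subject_id = ids, group = group, lesion_side = lesion,
                         dominant_hand = dominant, sex = sex, age = age,
                         days_post_stroke = days, severity = severity,
                         fmul_true = fmul, stringsAsFactors = FALSE)
  structure(list(config = config, subjects = subjects, truth = truth),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d patients + %d controls (seed %d)\n",
              sum(x$subjects$group == "patient"), sum(x$subjects$group == "control"),
              x$config$seed))
  invisible(x)
}

#' Ground-truth index table of a cohort
#'
#' Arranges each subject's implied true indices (C_V, SSI, C_T, regional LI
#' per arm, MVC per arm) into the column layout consumed by
#' \code{\link{build_feature_table}} -- the recovery oracle for the
#' regression stage.
#'
#' @param cohort \code{cohort}.
#' @param measurement_sd optional additive noise applied to every index
#'   column (emulating estimation error) using the cohort seed.
#' @return data.frame, one row per subject.
#' @export
true_indices_table <- function(cohort, measurement_sd = 0) {
  s <- cohort$subjects
  rows <- lapply(seq_len(nrow(s)), function(i) {
    tr <- cohort$truth[[i]]
    data.frame(subject_id = s$subject_id[i], group = s$group[i],
               age = s$age[i], days_post_stroke = s$days_post_stroke[i],
               fmul = tr$fmul_true,
               mvc_af = tr$mvc[["affected"]], mvc_un = tr$mvc[["unaffected"]],
               li_pmc_af = tr$li$affected[["PMC"]], li_pmc_un = tr$li$unaffected[["PMC"]],
               li_m1_af = tr$li$affected[["M1"]], li_m1_un = tr$li$unaffected[["M1"]],
               li_s1_af = tr$li$affected[["S1"]], li_s1_un = tr$li$unaffected[["S1"]],
               ssi_af = tr$ssi[["affected"]], ssi_un = tr$ssi[["unaffected"]],
               c_v_af = tr$c_v[["affected"]], c_v_un = tr$c_v[["unaffected"]],
               c_t_af = tr$c_t[["affected"]], c_t_un = tr$c_t[["unaffected"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (measurement_sd > 0) {
    set.seed(derive_seed(cohort$config$seed, nrow(s) + 1L))
    num <- setdiff(names(out), c("subject_id", "group", "age", "days_post_stroke", "fmul"))
    for (cn in num) out[[cn]] <- out[[cn]] + rnorm(nrow(out), 0, measurement_sd)
  }
  out
}

# internal: trapezoid force profile values at given times within a lift slot
trapezoid <- function(t, rise = 0.4, plateau = 1.0, fall = 0.4, level = 1) {
  up <- t >= 0 & t < rise
  flat <- t >= rise & t < rise + plateau
  down <- t >= rise + plateau & t < rise + plateau + fall
  out <- numeric(length(t))
  out[up] <- level * t[up] / rise
  out[flat] <- level
  out[down] <- level * (1 - (t[down] - rise - plateau) / fall)
  out
}

#' Simulate an sEMG session for one subject and arm
#'
#' Builds the block recording: three MVC contractions, then
#' \code{trials_per_block} task/rest trials with \code{lifts_per_trial}
#' trapezoid force lifts at 30% MVC (+/- jitter).  The sEMG of each muscle is
#' an amplitude-modulated wideband carrier (Gaussian noise bandpassed
#' 20-450 Hz): during lifts the envelope follows \code{s_l * V_l * bell(t)}
#' with \code{V_l} the planted per-arm synergy vector perturbed per lift,
#' and during MVC every muscle reaches its maximal envelope, which anchors
#' the per-muscle min-max normalization downstream.
#'
#' @param cohort \code{cohort} from \code{\link{generate_cohort}}.
#' @param subject_id subject identifier.
#' @param arm "affected" or "unaffected".
#' @return \code{emg_session}.
#' @export
simulate_emg_session <- function(cohort, subject_id, arm = c("affected", "unaffected")) {
  arm <- match.arg(arm)
  cfg <- cohort$config
  i <- match(subject_id, cohort$subjects$subject_id)
  if (is.na(i)) stop_strokesyn("unknown subject", "strokesyn_domain_error")
  tr <- cohort$truth[[i]]
  set.seed(derive_seed(cfg$seed, i, arm, "emg"))

  mvc <- tr$mvc[[arm]]
  mvc_levels <- mvc * (1 + rnorm(3, 0, 0.02))
  # protocol: the target is 30% of the mean of the three measured MVC trials
  target <- cfg$target_fraction * mean(mvc_levels)
  fs <- cfg$force_fs
  # timeline: 2 s lead-in, 3 x (3 s MVC + 3 s rest), then trials
  mvc_lead <- 2; mvc_on <- 3; mvc_off <- 3
  pre_s <- mvc_lead + 3 * (mvc_on + mvc_off)
  total_s <- pre_s + cfg$trials_per_block * (cfg$task_s + cfg$rest_s)
  nf <- round(total_s * fs)
  force <- numeric(nf)
  events <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                       kind = character(0), stringsAsFactors = FALSE)
  # index window of [t0, t0 + dur) on a uniform timeline starting at 0
  win <- function(t0, dur, rate, nmax) {
    ix <- (floor(t0 * rate) + 1L):min(nmax, ceiling((t0 + dur) * rate))
    ix[ix >= 1L]
  }
  for (k in 1:3) {
    on <- mvc_lead + (k - 1) * (mvc_on + mvc_off)
    idx <- win(on, mvc_on, fs, nf)
    force[idx] <- trapezoid((idx - 1) / fs - on, rise = 0.5, plateau = 2.0,
                            fall = 0.5, level = mvc_levels[k])
    events <- rbind(events, data.frame(onset_s = on, duration_s = mvc_on, kind = "mvc"))
  }

  n_emg <- round(total_s * cfg$emg_fs)
  env <- matrix(0, 5L, n_emg)           # per-muscle envelope, unit = muscle gain
  # MVC: all muscles at full envelope
  for (k in 1:3) {
    on <- mvc_lead + (k - 1) * (mvc_on + mvc_off)
    idx <- win(on, mvc_on, cfg$emg_fs, n_emg)
    bell <- trapezoid((idx - 1) / cfg$emg_fs - on, rise = 0.5, plateau = 2.0,
                      fall = 0.5, level = 1)
    env[, idx] <- env[, idx] + rep(bell, each = 5L)
  }

  lift_slot <- 1 / cfg$cue_hz                        # one lift per 0.5 Hz cue = 2 s
  lift_dur <- 0.9 * lift_slot                        # rise + plateau + fall
  lifts <- list()
  for (k in seq_len(cfg$trials_per_block)) {
    on <- pre_s + (k - 1) * (cfg$task_s + cfg$rest_s)
    events <- rbind(events,
                    data.frame(onset_s = on, duration_s = cfg$task_s, kind = "task"),
                    data.frame(onset_s = on + cfg$task_s, duration_s = cfg$rest_s,
                               kind = "rest"))
    for (l in seq_len(cfg$lifts_per_trial)) {
      t0 <- on + (l - 1) * lift_slot
      if (t0 + lift_dur > on + cfg$task_s) break
      level <- target * (1 + rnorm(1, 0, cfg$force_jitter_sd))
      idx <- win(t0, lift_dur, fs, nf)
      force[idx] <- trapezoid((idx - 1) / fs - t0, rise = 0.2 * lift_dur,
                              plateau = 0.6 * lift_dur, fall = 0.2 * lift_dur,
                              level = level)
      # per-lift synergy vector: planted arm vector plus trial noise
      v_l <- tr$V[[arm]] + rnorm(5, 0, tr$trial_noise_sd)
      v_l <- pmax(v_l, 0); v_l <- v_l / sqrt(sum(v_l^2))
      s_l <- level / mvc
      eidx <- win(t0, lift_dur, cfg$emg_fs, n_emg)
      bell <- sin(pi * clamp((eidx - 1) / cfg$emg_fs - t0, 0, lift_dur) / lift_dur)^2
      env[, eidx] <- env[, eidx] + s_l * outer(v_l, bell)
      lifts[[length(lifts) + 1L]] <- list(trial = k, lift = l, v = v_l, level = level)
    }
  }

  gains <- runif(5, 300, 600)           # per-muscle microvolt gain
  bp <- signal::butter(4, c(20, 450) / (cfg$emg_fs / 2), type = "pass")
  emg <- matrix(0, 5L, n_emg)
  for (m in 1:5) {
    # single-pass bandpass is enough for carrier synthesis (phase irrelevant)
    carrier <- as.numeric(signal::filter(bp, rnorm(n_emg)))
    carrier <- carrier / sd(carrier)
    floor_noise <- cfg$emg_noise_floor * rnorm(n_emg)
    emg[m, ] <- gains[m] * (env[m, ] * carrier + floor_noise)
  }
  rownames(emg) <- cfg$muscles
  emg_session(emg = emg, emg_fs = cfg$emg_fs, force = force, force_fs = fs,
              muscle_names = cfg$muscles, mvc_trials = mvc_levels,
              events = events, target_force = target)
}

#' Simulate an fNIRS session for one subject and arm
#'
#' Covers the same block timeline as the sEMG session (including the MVC
#' preamble, during which no task regressor is active).  Per channel the
#' planted HbO is \code{beta_true x (task boxcar convolved with the canonical
#' HRF)} plus cardiac (~1 Hz), respiratory (~0.3 Hz) and Mayer-wave
#' (~0.1 Hz) sinusoids, linear drift and white noise; HbR is a scaled
#' negative copy with its own noise.  Intensity is produced by the exact
#' inverse of the MBLL used in analysis, and motion spikes are injected in
#' optical-density space at the configured rate.
#'
#' @inheritParams simulate_emg_session
#' @param region_map channel map (must cover 24 channels).
#' @return \code{fnirs_session}.
#' @export
simulate_fnirs_session <- function(cohort, subject_id,
                                   arm = c("affected", "unaffected"),
                                   region_map = default_region_map()) {
  arm <- match.arg(arm)
  cfg <- cohort$config
  i <- match(subject_id, cohort$subjects$subject_id)
  if (is.na(i)) stop_strokesyn("unknown subject", "strokesyn_domain_error")
  prof <- cohort$subjects[i, ]
  tr <- cohort$truth[[i]]
  validate_region_map(region_map, 24L)
  set.seed(derive_seed(cfg$seed, i, arm, "fnirs"))

  fs <- cfg$fnirs_fs
  pre_s <- 2 + 3 * 6
  total_s <- pre_s + cfg$trials_per_block * (cfg$task_s + cfg$rest_s)
  ns <- round(total_s * fs)
  tt <- (seq_len(ns) - 1) / fs
  events <- do.call(rbind, lapply(seq_len(cfg$trials_per_block), function(k) {
    on <- pre_s + (k - 1) * (cfg$task_s + cfg$rest_s)
    rbind(data.frame(onset_s = on, duration_s = cfg$task_s, kind = "task"),
          data.frame(onset_s = on + cfg$task_s, duration_s = cfg$rest_s, kind = "rest"))
  }))
  reg <- task_regressor(events, ns, fs)

  side <- arm_side(prof$lesion_side, prof$dominant_hand, arm)
  contra_hemi <- if (side == "left") "right" else "left"
  beta_true <- numeric(24L)
  for (ch in seq_len(24L)) {
    r <- region_map$region[region_map$channel == ch]
    h <- region_map$hemisphere[region_map$channel == ch]
    role <- if (h == contra_hemi) "contra" else "ipsi"
    beta_true[ch] <- tr$beta[[arm]][[r]][[role]]
  }

  hbo <- matrix(0, 24L, ns); hbr <- matrix(0, 24L, ns)
  for (ch in seq_len(24L)) {
    ph <- runif(4, 0, 2 * pi)
    noise <- cfg$cardiac_amp * sin(2 * pi * 1.0 * tt + ph[1]) +
      cfg$resp_amp * sin(2 * pi * 0.30 * tt + ph[2]) +
      cfg$mayer_amp * sin(2 * pi * 0.10 * tt + ph[3]) +
      cfg$drift_amp * (tt / total_s - 0.5) * 2 +
      rnorm(ns, 0, cfg$white_sd)
    hbo[ch, ] <- beta_true[ch] * reg + noise
    hbr[ch, ] <- -0.3 * hbo[ch, ] + rnorm(ns, 0, 0.3 * cfg$white_sd)
  }
  od <- mbll_forward(hbo, hbr)
  # motion spikes in OD space: exponential-decay transients
  if (cfg$spike_rate > 0) {
    for (ch in seq_len(24L)) for (w in 1:2) {
      n_spikes <- rbinom(1L, ns, cfg$spike_rate / fs)
      if (n_spikes > 0) {
        pos <- sample(ns, n_spikes)
        for (p in pos) {
          amp <- sample(c(-1, 1), 1L) * cfg$spike_amp_od * runif(1, 0.5, 1.5)
          span <- p:min(ns, p + round(0.5 * fs))
          od[ch, w, span] <- od[ch, w, span] + amp * exp(-(span - p) / (0.1 * fs))
        }
      }
    }
  }
  i0 <- matrix(runif(24 * 2, 0.5, 2.0), 24L, 2L)
  intensity <- array(NA_real_, dim(od))
  for (ch in seq_len(24L)) for (w in 1:2)
    intensity[ch, w, ] <- i0[ch, w] * exp(-od[ch, w, ])
  fnirs_session(intensity, fs = fs, events = events,
                source_detector_mm = 30)
}
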