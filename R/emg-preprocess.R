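# sEMG preprocessing: bandpass + detrend + rectify + lowpass envelope,
# force-driven lift segmentation with the two exclusion rules (duration and
# force deviation), and min-max amplitude plus time normalization to the
# fixed 5 x 50 lift matrix consumed by the synergy decomposition.

#' Construct an sEMG session object
#'
#' Bundles a multi-muscle sEMG recording with its synchronized force trace,
#' MVC values and event log.
#'
#' @param emg numeric matrix, muscles x samples (microvolts).
#' @param emg_fs sEMG sampling rate in Hz.
#' @param force numeric force trace (N) sampled at \code{force_fs}.
#' @param force_fs force sampling rate in Hz (dynamometer clock).
#' @param muscle_names character vector of muscle labels.
#' @param mvc_trials the three MVC force maxima (N).
#' @param events data.frame with columns \code{onset_s}, \code{duration_s},
#'   \code{kind} (\code{"task"}, \code{"rest"} or \code{"mvc"}).
#' @param target_force task target force (N); defaults to 30% of the mean MVC.
#' @return object of class \code{"emg_session"}.
#' @export
emg_session <- function(emg, emg_fs, force, force_fs, muscle_names,
                        mvc_trials, events,
                        target_force = 0.30 * mean(mvc_trials)) {
  emg <- as.matrix(emg)
  stopifnot(nrow(emg) == length(muscle_names), length(mvc_trials) == 3L)
  if (target_force <= 0)
    stop_strokesyn("target_force must be positive", "strokesyn_domain_error")
  structure(list(emg = emg, emg_fs = emg_fs, force = as.numeric(force),
                 force_fs = force_fs, muscle_names = muscle_names,
                 mvc_trials = as.numeric(mvc_trials), events = events,
                 target_force = target_force),
            class = "emg_session")
}

#' @export
print.emg_session <- function(x, ...) {
  cat(sprintf("sEMG session: %d muscles x %d samples at %.1f Hz, %.1f s\n",
              nrow(x$emg), ncol(x$emg), x$emg_fs, ncol(x$emg) / x$emg_fs))
  cat(sprintf("  force: %d samples at %g Hz; target %.2f N (MVC %.1f N)\n",
              length(x$force), x$force_fs, x$target_force, mean(x$mvc_trials)))
  cat(sprintf("  events: %d (%s)\n", nrow(x$events),
              paste(sprintf("%s x%d", names(table(x$events$kind)),
                            as.integer(table(x$events$kind))), collapse = ", ")))
  invisible(x)
}

#' Extract the sEMG linear envelope
#'
#' Per channel: zero-phase 4th-order Butterworth bandpass 20-450 Hz, linear
#' detrend, full-wave rectification, then a zero-phase 4th-order Butterworth
#' low-pass at 5 Hz.  Residual filter ringing below zero is clipped to zero.
#'
#' @param session \code{emg_session} (or a bare muscles x samples matrix with
#'   \code{emg_fs} supplied).
#' @param emg_fs sampling rate, required when \code{session} is a matrix.
#' @param band bandpass edges in Hz.
#' @param lowpass envelope low-pass cutoff in Hz.
#' @return matrix muscles x samples, non-negative.
#' @export
envelope_extract <- function(session, emg_fs = NULL, band = c(20, 450), lowpass = 5) {
  if (inherits(session, "emg_session")) {
    emg <- session$emg; emg_fs <- session$emg_fs
  } else {
    emg <- as.matrix(session)
    if (is.null(emg_fs)) stop_strokesyn("emg_fs required", "strokesyn_domain_error")
  }
  if (emg_fs <= 2 * band[2])
    stop_strokesyn(sprintf("sampling rate %.1f Hz too low for a %g Hz bandpass edge",
                           emg_fs, band[2]), "strokesyn_rate_error")
  bp <- signal::butter(4, band / (emg_fs / 2), type = "pass")
  lp <- signal::butter(4, lowpass / (emg_fs / 2), type = "low")
  n <- ncol(emg)
  tt <- seq_len(n)
  pad <- round(emg_fs)                            # 1 s of reflection padding
  env <- t(apply(emg, 1L, function(x) {
    x <- zp_filter(bp, x, pad)
    x <- lm.fit(cbind(1, tt), x)$residuals       # linear detrend
    x <- abs(x)                                   # full-wave rectification
    pmax(zp_filter(lp, x, pad), 0)
  }))
  dimnames(env) <- dimnames(emg)
  env
}

#' Segment individual lifts from the force trace
#'
#' Lifts are detected on the dynamometer timeline inside task event windows.
#' The baseline is the median force over rest periods; a lift starts when the
#' force rises above baseline + 5% of the target and ends when it returns
#' below that threshold.  Each window is prepended by two force samples
#' (0.2 s at 10 Hz).  A lift is excluded when its duration exceeds
#' \code{max_duration_s} (3 s) or when its plateau force (mean of samples
#' above 50% of target within the lift) deviates from the target by more than
#' \code{max_deviation} (15%).
#'
#' @param envelope muscles x samples envelope matrix at \code{session$emg_fs}.
#' @param session \code{emg_session} providing force, rates, events and target.
#' @param max_duration_s exclusion threshold on the lifting-cycle duration.
#' @param max_deviation exclusion threshold on relative plateau deviation.
#' @param onset_fraction onset threshold as a fraction of the target force
#'   above baseline.
#' @return list with \code{segments} (list of raw lifts: \code{X} envelope
#'   submatrix, \code{lift_index}, \code{duration_s}, \code{plateau_force},
#'   \code{t_start}, \code{t_end}) and \code{exclusions} (data.frame
#'   \code{lift_index}, \code{rule}, \code{detail}); counts satisfy
#'   detected = retained + excluded.
#' @export
segment_lifts <- function(envelope, session, max_duration_s = 3,
                          max_deviation = 0.15, onset_fraction = 0.05) {
  force <- session$force
  if (length(force) == 0L)
    stop_strokesyn("empty force trace", "strokesyn_segment_error")
  fs <- session$force_fs
  ev <- session$events
  t_force <- (seq_along(force) - 1L) / fs
  rest <- rep(FALSE, length(force))
  for (k in which(ev$kind == "rest"))
    rest <- rest | (t_force >= ev$onset_s[k] & t_force < ev$onset_s[k] + ev$duration_s[k])
  if (!any(rest))
    stop_strokesyn("no rest period available to estimate the force baseline",
                   "strokesyn_segment_error")
  baseline <- median(force[rest])
  thr <- baseline + onset_fraction * session$target_force
  task <- rep(FALSE, length(force))
  for (k in which(ev$kind == "task"))
    task <- task | (t_force >= ev$onset_s[k] & t_force < ev$onset_s[k] + ev$duration_s[k])

  above <- force > thr & task
  d <- diff(c(FALSE, above))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  if (length(ends) < length(starts)) ends <- c(ends, length(force))

  segments <- list()
  exclusions <- data.frame(lift_index = integer(0), rule = character(0),
                           detail = character(0), stringsAsFactors = FALSE)
  emg_fs <- session$emg_fs
  n_emg <- ncol(envelope)
  for (i in seq_along(starts)) {
    s <- max(1L, starts[i] - 2L)              # two dynamometer samples before onset
    e <- ends[i]
    duration <- (ends[i] - starts[i] + 1L) / fs
    seg_force <- force[starts[i]:e]
    plateau_idx <- seg_force > 0.5 * session$target_force
    plateau <- if (any(plateau_idx)) mean(seg_force[plateau_idx]) else NA_real_
    if (duration > max_duration_s) {
      exclusions <- rbind(exclusions, data.frame(
        lift_index = i, rule = "duration",
        detail = sprintf("%.2f s > %g s", duration, max_duration_s)))
      next
    }
    dev <- if (is.na(plateau)) Inf else abs(plateau - session$target_force) / session$target_force
    if (dev > max_deviation) {
      exclusions <- rbind(exclusions, data.frame(
        lift_index = i, rule = "force-deviation",
        detail = sprintf("plateau %.2f N deviates %.0f%% from target",
                         ifelse(is.na(plateau), 0, plateau), 100 * dev)))
      next
    }
    i0 <- max(1L, floor((s - 1L) / fs * emg_fs) + 1L)
    i1 <- min(n_emg, ceiling(e / fs * emg_fs))
    segments[[length(segments) + 1L]] <- list(
      X = envelope[, i0:i1, drop = FALSE], lift_index = i,
      duration_s = duration, plateau_force = plateau,
      t_start = (s - 1L) / fs, t_end = e / fs)
  }
  list(segments = segments, exclusions = exclusions,
       n_detected = length(starts), baseline = baseline)
}

#' Normalize a lift segment in amplitude and time
#'
#' Amplitude: per muscle, \code{(x - min_m) / (max_m - min_m)} with extrema
#' taken over the whole block envelope of the arm (including the MVC
#' contractions, which anchor each muscle's maximum).  Time: linear
#' interpolation to \code{q} samples.
#'
#' @param segment raw segment from \code{segment_lifts}.
#' @param mins,maxs per-muscle extrema of the block envelope.
#' @param q time-normalized sample count (50).
#' @param muscle_names optional labels used in error messages.
#' @return list of class \code{"lift_segment"}: \code{X} (p x q, entries in
#'   [0, 1]), \code{lift_index}, \code{duration_s}, \code{plateau_force}.
#' @export
normalize_segment <- function(segment, mins, maxs, q = 50L, muscle_names = NULL) {
  X <- segment$X
  p <- nrow(X)
  stopifnot(length(mins) == p, length(maxs) == p)
  bad <- which(maxs <= mins)
  if (length(bad)) {
    nm <- if (is.null(muscle_names)) as.character(bad[1L]) else muscle_names[bad[1L]]
    stop_strokesyn(sprintf("degenerate channel '%s': max equals min over the block", nm),
                   "strokesyn_degenerate_channel")
  }
  Xn <- (X - mins) / (maxs - mins)
  Xn <- clamp(Xn, 0, 1)
  Xq <- t(apply(Xn, 1L, resample_linear, n = q))
  dimnames(Xq) <- list(rownames(X), NULL)
  structure(list(X = Xq, lift_index = segment$lift_index,
                 duration_s = segment$duration_s,
                 plateau_force = segment$plateau_force),
            class = "lift_segment")
}

#' Full sEMG preprocessing for one session
#'
#' Envelope extraction, lift segmentation and normalization in one call.
#'
#' @param session \code{emg_session}.
#' @param q time-normalized sample count.
#' @param ... passed to \code{segment_lifts}.
#' @return list with \code{lifts} (normalized \code{lift_segment}s),
#'   \code{exclusions}, \code{n_detected}, \code{envelope}.
#' @export
semg_preprocess <- function(session, q = 50L, ...) {
  env <- envelope_extract(session)
  seg <- segment_lifts(env, session, ...)
  mins <- apply(env, 1L, min)
  maxs <- apply(env, 1L, max)
  lifts <- lapply(seg$segments, normalize_segment, mins = mins, maxs = maxs,
                  q = q, muscle_names = session$muscle_names)
  list(lifts = lifts, exclusions = seg$exclusions,
       n_detected = seg$n_detected, envelope = env)
}
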