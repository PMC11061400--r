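# fNIRS processing chain: raw dual-wavelength intensity -> optical density ->
# motion-artifact correction -> bandpass -> modified Beer-Lambert law ->
# per-channel GLM beta.  All analyses downstream consume HbO only; HbR is
# computed by the MBLL but never used further.

#' Default extinction coefficients at 830 and 704 nm
#'
#' Molar extinction coefficients (1/(mM cm)) for oxy- and deoxyhemoglobin at
#' the instrument's two wavelengths, from standard tabulations.  Rows are
#' wavelengths (830, 704 nm); columns are (HbO, HbR).  The MBLL inverse/
#' forward pair always uses the same table, so analyses based on round-trip
#' consistency do not depend on the specific values.
#'
#' @return 2 x 2 numeric matrix with dimnames.
#' @export
extinction_defaults <- function() {
  matrix(c(0.974, 0.693,
           0.310, 1.660),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("830", "704"), c("HbO", "HbR")))
}

#' Construct an fNIRS session object
#'
#' @param intensity numeric array channels x wavelengths x samples, or a list
#'   of two channels x samples matrices (one per wavelength); strictly
#'   positive.
#' @param fs sampling rate (Hz).
#' @param wavelengths wavelengths in nm, default c(830, 704).
#' @param events data.frame with \code{onset_s}, \code{duration_s},
#'   \code{kind} ("task"/"rest").
#' @param source_detector_mm source-detector separation (mm).
#' @return object of class \code{"fnirs_session"}.
#' @export
fnirs_session <- function(intensity, fs = 10, wavelengths = c(830, 704),
                          events, source_detector_mm = 30) {
  if (is.list(intensity)) {
    stopifnot(length(intensity) == 2L)
    nch <- nrow(intensity[[1L]]); ns <- ncol(intensity[[1L]])
    arr <- array(NA_real_, c(nch, 2L, ns))
    arr[, 1L, ] <- intensity[[1L]]; arr[, 2L, ] <- intensity[[2L]]
    intensity <- arr
  }
  stopifnot(length(dim(intensity)) == 3L, dim(intensity)[2L] == 2L)
  if (any(intensity <= 0))
    stop_strokesyn("intensity must be strictly positive", "strokesyn_domain_error")
  structure(list(intensity = intensity, fs = fs, wavelengths = wavelengths,
                 events = events, source_detector_mm = source_detector_mm),
            class = "fnirs_session")
}

#' @export
print.fnirs_session <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("fNIRS session: %d channels x %d wavelengths (%s nm) x %d samples at %g Hz\n",
              d[1], d[2], paste(x$wavelengths, collapse = "/"), d[3], x$fs))
  invisible(x)
}

#' Convert raw intensity to optical density
#'
#' \code{OD(t) = -ln(I(t) / mean(I))} per channel and wavelength; the
#' reference is the temporal mean of that channel-wavelength series.
#'
#' @param intensity channels x wavelengths x samples array (or a matrix of
#'   series in rows), strictly positive.
#' @return optical density, same shape.
#' @export
intensity_to_od <- function(intensity) {
  if (is.matrix(intensity)) {
    if (any(intensity <= 0))
      stop_strokesyn(sprintf("non-positive intensity in row %d",
                             which(apply(intensity <= 0, 1L, any))[1L]),
                     "strokesyn_domain_error")
    return(-log(intensity / rowMeans(intensity)))
  }
  d <- dim(intensity)
  od <- intensity
  for (ch in seq_len(d[1])) for (w in seq_len(d[2])) {
    x <- intensity[ch, w, ]
    if (any(x <= 0))
      stop_strokesyn(sprintf("non-positive intensity in channel %d, wavelength %d", ch, w),
                     "strokesyn_domain_error")
    od[ch, w, ] <- -log(x / mean(x))
  }
  od
}

#' Bandpass a hemodynamic (or OD) series
#'
#' Zero-phase 3rd-order Butterworth bandpass, default 0.01-0.08 Hz, removing
#' drift and slow physiology below the task frequency and cardiac/respiratory
#' oscillations above it.
#'
#' @param x numeric vector, matrix (series in rows) or channels x wavelengths
#'   x samples array.
#' @param fs sampling rate (Hz).
#' @param band passband edges (Hz).
#' @param order filter order.
#' @return filtered series, same shape and length.
#' @export
bandpass_hemo <- function(x, fs = 10, band = c(0.01, 0.08), order = 3L) {
  if (fs <= 2 * band[2])
    stop_strokesyn(sprintf("sampling rate %g Hz too low for a %g Hz passband edge",
                           fs, band[2]), "strokesyn_rate_error")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  # demean first (the passband excludes DC anyway) and reflect-pad one
  # high-pass time constant so edge transients stay out of the series
  pad <- round(fs / band[1])
  f1 <- function(v) zp_filter(bf, v - mean(v), pad)
  if (is.matrix(x)) {
    out <- t(apply(x, 1L, f1)); dimnames(out) <- dimnames(x); return(out)
  }
  if (length(dim(x)) == 3L) {
    out <- x
    for (ch in seq_len(dim(x)[1])) for (w in seq_len(dim(x)[2]))
      out[ch, w, ] <- f1(x[ch, w, ])
    return(out)
  }
  f1(as.numeric(x))
}

#' Modified Beer-Lambert law: optical density to hemoglobin concentrations
#'
#' Per channel and sample solves the 2 x 2 linear system
#' \code{dOD(lambda) = d * DPF * E(lambda, .) %*% c(dHbO, dHbR) * 1e-3},
#' with \code{d} the source-detector distance in cm, DPF the differential
#' pathlength factor and E the extinction matrix in 1/(mM cm); concentrations
#' are returned in micromolar.
#'
#' @param od channels x wavelengths x samples optical-density array.
#' @param dpf differential pathlength factor (same for both wavelengths by
#'   default).
#' @param extinction 2 x 2 extinction matrix (wavelengths x chromophores).
#' @param distance_mm source-detector separation in mm.
#' @return list of class \code{"hemo_series"}: \code{hbo}, \code{hbr}
#'   (channels x samples matrices, micromolar).
#' @export
mbll_convert <- function(od, dpf = 6.0, extinction = extinction_defaults(),
                         distance_mm = 30) {
  if (abs(det(extinction)) < 1e-12)
    stop_strokesyn("extinction matrix is singular", "strokesyn_mbll_error")
  d_cm <- distance_mm / 10
  A <- d_cm * dpf * extinction * 1e-3     # OD per micromolar
  Ainv <- solve(A)
  nch <- dim(od)[1]; ns <- dim(od)[3]
  hbo <- matrix(NA_real_, nch, ns); hbr <- matrix(NA_real_, nch, ns)
  for (ch in seq_len(nch)) {
    conc <- Ainv %*% rbind(od[ch, 1L, ], od[ch, 2L, ])
    hbo[ch, ] <- conc[1L, ]; hbr[ch, ] <- conc[2L, ]
  }
  structure(list(hbo = hbo, hbr = hbr), class = "hemo_series")
}

#' Forward modified Beer-Lambert law
#'
#' Exact inverse of \code{\link{mbll_convert}}: maps HbO/HbR concentration
#' changes (micromolar) to dual-wavelength optical density.
#'
#' @param hbo,hbr channels x samples matrices (micromolar).
#' @inheritParams mbll_convert
#' @return channels x wavelengths x samples OD array.
#' @export
mbll_forward <- function(hbo, hbr, dpf = 6.0, extinction = extinction_defaults(),
                         distance_mm = 30) {
  d_cm <- distance_mm / 10
  A <- d_cm * dpf * extinction * 1e-3
  nch <- nrow(hbo); ns <- ncol(hbo)
  od <- array(NA_real_, c(nch, 2L, ns))
  for (ch in seq_len(nch)) {
    o <- A %*% rbind(hbo[ch, ], hbr[ch, ])
    od[ch, 1L, ] <- o[1L, ]; od[ch, 2L, ] <- o[2L, ]
  }
  od
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities: response peaking at 6 s minus an
#' undershoot peaking at 16 s scaled by 1/6, sampled at \code{dt}; normalized
#' to unit peak.
#'
#' @param t_max support length in seconds.
#' @param dt sample interval in seconds.
#' @param peak1,peak2 shape parameters (seconds to peak with unit rate).
#' @param ratio undershoot ratio.
#' @return numeric vector of HRF samples.
#' @export
hrf_double_gamma <- function(t_max = 32, dt = 0.1, peak1 = 6, peak2 = 16,
                             ratio = 1 / 6) {
  t <- seq(0, t_max, by = dt)
  # gamma with unit rate and shape a peaks at a - 1, so shape = peak + 1
  h <- dgamma(t, shape = peak1 + 1, rate = 1) -
    ratio * dgamma(t, shape = peak2 + 1, rate = 1)
  h / max(h)
}

# internal: boxcar from events convolved with the canonical HRF, on the
# session timeline
task_regressor <- function(events, n_samples, fs, hrf = NULL) {
  if (is.null(hrf)) hrf <- hrf_double_gamma(dt = 1 / fs)
  box <- numeric(n_samples)
  tt <- (seq_len(n_samples) - 1L) / fs
  for (k in which(events$kind == "task"))
    box[tt >= events$onset_s[k] & tt < events$onset_s[k] + events$duration_s[k]] <- 1
  reg <- convolve(box, rev(hrf), type = "open")[seq_len(n_samples)]
  reg
}

#' Per-channel GLM beta estimation
#'
#' Regresses each channel's HbO series on an intercept and a task regressor
#' (event boxcar convolved with the canonical double-gamma HRF, bandpass
#' filtered identically to the data so the passband restriction does not bias
#' the estimate).  The task coefficient beta quantifies activation.
#'
#' @param hbo channels x samples HbO matrix (already preprocessed).
#' @param events event data.frame with task blocks.
#' @param fs sampling rate (Hz).
#' @param band passband applied to the regressor (match the data filtering;
#'   \code{NULL} to skip).
#' @param hrf optional HRF samples at \code{1/fs} spacing.
#' @return list of class \code{"beta_map"}: \code{beta} (one per channel),
#'   \code{se}, \code{design_info}.
#' @export
fit_glm <- function(hbo, events, fs = 10, band = c(0.01, 0.08), hrf = NULL) {
  hbo <- as.matrix(hbo)
  ns <- ncol(hbo)
  if (nrow(events[events$kind == "task", , drop = FALSE]) == 0L)
    stop_strokesyn("no task events within the recording", "strokesyn_glm_error")
  reg <- task_regressor(events, ns, fs, hrf)
  if (!is.null(band)) reg <- bandpass_hemo(reg, fs = fs, band = band)
  X <- cbind(1, reg)
  if (qr(X)$rank < 2L)
    stop_strokesyn("rank-deficient design matrix", "strokesyn_glm_error")
  fit <- lm.fit(X, t(hbo))
  cf <- fit$coefficients
  if (is.null(dim(cf))) cf <- matrix(cf, ncol = 1L)
  res <- as.matrix(fit$residuals)
  dfree <- ns - 2L
  xtxinv <- chol2inv(chol(crossprod(X)))[2L, 2L]
  se <- sqrt(colSums(res^2) / dfree * xtxinv)
  structure(list(beta = unname(cf[2L, ]), se = unname(se),
                 design_info = list(hrf = "double-gamma (peak 6 s, undershoot 16 s, ratio 1/6)",
                                    band = band, n_samples = ns, fs = fs)),
            class = "beta_map")
}

#' @export
print.beta_map <- function(x, ...) {
  cat(sprintf("GLM beta map: %d channels; beta range [%.3f, %.3f]\n",
              length(x$beta), min(x$beta), max(x$beta)))
  invisible(x)
}

#' Full fNIRS preprocessing chain for one session
#'
#' Intensity to OD, kurtosis-based wavelet artifact correction, 0.01-0.08 Hz
#' bandpass, MBLL conversion, then per-channel GLM.  HbR is carried through
#' the MBLL but not consumed by any later stage.
#'
#' @param session \code{fnirs_session}.
#' @param dpf,extinction,k_threshold,band pipeline parameters.
#' @return list with \code{beta_map}, \code{hemo} (\code{hemo_series}),
#'   \code{od_corrected}.
#' @export
fnirs_pipeline <- function(session, dpf = 6.0, extinction = extinction_defaults(),
                           k_threshold = 3.3, band = c(0.01, 0.08)) {
  od <- intensity_to_od(session$intensity)
  for (ch in seq_len(dim(od)[1])) for (w in 1:2)
    od[ch, w, ] <- kurtosis_wavelet_correct(od[ch, w, ], k_threshold = k_threshold)
  od <- bandpass_hemo(od, fs = session$fs, band = band)
  hemo <- mbll_convert(od, dpf = dpf, extinction = extinction,
                       distance_mm = session$source_detector_mm)
  bm <- fit_glm(hemo$hbo, session$events, fs = session$fs, band = band)
  list(beta_map = bm, hemo = hemo, od_corrected = od)
}
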