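# Orthonormal Daubechies-5 wavelet transform and the kurtosis-based wavelet
# motion-artifact correction used on fNIRS optical-density series.
#
# The periodized analysis/synthesis pair below is a plain orthonormal filter
# bank: analysis correlates the signal with even shifts of the scaling/wavelet
# filters, synthesis is the transpose, so reconstruction is exact to machine
# precision.  Signals are symmetrically padded to a multiple of 2^levels
# before the transform and truncated afterwards.

# db5 orthonormal scaling filter (10 taps)
DB5_H <- c(0.16010239797419293, 0.60382926979718957, 0.72430852843777293,
           0.13842814590132074, -0.24229488706638203, -0.03224486958463837,
           0.07757149384004572, -0.00624149021279827, -0.01258075199908200,
           0.00333572528547377)
# quadrature mirror wavelet filter g[n] = (-1)^n h[L-1-n]
DB5_G <- rev(DB5_H) * (-1)^(seq_along(DB5_H) - 1L)

# internal: one-level periodized analysis -> list(approx, detail)
dwt_step <- function(x, h = DB5_H, g = DB5_G) {
  N <- length(x)
  L <- length(h)
  idx <- outer(seq(0L, N - 2L, by = 2L), seq_len(L) - 1L, "+") %% N + 1L
  Xm <- matrix(x[idx], nrow = N %/% 2L, ncol = L)
  list(a = as.numeric(Xm %*% h), d = as.numeric(Xm %*% g))
}

# internal: one-level periodized synthesis (transpose of dwt_step)
idwt_step <- function(a, d, h = DB5_H, g = DB5_G) {
  N <- 2L * length(a)
  L <- length(h)
  x <- numeric(N)
  for (n in seq_len(L)) {
    pos <- (seq(0L, N - 2L, by = 2L) + (n - 1L)) %% N + 1L
    contrib <- a * h[n] + d * g[n]
    # accumulate with possible repeated positions (N < L case excluded upstream)
    x[pos] <- x[pos] + contrib
  }
  x
}

# internal: multilevel periodized DWT; returns list(details = list, approx, n)
dwt_multilevel <- function(x, levels) {
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a)
    details[[j]] <- s$d
    a <- s$a
  }
  list(details = details, approx = a)
}

dwt_inverse <- function(decomp) {
  a <- decomp$approx
  for (j in rev(seq_along(decomp$details)))
    a <- idwt_step(a, decomp$details[[j]])
  a
}

# internal: (non-excess) sample kurtosis m4 / m2^2; Gaussian -> ~3
sample_kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^4) / m2^2
}

#' Kurtosis-based wavelet motion-artifact correction
#'
#' Per series: multilevel Daubechies-5 wavelet decomposition (5 levels,
#' symmetric padding to a multiple of 2^5); at each detail level whose
#' coefficient kurtosis exceeds \code{k_threshold}, the largest-magnitude
#' coefficient is zeroed repeatedly until the kurtosis falls to the threshold;
#' then the inverse transform restores the series at its original length.
#' Motion spikes concentrate energy in few large detail coefficients and push
#' the kurtosis far above the Gaussian value of ~3, so they are removed while
#' near-Gaussian levels pass through untouched.
#'
#' @param od numeric vector or matrix (series in rows).
#' @param k_threshold kurtosis threshold (default 3.3).
#' @param levels decomposition depth.
#' @return corrected series, same shape and length as the input.
#' @export
kurtosis_wavelet_correct <- function(od, k_threshold = 3.3, levels = 5L) {
  if (is.matrix(od)) {
    out <- t(apply(od, 1L, kurtosis_wavelet_correct,
                   k_threshold = k_threshold, levels = levels))
    dimnames(out) <- dimnames(od)
    return(out)
  }
  x <- as.numeric(od)
  n <- length(x)
  block <- 2L^levels
  if (n < max(block, length(DB5_H)))
    stop_strokesyn(sprintf("series of length %d too short for a %d-level db5 transform",
                           n, levels), "strokesyn_wavelet_error")
  pad <- (block - n %% block) %% block
  if (pad > 0) {
    # symmetric (reflection) padding keeps the appended stretch artifact-free
    x <- c(x, rev(x)[seq_len(pad)])
  }
  dec <- dwt_multilevel(x, levels)
  for (j in seq_len(levels)) {
    d <- dec$details[[j]]
    while (length(d) > 3L && sample_kurtosis(d) > k_threshold && any(d != 0)) {
      d[which.max(abs(d))] <- 0
    }
    dec$details[[j]] <- d
  }
  y <- dwt_inverse(dec)
  y[seq_len(n)]
}
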