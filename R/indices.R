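# Muscle-synergy indices computed per subject and arm: the synergy stability
# index (SSI, stability of the base vector across lifts), closeness of the
# base vector to the control baseline (C_V, cosine similarity) and closeness
# of the time profile to the control baseline (C_T, maximum normalized
# circular cross-correlation).

#' Synergy stability index
#'
#' Mean Pearson correlation of the per-lift base vectors over all ordered
#' pairs: \code{SSI = 1/(K^2 i (i-1)) * sum_{l != q} r(V_l, V_q)} with
#' \code{i} lifts and \code{K} synergies.  With \code{K = 1} (the supported
#' scope) this is the mean pairwise correlation, in [-1, 1].
#'
#' @param V_list list of per-lift base vectors (equal length, length >= 2
#'   vectors required).
#' @param K number of synergies (only 1 supported).
#' @return scalar SSI.
#' @export
synergy_stability_index <- function(V_list, K = 1L) {
  if (K != 1L)
    stop_strokesyn("only K = 1 is supported", "strokesyn_domain_error")
  i <- length(V_list)
  if (i < 2L)
    stop_strokesyn("SSI undefined for fewer than 2 lifts", "strokesyn_index_error")
  sds <- vapply(V_list, sd, numeric(1))
  if (any(sds == 0))
    stop_strokesyn(sprintf("constant base vector in lift %d: Pearson correlation undefined",
                           which(sds == 0)[1L]), "strokesyn_index_error")
  total <- 0
  for (l in seq_len(i)) for (q in seq_len(i)) if (l != q)
    total <- total + cor(V_list[[l]], V_list[[q]])
  total / (K^2 * i * (i - 1))
}

#' Closeness of a synergy base vector to the baseline
#'
#' Cosine similarity between an individual lift's base vector and the control
#' baseline vector.  For non-negative inputs the value lies in [0, 1], 1
#' meaning identical muscle weighting.
#'
#' @param V_i individual base vector.
#' @param V_B baseline base vector (same length).
#' @return scalar cosine similarity.
#' @export
closeness_vector <- function(V_i, V_B) {
  if (length(V_i) != length(V_B))
    stop_strokesyn("vectors must have equal length", "strokesyn_shape_error")
  ni <- l2norm(V_i); nb <- l2norm(V_B)
  if (ni == 0 || nb == 0)
    stop_strokesyn("zero vector: cosine undefined", "strokesyn_index_error")
  sum(V_i * V_B) / (ni * nb)
}

#' Closeness of a synergy time profile to the baseline
#'
#' Maximum over circular lags of the normalized circular cross-correlation
#' \code{max_tau sum_m T_i(m) T_B(m + tau) / sqrt(sum T_i^2 * sum T_B^2)}.
#' For non-negative profiles the value lies in [0, 1] and is invariant to
#' circular shifts of either argument.
#'
#' @param T_i individual time profile.
#' @param T_B baseline time profile (same length).
#' @return scalar C_T.
#' @export
closeness_time <- function(T_i, T_B) {
  if (length(T_i) != length(T_B))
    stop_strokesyn("profiles must have equal length", "strokesyn_shape_error")
  ni <- l2norm(T_i); nb <- l2norm(T_B)
  if (ni == 0 || nb == 0)
    stop_strokesyn("zero profile: C_T undefined", "strokesyn_index_error")
  q <- length(T_i)
  cc <- vapply(seq_len(q) - 1L, function(tau) {
    sum(T_i * T_B[((seq_len(q) - 1L + tau) %% q) + 1L])
  }, numeric(1))
  max(cc) / (ni * nb)
}

#' Aggregate per-lift synergy indices to one value per subject-arm
#'
#' C_V and C_T are averaged over the retained lifts; SSI is computed once
#' over all retained lifts of the arm.  With fewer than two lifts SSI is
#' reported as \code{NA}.
#'
#' @param V_list per-lift base vectors of one arm.
#' @param T_list per-lift time profiles of one arm.
#' @param baseline \code{baseline_synergy} for the matching hand.
#' @param arm "affected" or "unaffected".
#' @return list of class \code{"synergy_indices"}: \code{ssi}, \code{c_v},
#'   \code{c_t}, \code{arm}, \code{lifts_used}.
#' @export
aggregate_indices <- function(V_list, T_list, baseline, arm = c("affected", "unaffected")) {
  arm <- match.arg(arm)
  stopifnot(length(V_list) == length(T_list))
  i <- length(V_list)
  if (i == 0L) {
    return(structure(list(ssi = NA_real_, c_v = NA_real_, c_t = NA_real_,
                          arm = arm, lifts_used = 0L), class = "synergy_indices"))
  }
  c_v <- mean(vapply(V_list, closeness_vector, numeric(1), V_B = baseline$V_B))
  c_t <- mean(vapply(T_list, closeness_time, numeric(1), T_B = baseline$T_B))
  ssi <- if (i >= 2L) synergy_stability_index(V_list) else NA_real_
  structure(list(ssi = ssi, c_v = c_v, c_t = c_t, arm = arm, lifts_used = i),
            class = "synergy_indices")
}

#' @export
print.synergy_indices <- function(x, ...) {
  cat(sprintf("synergy indices (%s arm, %d lifts): SSI = %s, C_V = %.4f, C_T = %.4f\n",
              x$arm, x$lifts_used,
              if (is.na(x$ssi)) "NA" else sprintf("%.4f", x$ssi), x$c_v, x$c_t))
  invisible(x)
}
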