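# Muscle-synergy extraction by multivariate curve resolution - alternating
# least squares (MCR-ALS) with non-negativity constraints and deterministic
# SIMPLISMA-style pure-variable initialization.
#
# A lift is a matrix X (p x q): p = 5 muscles, q = 50 time-normalized samples,
# entries in [0, 1].  The model is X ~ V %*% T with V (p x n) the non-negative
# base vectors (columns unit Euclidean norm) and T (n x q) the non-negative
# time profiles; E = X - V T is the residual.

#' Variance accounted for by a reconstruction
#'
#' \code{VAF = 1 - ||X - M||^2 / ||X - mean(X)||^2}, where \code{mean(X)} is
#' the matrix whose columns hold the column means of \code{X} (the mean across
#' muscles at each time sample) and \code{||.||} is the Frobenius norm.
#'
#' @param X observed non-negative matrix (p x q).
#' @param M reconstruction, same shape as \code{X}.
#' @return scalar VAF in (-Inf, 1]; 1 means a perfect reconstruction.
#' @examples
#' X <- matrix(runif(20), 4, 5)
#' compute_vaf(X, X)  # 1
#' @export
compute_vaf <- function(X, M) {
  X <- as.matrix(X); M <- as.matrix(M)
  if (!all(dim(X) == dim(M)))
    stop_strokesyn("X and M must have the same shape", "strokesyn_shape_error")
  mu <- matrix(colMeans(X), nrow(X), ncol(X), byrow = TRUE)
  denom <- sum((X - mu)^2)
  if (denom <= 0)
    stop_strokesyn("VAF undefined: X is constant within every column", "strokesyn_vaf_error")
  1 - sum((X - M)^2) / denom
}

# internal: SIMPLISMA-style pure-variable selection.  Purity of column j is
# sd_j / (mean_j + offset) with offset = 5% of the largest column mean;
# subsequent picks are down-weighted by the fraction of their energy outside
# the span of already-selected columns.
simplisma_init <- function(X, n) {
  p <- nrow(X); q <- ncol(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2L, function(c) sqrt(mean((c - mean(c))^2)))
  offset <- 0.05 * max(mu)
  purity <- sdv / (mu + offset)
  picked <- integer(0)
  V <- matrix(0, p, n)
  basis <- NULL  # orthonormal basis of picked columns
  for (k in seq_len(n)) {
    w <- rep(1, q)
    if (!is.null(basis)) {
      proj <- crossprod(basis, X)                  # (k-1) x q
      en <- colSums(X^2)
      w <- ifelse(en > 0, pmax(0, 1 - colSums(proj^2) / en), 0)
    }
    score <- purity * w
    score[picked] <- -Inf
    j <- which.max(score)
    picked <- c(picked, j)
    col <- X[, j]
    if (all(col == 0)) col <- rep(1, p)
    V[, k] <- col / l2norm(col)
    u <- col
    if (!is.null(basis)) u <- u - basis %*% crossprod(basis, col)
    if (l2norm(u) > 1e-12) basis <- cbind(basis, u / l2norm(u))
  }
  V
}

#' MCR-ALS synergy decomposition of a single lift
#'
#' Factorizes a non-negative lift matrix \code{X} (muscles x time) as
#' \code{V \%*\% T} with non-negative factors, by alternating exact
#' non-negative least-squares solves.  Initialization picks \code{n} pure
#' variables (time samples) by a SIMPLISMA purity criterion, so the algorithm
#' is fully deterministic -- the stated motivation for preferring MCR-ALS over
#' randomly initialized NMF in this setting.  On exit the columns of \code{V}
#' are rescaled to unit Euclidean norm with the scale absorbed into \code{T}.
#'
#' @param X non-negative matrix (p x q).
#' @param n number of synergies, \code{1 <= n <= min(p, q)}.
#' @param tol convergence tolerance on the relative VAF change.
#' @param max_iter iteration cap.
#' @return object of class \code{"mcr_als"} with elements \code{V} (p x n,
#'   unit-norm columns), \code{T} (n x q), \code{E} (residual \code{X - V T}),
#'   \code{vaf}, \code{n}, \code{iterations}, \code{converged},
#'   \code{objective} (per-iteration \code{||X - V T||^2}).
#' @examples
#' v <- c(0.2, 0.1, 0.9, 0.1, 0.4); v <- v / sqrt(sum(v^2))
#' X <- v %*% t(sin(seq(0, pi, length.out = 50))^2)
#' m <- mcr_als(X, n = 1)
#' m$vaf
#' @export
mcr_als <- function(X, n = 1L, tol = 1e-8, max_iter = 500L) {
  X <- as.matrix(X)
  if (any(X < 0))
    stop_strokesyn("X must be non-negative", "strokesyn_domain_error")
  p <- nrow(X); q <- ncol(X)
  if (n < 1L || n > min(p, q))
    stop_strokesyn(sprintf("n must be in [1, %d]", min(p, q)), "strokesyn_domain_error")
  V <- simplisma_init(X, n)
  vaf_prev <- -Inf
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  Tm <- matrix(0, n, q)
  for (iter in seq_len(max_iter)) {
    if (n == 1L) {
      # single-component NNLS has a closed form: positive part of the
      # least-squares projection
      Tm <- matrix(pmax(crossprod(V, X), 0) / sum(V^2), 1L, q)
      te <- sum(Tm^2)
      V <- matrix(if (te > 0) pmax(X %*% t(Tm), 0) / te else rep(1 / sqrt(p), p),
                  p, 1L)
    } else {
      Tm <- nnls_multi(V, X)                        # T given V
      V <- t(nnls_multi(t(Tm), t(X)))               # V given T (rows of V)
    }
    # guard against collapsed (all-zero) components
    dead <- colSums(V) == 0 & rowSums(Tm) == 0
    if (any(dead)) V[, dead] <- 1 / sqrt(p)
    R <- X - V %*% Tm
    objective <- c(objective, sum(R^2))
    vaf <- compute_vaf(X, V %*% Tm)
    if (is.finite(vaf_prev) && abs(vaf - vaf_prev) <= tol * max(1, abs(vaf_prev))) {
      converged <- TRUE
      break
    }
    vaf_prev <- vaf
  }
  # unit-norm V columns, scale absorbed into T
  nrm <- sqrt(colSums(V^2))
  nz <- nrm > 0
  V[, nz] <- sweep(V[, nz, drop = FALSE], 2L, nrm[nz], "/")
  Tm[nz, ] <- sweep(Tm[nz, , drop = FALSE], 1L, nrm[nz], "*")
  M <- V %*% Tm
  structure(list(V = V, T = Tm, E = X - M, vaf = compute_vaf(X, M),
                 n = n, iterations = iter, converged = converged,
                 objective = objective, X = X),
            class = "mcr_als")
}

#' @export
print.mcr_als <- function(x, ...) {
  cat(sprintf("MCR-ALS decomposition: %d muscle(s) x %d sample(s), n = %d synergy(ies)\n",
              nrow(x$V), ncol(x$T), x$n))
  cat(sprintf("  VAF = %.4f after %d iteration(s)%s\n", x$vaf, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
fitted.mcr_als <- function(object, ...) object$V %*% object$T

#' @export
residuals.mcr_als <- function(object, ...) object$E

#' @export
summary.mcr_als <- function(object, ...) {
  out <- list(n = object$n, vaf = object$vaf, iterations = object$iterations,
              converged = object$converged,
              v_peak = apply(object$V, 2L, which.max))
  class(out) <- "summary.mcr_als"
  out
}

#' @export
print.summary.mcr_als <- function(x, ...) {
  cat(sprintf("n = %d synergies, VAF = %.4f (%d iterations, converged: %s)\n",
              x$n, x$vaf, x$iterations, x$converged))
  cat("dominant muscle per synergy:", paste(x$v_peak, collapse = ", "), "\n")
  invisible(x)
}

#' Minimum synergy count satisfying the group VAF criterion
#'
#' Returns the smallest \code{n} such that strictly more than half of the
#' subjects in \emph{each} group have a subject-level VAF above the threshold.
#' Subject-level VAF at a given \code{n} is the mean over that subject's
#' retained lifts.
#'
#' @param vaf_by_subject numeric matrix, subjects x synergy counts
#'   (column j = VAF at n = j), rownames are subject ids.
#' @param group factor/character vector per subject (two or more groups).
#' @param threshold VAF threshold (default 0.80).
#' @return list with \code{n} (selected count) and \code{criterion_met}
#'   (FALSE when even the maximum count fails, in which case the maximum is
#'   returned with a warning).
#' @export
select_synergy_count <- function(vaf_by_subject, group, threshold = 0.80) {
  vaf_by_subject <- as.matrix(vaf_by_subject)
  group <- as.factor(group)
  stopifnot(length(group) == nrow(vaf_by_subject))
  for (n in seq_len(ncol(vaf_by_subject))) {
    ok <- vapply(levels(group), function(g) {
      v <- vaf_by_subject[group == g, n]
      sum(v > threshold) > length(v) / 2     # strict majority
    }, logical(1))
    if (all(ok)) return(list(n = n, criterion_met = TRUE))
  }
  warning("VAF criterion not met at any synergy count; returning the maximum")
  list(n = ncol(vaf_by_subject), criterion_met = FALSE)
}

#' Baseline synergy from healthy controls
#'
#' Averages unit-normalized per-lift base vectors and unit-energy time
#' profiles across a control subject's retained lifts, then across subjects,
#' renormalizing at each stage (V_B to unit Euclidean norm, T_B to unit
#' energy).  Computed separately per hand (dominant / non-dominant).
#'
#' @param models nested list: one element per control subject, each a list of
#'   per-lift \code{mcr_als} fits with \code{n = 1}.
#' @param hand label stored on the result ("dominant" or "non-dominant").
#' @return list of class \code{"baseline_synergy"}: \code{V_B} (unit-norm
#'   5-vector), \code{T_B} (unit-energy 50-vector), \code{hand},
#'   \code{n_subjects}, \code{skipped} (ids of subjects with no retained lifts).
#' @export
compute_baseline <- function(models, hand = c("dominant", "non-dominant")) {
  hand <- match.arg(hand)
  if (length(models) == 0L)
    stop_strokesyn("no control subjects supplied", "strokesyn_baseline_error")
  skipped <- character(0)
  Vs <- list(); Ts <- list()
  ids <- names(models)
  if (is.null(ids)) ids <- as.character(seq_along(models))
  for (s in seq_along(models)) {
    lifts <- models[[s]]
    if (length(lifts) == 0L) { skipped <- c(skipped, ids[s]); next }
    Vm <- sapply(lifts, function(m) { v <- m$V[, 1L]; v / l2norm(v) })
    Tm <- sapply(lifts, function(m) { tt <- m$T[1L, ]; tt / l2norm(tt) })
    v <- rowMeans(Vm); tt <- rowMeans(Tm)
    Vs[[length(Vs) + 1L]] <- v / l2norm(v)
    Ts[[length(Ts) + 1L]] <- tt / l2norm(tt)
  }
  if (length(Vs) == 0L)
    stop_strokesyn("no control subject has retained lifts", "strokesyn_baseline_error")
  V_B <- rowMeans(do.call(cbind, Vs)); V_B <- V_B / l2norm(V_B)
  T_B <- rowMeans(do.call(cbind, Ts)); T_B <- T_B / l2norm(T_B)
  structure(list(V_B = V_B, T_B = T_B, hand = hand,
                 n_subjects = length(Vs), skipped = skipped),
            class = "baseline_synergy")
}
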