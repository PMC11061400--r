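# Exact non-negative least squares for many right-hand sides.
#
# The alternating least-squares loop of mcr_als() solves, at every iteration,
# min ||A w - b||^2 subject to w >= 0 for each of the q = 50 time samples (and
# each of the p = 5 muscle rows).  With at most n = 5 unknowns the unique NNLS
# solution can be found exactly by enumerating the 2^n - 1 candidate supports
# and checking the KKT conditions, which vectorizes over all right-hand sides
# and avoids an R-level active-set loop per column.

#' Non-negative least squares with multiple right-hand sides
#'
#' Solves \code{min ||A W - B||^2} over \code{W >= 0} column by column, exactly.
#' Intended for small systems (\code{ncol(A) <= 8}); the unique solution is
#' identified by support enumeration with a KKT check.
#'
#' @param A numeric matrix (m x n), n small.
#' @param B numeric matrix (m x k) of right-hand sides (a vector is treated as
#'   one column).
#' @param tol feasibility/optimality tolerance.
#' @return numeric matrix (n x k) with non-negative entries.
#' @keywords internal
nnls_multi <- function(A, B, tol = 1e-10) {
  A <- as.matrix(A)
  if (is.vector(B)) B <- matrix(B, ncol = 1L)
  n <- ncol(A); k <- ncol(B)
  if (n > 8L) stop_strokesyn("nnls_multi supports at most 8 unknowns", "strokesyn_nnls_error")
  AtA <- crossprod(A)
  AtB <- crossprod(A, B)
  scale <- max(diag(AtA), 1)
  W <- matrix(0, n, k)
  # gradient at W = 0 is -AtB; zero solution is optimal where AtB <= 0
  unsolved <- which(apply(AtB > tol * scale, 2L, any))
  if (length(unsolved) == 0L) return(W)
  supports <- lapply(seq_len(2L^n - 1L), function(m) which(bitwAnd(m, 2L^(seq_len(n) - 1L)) > 0L))
  # visit small supports first: the first KKT-feasible support wins
  supports <- supports[order(lengths(supports))]
  for (S in supports) {
    if (length(unsolved) == 0L) break
    AtA_S <- AtA[S, S, drop = FALSE]
    sol <- tryCatch(solve(AtA_S, AtB[S, unsolved, drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(sol)) next
    feas <- apply(sol >= -tol * scale, 2L, all)
    if (!any(feas)) next
    # KKT: gradient AtA W - AtB must be >= 0 on the zero set
    grad <- AtA[, S, drop = FALSE] %*% sol[, feas, drop = FALSE] -
      AtB[, unsolved[feas], drop = FALSE]
    comp <- setdiff(seq_len(n), S)
    ok <- if (length(comp)) apply(grad[comp, , drop = FALSE] >= -tol * scale, 2L, all)
          else rep(TRUE, sum(feas))
    if (!any(ok)) next
    hit <- unsolved[feas][ok]
    W[S, hit] <- pmax(sol[, feas, drop = FALSE][, ok, drop = FALSE], 0)
    unsolved <- setdiff(unsolved, hit)
  }
  if (length(unsolved)) {
    # numerically degenerate columns: fall back to ridge-regularized supports
    AtA_r <- AtA + diag(1e-12 * scale, n)
    for (j in unsolved) {
      best <- NULL; best_obj <- Inf
      for (S in supports) {
        sol <- tryCatch(solve(AtA_r[S, S, drop = FALSE], AtB[S, j]),
                        error = function(e) NULL)
        if (is.null(sol) || any(sol < -tol * scale)) next
        w <- numeric(n); w[S] <- pmax(sol, 0)
        obj <- sum(w * (AtA %*% w)) - 2 * sum(w * AtB[, j])
        if (obj < best_obj) { best_obj <- obj; best <- w }
      }
      if (!is.null(best)) W[, j] <- best
    }
  }
  W
}
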