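# VAF, the multi-RHS NNLS solver, MCR-ALS decomposition, synergy-count
# selection and control baselines.

test_that("VAF identities and worked example match a norm-based oracle", {
  set.seed(1)
  X <- matrix(runif(20, 0.1, 1), 4, 5)
  expect_equal(compute_vaf(X, X), 1)
  mu <- matrix(colMeans(X), 4, 5, byrow = TRUE)
  expect_equal(compute_vaf(X, mu), 0)
  # worked 2x2 example, cross-checked against explicit Frobenius norms
  X2 <- matrix(c(1, 3, 2, 4), 2, 2)       # rows (1,2), (3,4)
  M2 <- matrix(c(1, 3, 2, 5), 2, 2)       # rows (1,2), (3,5)
  expect_equal(compute_vaf(X2, M2), vaf_oracle(X2, M2))
  expect_equal(compute_vaf(X2, M2), 1 - 1 / 4)
  expect_error(compute_vaf(matrix(2, 3, 3), matrix(1, 3, 3)),
               class = "strokesyn_vaf_error")
})

test_that("nnls_multi agrees with an established NNLS solver", {
  skip_if_not_installed("pracma")
  set.seed(11)
  for (rep in 1:25) {
    m <- sample(4:12, 1); n <- sample(1:5, 1)
    A <- matrix(runif(m * n), m, n)
    B <- matrix(rnorm(m * 3), m, 3)
    W <- nnls_multi(A, B)
    for (j in 1:3) {
      ref <- pracma::lsqnonneg(A, B[, j])$x
      expect_equal(unname(W[, j]), unname(ref), tolerance = 1e-7)
    }
  }
})

test_that("MCR-ALS recovers a planted rank-1 factorization exactly", {
  for (seed in 1:10) {
    v <- unit_nonneg(seed)
    tt <- bell50() * runif(1, 0.2, 1)
    X <- v %*% t(tt)
    m <- mcr_als(X, n = 1)
    expect_gte(m$vaf, 1 - 1e-9)
    expect_gte(abs(sum(m$V[, 1] * v)), 1 - 1e-9)
    expect_equal(sqrt(sum(m$V[, 1]^2)), 1)
  }
})

test_that("MCR-ALS respects its contracts on degenerate and invalid input", {
  X <- matrix(runif(250), 5, 50)
  expect_error(mcr_als(X - 1, 1), class = "strokesyn_domain_error")
  expect_error(mcr_als(X, 0), class = "strokesyn_domain_error")
  expect_error(mcr_als(X, 6), class = "strokesyn_domain_error")
  # an all-zero muscle row stays zero in the n = 1 solution
  X0 <- X; X0[3, ] <- 0
  m <- mcr_als(X0, 1)
  expect_equal(m$V[3, 1], 0)
})

test_that("VAF is non-decreasing in n and the objective never increases", {
  set.seed(5)
  for (rep in 1:4) {
    X <- abs(matrix(rnorm(250), 5, 50))
    vafs <- vapply(1:5, function(n) mcr_als(X, n)$vaf, numeric(1))
    expect_true(all(diff(vafs) >= -1e-9))
    m <- mcr_als(X, 3)
    expect_true(all(diff(m$objective) <= 1e-9))
  }
})

test_that("MCR-ALS is scale invariant: V fixed, T scales with the data", {
  set.seed(3)
  X <- abs(matrix(rnorm(250), 5, 50)) + 0.01
  m1 <- mcr_als(X, 2)
  m2 <- mcr_als(5 * X, 2)
  expect_equal(m2$V, m1$V, tolerance = 1e-6)
  expect_equal(m2$T, 5 * m1$T, tolerance = 1e-5)
})

test_that("rank-1 MCR-ALS matches a dense grid search on small matrices", {
  set.seed(8)
  for (rep in 1:3) {
    X <- abs(matrix(rnorm(12), 3, 4))
    m <- mcr_als(X, 1)
    # oracle: scan unit non-negative directions on a spherical grid; the
    # optimal T given v >= 0 is the positive part of the projection
    best <- -Inf
    for (th1 in seq(0, pi / 2, length.out = 90)) {
      for (th2 in seq(0, pi / 2, length.out = 90)) {
        v <- c(cos(th1), sin(th1) * cos(th2), sin(th1) * sin(th2))
        tt <- pmax(crossprod(X, v), 0)
        best <- max(best, vaf_oracle(X, v %*% t(tt)))
      }
    }
    expect_equal(m$vaf, best, tolerance = 1e-3)
  }
})

test_that("synergy-count rule needs a strict majority above 80% in each group", {
  # everyone passes at n = 1
  v <- matrix(0.95, 10, 3)
  g <- rep(c("patient", "control"), each = 5)
  expect_equal(select_synergy_count(v, g)$n, 1L)
  # patients 8/15 pass at n = 1 but controls only 7/15; both pass at n = 2
  vaf <- matrix(0, 30, 3)
  vaf[1:8, 1] <- 0.9;  vaf[9:15, 1] <- 0.5    # patients at n = 1
  vaf[16:22, 1] <- 0.9; vaf[23:30, 1] <- 0.5  # controls at n = 1 (7/15)
  vaf[1:9, 2] <- 0.9;  vaf[10:15, 2] <- 0.5   # patients at n = 2 (9/15)
  vaf[16:24, 2] <- 0.9; vaf[25:30, 2] <- 0.5  # controls at n = 2 (9/15)
  vaf[, 3] <- 0.95
  g2 <- rep(c("patient", "control"), each = 15)
  expect_equal(select_synergy_count(vaf, g2)$n, 2L)
  # exactly half is not a strict majority
  v3 <- matrix(0, 4, 2); v3[1:2, 1] <- 0.9; v3[, 2] <- 0.9
  g3 <- rep("patient", 4)
  expect_equal(select_synergy_count(v3, g3)$n, 2L)
  # unreachable criterion returns the maximum with a warning
  expect_warning(res <- select_synergy_count(matrix(0.1, 4, 2), g3))
  expect_false(res$criterion_met)
})

test_that("control baselines average unit-normalized lifts then subjects", {
  lift_model <- function(v, tt) {
    v <- v / sqrt(sum(v^2))
    structure(list(V = matrix(v, ncol = 1), T = matrix(tt, nrow = 1)),
              class = "mcr_als")
  }
  tt <- bell50()
  # one subject with identical lifts reproduces that V
  v <- unit_nonneg(2)
  b1 <- compute_baseline(list(S1 = list(lift_model(v, tt), lift_model(v, tt))),
                         hand = "dominant")
  expect_equal(b1$V_B, v, tolerance = 1e-12)
  expect_equal(sum(b1$T_B^2), 1)
  # two orthogonal single-muscle subjects -> (e1 + e2)/sqrt(2)
  b2 <- compute_baseline(list(
    A = list(lift_model(c(1, 0, 0, 0, 0), tt)),
    B = list(lift_model(c(0, 1, 0, 0, 0), tt))), hand = "non-dominant")
  expect_equal(b2$V_B, c(1, 1, 0, 0, 0) / sqrt(2))
  # identical bells give the same bell at unit energy
  expect_equal(b2$T_B, tt / sqrt(sum(tt^2)))
  # subjects without retained lifts are skipped, none at all is an error
  b3 <- compute_baseline(list(A = list(lift_model(v, tt)), B = list()),
                         hand = "dominant")
  expect_equal(b3$skipped, "B")
  expect_error(compute_baseline(list(A = list()), hand = "dominant"),
               class = "strokesyn_baseline_error")
})
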