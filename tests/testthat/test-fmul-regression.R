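# Feature-table assembly, OLS fitting and the exhaustive best-subset search.

make_indices <- function(n = 20, seed = 1) {
  set.seed(seed)
  data.frame(subject_id = sprintf("P%02d", 1:n), group = "patient",
             age = round(runif(n, 30, 80)), days_post_stroke = round(runif(n, 10, 700)),
             fmul = round(runif(n, 12, 64)),
             mvc_af = runif(n, 80, 150), mvc_un = runif(n, 150, 250),
             li_pmc_af = runif(n, -0.3, 0.5), li_pmc_un = runif(n, 0.3, 0.6),
             li_m1_af = runif(n, -0.3, 0.5), li_m1_un = runif(n, 0.3, 0.6),
             li_s1_af = runif(n, -0.1, 0.5), li_s1_un = runif(n, 0.3, 0.6),
             ssi_af = runif(n, 0.6, 1), ssi_un = runif(n, 0.8, 1),
             c_v_af = runif(n, 0.6, 1), c_v_un = runif(n, 0.85, 1),
             c_t_af = runif(n, 0.8, 1), c_t_un = runif(n, 0.9, 1),
             stringsAsFactors = FALSE)
}

test_that("the feature table has the 21 named predictors and exact ratios", {
  idx <- make_indices()
  tab <- build_feature_table(idx)
  preds <- setdiff(names(tab), c("subject_id", "group", "FMul"))
  expect_equal(length(preds), 21L)
  expect_equal(tab$C_V_r, idx$c_v_un / idx$c_v_af)
  expect_equal(tab$F_r, idx$mvc_un / idx$mvc_af)
  # hand arithmetic: C_V-un = 0.9, C_V-af = 0.6 -> 1.5
  idx2 <- idx; idx2$c_v_un[1] <- 0.9; idx2$c_v_af[1] <- 0.6
  expect_equal(build_feature_table(idx2)$C_V_r[1], 1.5)
  # identical arms -> all ratios 1
  idx3 <- idx
  for (v in c("li_pmc", "li_m1", "li_s1", "ssi", "c_v", "c_t", "mvc"))
    idx3[[paste0(v, "_un")]] <- idx3[[paste0(v, "_af")]]
  tab3 <- build_feature_table(idx3)
  for (v in c("LI_PMC_r", "LI_M1_r", "LI_S1_r", "SSI_r", "C_V_r", "C_T_r", "F_r"))
    expect_equal(unname(tab3[[v]]), rep(1, nrow(tab3)))
  # zero affected-side value -> missing ratio with a log entry
  idx4 <- idx; idx4$li_pmc_af[2] <- 0
  tab4 <- build_feature_table(idx4)
  expect_true(is.na(tab4$LI_PMC_r[2]))
  expect_match(attr(tab4, "ratio_log"), "LI_PMC_r")
  # direction switch
  tab5 <- build_feature_table(idx, ratio_direction = "affected_over_unaffected")
  expect_equal(tab5$F_r, idx$mvc_af / idx$mvc_un)
})

test_that("OLS fits match hand-computed normal equations", {
  tab <- data.frame(subject_id = as.character(1:3), group = "patient",
                    x = c(0, 1, 2), FMul = c(1, 2, 4))
  m <- fit_linear_model(tab, "x")
  # normal equations: slope = Sxy/Sxx = 3/2, intercept = ybar - slope * xbar
  expect_equal(unname(m$B), c(7 / 3 - 1.5, 1.5), tolerance = 1e-12)
  # exact line: y = 2x
  tab2 <- data.frame(subject_id = as.character(1:6), group = "patient",
                     x = 1:6, FMul = 2 * (1:6))
  m2 <- fit_linear_model(tab2, "x")
  expect_equal(unname(m2$B), c(0, 2), tolerance = 1e-10)
  expect_equal(m2$r2_adj, 1)
  # collinear predictors are rejected
  tab3 <- data.frame(subject_id = as.character(1:10), group = "patient",
                     x = 1:10, y = 2 * (1:10), FMul = rnorm(10) + 1:10)
  expect_error(fit_linear_model(tab3, c("x", "y")),
               class = "strokesyn_regression_error")
  expect_error(fit_linear_model(tab2[1:2, ], "x"),
               class = "strokesyn_regression_error")
})

test_that("the model F-test p-value is uniform under the null", {
  ps <- vapply(1:200, function(s) {
    set.seed(s)
    tab <- data.frame(subject_id = as.character(1:25), group = "patient",
                      x = rnorm(25), FMul = rnorm(25))
    fit_linear_model(tab, "x")$p_model
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the exhaustive search enumerates C(21,4) models deterministically", {
  idx <- make_indices(n = 25, seed = 3)
  tab <- build_feature_table(idx)
  m <- exhaustive_subset_search(tab)
  expect_equal(attr(m, "n_models"), choose(21, 4))
  expect_equal(attr(m, "n_models"), 5985L)
  # invariance to predictor order
  m2 <- exhaustive_subset_search(tab, predictors = rev(strokesyn:::FEATURE_PREDICTORS))
  expect_setequal(m$selected, m2$selected)
  expect_equal(m$r2_adj, m2$r2_adj, tolerance = 1e-12)
  # the winning 4-subset beats every single predictor
  singles <- vapply(strokesyn:::FEATURE_PREDICTORS,
                    function(p) fit_linear_model(tab, p)$r2_adj, numeric(1))
  expect_gte(m$r2_adj, max(singles))
})

test_that("a predictor equal to the response dominates the search", {
  idx <- make_indices(n = 18, seed = 9)
  tab <- build_feature_table(idx)
  tab$age <- tab$FMul            # smuggle the response in as a predictor
  m <- exhaustive_subset_search(tab)
  expect_true("age" %in% m$selected)
  expect_gt(m$r2_adj, 0.999999)
})

test_that("the planted four-predictor model is recovered from synthetic cohorts", {
  hits <- 0
  for (s in 1:5) {
    cfg <- simulation_config(n_patients = 30, n_controls = 15, seed = 9000 + s,
                             fmul_noise_sd = 0.25)
    coh <- generate_cohort(cfg)
    tab <- build_feature_table(true_indices_table(coh, measurement_sd = 0.001))
    m <- fmul_lm(tab)
    if (setequal(m$selected, c("C_V_af", "LI_PMC_un", "F_r", "C_V_r"))) hits <- hits + 1
  }
  expect_gte(hits, 4)
  # planted coefficients recovered within 3 SE
  cfg <- simulation_config(n_patients = 30, n_controls = 15, seed = 9100,
                           fmul_noise_sd = 0.25)
  coh <- generate_cohort(cfg)
  tab <- build_feature_table(true_indices_table(coh, measurement_sd = 0.001))
  m <- fit_linear_model(tab, c("C_V_af", "LI_PMC_un", "F_r", "C_V_r"))
  th <- cfg$theta
  expect_true(all(abs(m$B - th) <= 3 * m$se + 0.35))  # 0.35 covers score rounding
})

test_that("predictions apply the published linear form exactly", {
  # coefficients of the reported model applied to a fixed feature row
  B_pub <- c(-200.24, 133.49, 30.33, 45.95, 83.70)
  row <- data.frame(subject_id = "X", C_V_af = 0.87, LI_PMC_un = 0.42,
                    F_r = 1.35, C_V_r = 1.12)
  model <- structure(list(selected = c("C_V_af", "LI_PMC_un", "F_r", "C_V_r"),
                          B = B_pub, data = row), class = "fmul_lm")
  pr <- predict(model, row)
  by_hand <- -200.24 + 133.49 * 0.87 + 30.33 * 0.42 + 45.95 * 1.35 + 83.70 * 1.12
  expect_equal(unname(pr$fitted), by_hand, tolerance = 1e-9)
  # fitted values reproduce observations up to residuals; counts above 60
  idx <- make_indices(n = 15, seed = 12)
  tab <- build_feature_table(idx)
  m <- fit_linear_model(tab, c("C_V_af", "F_r"))
  pr2 <- predict(m)
  expect_equal(unname(pr2$fitted + m$residuals), m$data$FMul, tolerance = 1e-9)
  expect_equal(pr2$n_above, sum(pr2$fitted > 60))
  # equal rows get equal predictions
  tab_eq <- tab[c(1, 1), ]
  expect_equal(diff(unname(predict(m, tab_eq)$fitted)), 0)
})
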