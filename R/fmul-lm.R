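# Assembly of the 21-predictor feature table and the exhaustive best-subset
# linear model of the Fugl-Meyer upper-limb score (FMul): all C(21, 4) = 5985
# four-predictor OLS fits on the patient rows, selection by adjusted R^2.

FEATURE_PREDICTORS <- c("LI_PMC_af", "LI_M1_af", "LI_S1_af",
                        "LI_PMC_un", "LI_M1_un", "LI_S1_un",
                        "SSI_af", "SSI_un", "C_V_af", "C_V_un",
                        "C_T_af", "C_T_un",
                        "LI_PMC_r", "LI_M1_r", "LI_S1_r",
                        "SSI_r", "C_V_r", "C_T_r",
                        "age", "days_post_stroke", "F_r")

#' Assemble the 21-predictor feature table
#'
#' One row per subject.  Predictors: the three regional laterality indices
#' for affected- and unaffected-arm movement (6), SSI, C_V and C_T per arm
#' (6), the unaffected/affected ratios of those six indices (6), age, days
#' post stroke and the MVC force ratio F_r (3).  Controls contribute
#' days_post_stroke = 0 and their dominant/non-dominant arms mapped to
#' unaffected/affected.  A zero affected-side value makes the corresponding
#' ratio missing (logged), and missingness propagates.
#'
#' @param indices data.frame with columns \code{subject_id}, \code{group},
#'   \code{age}, \code{days_post_stroke}, \code{fmul}, \code{mvc_af},
#'   \code{mvc_un} and per-arm index columns \code{li_pmc_af}, \code{li_pmc_un},
#'   \code{li_m1_af}, \code{li_m1_un}, \code{li_s1_af}, \code{li_s1_un},
#'   \code{ssi_af}, \code{ssi_un}, \code{c_v_af}, \code{c_v_un}, \code{c_t_af},
#'   \code{c_t_un}.
#' @param ratio_direction ratio convention; the default follows the explicit
#'   definition "unaffected over affected".
#' @return data.frame of class \code{"feature_table"} with \code{subject_id},
#'   \code{group}, the 21 predictors and the response \code{FMul}; attribute
#'   \code{"ratio_log"} records ratios that were dropped.
#' @export
build_feature_table <- function(indices,
                                ratio_direction = c("unaffected_over_affected",
                                                    "affected_over_unaffected")) {
  ratio_direction <- match.arg(ratio_direction)
  req <- c("subject_id", "group", "age", "days_post_stroke", "fmul",
           "mvc_af", "mvc_un",
           "li_pmc_af", "li_pmc_un", "li_m1_af", "li_m1_un",
           "li_s1_af", "li_s1_un", "ssi_af", "ssi_un",
           "c_v_af", "c_v_un", "c_t_af", "c_t_un")
  miss <- setdiff(req, names(indices))
  if (length(miss))
    stop_strokesyn(paste("missing index columns:", paste(miss, collapse = ", ")),
                   "strokesyn_feature_error")
  log <- character(0)
  safe_ratio <- function(un, af, name) {
    num <- if (ratio_direction == "unaffected_over_affected") un else af
    den <- if (ratio_direction == "unaffected_over_affected") af else un
    bad <- !is.na(den) & den == 0
    if (any(bad))
      log <<- c(log, sprintf("%s: zero denominator for subject(s) %s", name,
                             paste(indices$subject_id[bad], collapse = ", ")))
    out <- num / den
    out[bad] <- NA_real_
    out
  }
  days <- ifelse(indices$group == "control", 0, indices$days_post_stroke)
  tab <- data.frame(
    subject_id = indices$subject_id, group = indices$group,
    LI_PMC_af = indices$li_pmc_af, LI_M1_af = indices$li_m1_af,
    LI_S1_af = indices$li_s1_af,
    LI_PMC_un = indices$li_pmc_un, LI_M1_un = indices$li_m1_un,
    LI_S1_un = indices$li_s1_un,
    SSI_af = indices$ssi_af, SSI_un = indices$ssi_un,
    C_V_af = indices$c_v_af, C_V_un = indices$c_v_un,
    C_T_af = indices$c_t_af, C_T_un = indices$c_t_un,
    LI_PMC_r = safe_ratio(indices$li_pmc_un, indices$li_pmc_af, "LI_PMC_r"),
    LI_M1_r = safe_ratio(indices$li_m1_un, indices$li_m1_af, "LI_M1_r"),
    LI_S1_r = safe_ratio(indices$li_s1_un, indices$li_s1_af, "LI_S1_r"),
    SSI_r = safe_ratio(indices$ssi_un, indices$ssi_af, "SSI_r"),
    C_V_r = safe_ratio(indices$c_v_un, indices$c_v_af, "C_V_r"),
    C_T_r = safe_ratio(indices$c_t_un, indices$c_t_af, "C_T_r"),
    age = indices$age, days_post_stroke = days,
    F_r = safe_ratio(indices$mvc_un, indices$mvc_af, "F_r"),
    FMul = indices$fmul, stringsAsFactors = FALSE)
  attr(tab, "ratio_log") <- log
  class(tab) <- c("feature_table", "data.frame")
  tab
}

# internal: OLS summary pieces for a predictor subset on complete rows
ols_stats <- function(X, y) {
  n <- length(y); k <- ncol(X)
  fit <- lm.fit(cbind(`(Intercept)` = 1, X), y)
  res <- fit$residuals
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
  list(fit = fit, rss = rss, r2 = r2, r2_adj = r2_adj, n = n, k = k)
}

#' Fit a linear model of FMul on a named predictor subset
#'
#' Ordinary least squares with coefficient t-tests, overall F-test,
#' standardized coefficients \code{beta_j = B_j * sd(x_j) / sd(y)} and
#' adjusted R^2; handles 1 to 4 (or more) predictors.  Fitted on rows with
#' complete data for the chosen columns (listwise deletion).
#'
#' @param table \code{feature_table} (or compatible data.frame with an
#'   \code{FMul} column).
#' @param predictors character vector of predictor column names.
#' @param rows optional logical/integer row filter applied before fitting
#'   (default: patient rows when a \code{group} column exists, else all).
#' @return object of class \code{"fmul_lm"}; see \code{\link{fmul_lm}}.
#' @export
fit_linear_model <- function(table, predictors, rows = NULL) {
  if (is.null(rows)) rows <- if ("group" %in% names(table)) table$group == "patient" else TRUE
  dat <- table[rows, , drop = FALSE]
  cols <- c(predictors, "FMul")
  dat <- dat[stats::complete.cases(dat[, cols, drop = FALSE]), , drop = FALSE]
  n <- nrow(dat); k <- length(predictors)
  if (n < k + 2L)
    stop_strokesyn("too few complete rows for the requested model",
                   "strokesyn_regression_error")
  X <- as.matrix(dat[, predictors, drop = FALSE])
  y <- dat$FMul
  if (k > 1L && kappa(cbind(1, scale(X, scale = FALSE)), exact = TRUE) > 1e10)
    stop_strokesyn("collinear predictors (condition number > 1e10)",
                   "strokesyn_regression_error")
  st <- ols_stats(X, y)
  B <- st$fit$coefficients
  dfree <- n - k - 1L
  XtXinv <- chol2inv(chol(crossprod(cbind(1, X))))
  se <- sqrt(diag(XtXinv) * st$rss / dfree)
  tstat <- B / se
  p_coef <- 2 * pt(abs(tstat), dfree, lower.tail = FALSE)
  f_stat <- (st$r2 / k) / ((1 - st$r2) / dfree)
  p_model <- pf(f_stat, k, dfree, lower.tail = FALSE)
  beta_std <- B[-1L] * apply(X, 2L, sd) / sd(y)
  structure(list(selected = predictors, B = B, se = se,
                 beta_std = beta_std, p_coef = p_coef[-1L],
                 p_intercept = p_coef[1L],
                 f_stat = f_stat, p_model = p_model,
                 r2 = st$r2, r2_adj = st$r2_adj, n = n, k = k,
                 fitted_rows = dat$subject_id, data = dat,
                 residuals = st$fit$residuals,
                 fitted_values = y - st$fit$residuals),
            class = "fmul_lm")
}

#' Exhaustive best-subset search over the 21 predictors
#'
#' Enumerates every subset of size \code{subset_size} of the 21 predictor
#' columns in deterministic lexicographic order (\code{utils::combn}), fits
#' OLS on complete patient rows, and returns the model with maximum adjusted
#' R^2 (ties resolved by enumeration order).
#'
#' @param table \code{feature_table}.
#' @param subset_size predictors per model (4 gives C(21,4) = 5985 fits).
#' @param predictors candidate predictor names (defaults to all 21).
#' @param rows optional row filter; default patient rows.
#' @return \code{fmul_lm} for the winning subset, with attributes
#'   \code{n_models} (number of subsets evaluated) and \code{search}
#'   (data.frame of every subset's adjusted R^2).
#' @export
exhaustive_subset_search <- function(table, subset_size = 4L,
                                     predictors = FEATURE_PREDICTORS,
                                     rows = NULL) {
  if (is.null(rows)) rows <- if ("group" %in% names(table)) table$group == "patient" else TRUE
  dat <- table[rows, , drop = FALSE]
  dat <- dat[stats::complete.cases(dat[, c(predictors, "FMul"), drop = FALSE]), , drop = FALSE]
  if (nrow(dat) < subset_size + 2L)
    stop_strokesyn("too few complete rows for the subset search",
                   "strokesyn_regression_error")
  y <- dat$FMul
  Xall <- as.matrix(dat[, predictors, drop = FALSE])
  n <- nrow(dat)
  combs <- combn(length(predictors), subset_size)
  adj <- numeric(ncol(combs))
  tss <- sum((y - mean(y))^2)
  for (j in seq_len(ncol(combs))) {
    X <- cbind(1, Xall[, combs[, j], drop = FALSE])
    rss <- sum(.lm.fit(X, y)$residuals^2)
    r2 <- 1 - rss / tss
    adj[j] <- 1 - (1 - r2) * (n - 1) / (n - subset_size - 1)
  }
  best <- which.max(adj)       # first maximum in enumeration order
  winner <- predictors[combs[, best]]
  model <- fit_linear_model(table, winner, rows = rows)
  attr(model, "n_models") <- ncol(combs)
  attr(model, "search") <- data.frame(
    subset = apply(combs, 2L, function(ix) paste(predictors[ix], collapse = "+")),
    r2_adj = adj, stringsAsFactors = FALSE)
  model
}

#' Best-subset FMul model
#'
#' The package's main fitting function: assembles nothing itself, but runs
#' the exhaustive \code{subset_size}-predictor search of
#' \code{\link{exhaustive_subset_search}} on a feature table and returns the
#' winning ordinary-least-squares model as a classed object with the usual
#' accessor methods (\code{print}, \code{summary}, \code{coef},
#' \code{predict}, \code{fitted}, \code{residuals}, \code{plot}).
#'
#' @inheritParams exhaustive_subset_search
#' @return object of class \code{"fmul_lm"}.
#' @examples
#' \donttest{
#' cfg <- simulation_config(n_patients = 12, n_controls = 6, seed = 1)
#' coh <- generate_cohort(cfg)
#' tab <- build_feature_table(true_indices_table(coh))
#' m <- fmul_lm(tab)
#' summary(m)
#' }
#' @export
fmul_lm <- function(table, subset_size = 4L, predictors = FEATURE_PREDICTORS,
                    rows = NULL) {
  exhaustive_subset_search(table, subset_size = subset_size,
                           predictors = predictors, rows = rows)
}

#' @export
coef.fmul_lm <- function(object, ...) object$B

#' @export
fitted.fmul_lm <- function(object, ...) object$fitted_values

#' @export
residuals.fmul_lm <- function(object, ...) object$residuals

#' Predict FMul scores for new rows
#'
#' Applies the fitted linear form to any rows of a feature table (patients or
#' controls) and reports how many predictions exceed \code{threshold} --
#' fitted scores above 60 are read as healthy-like performance.
#'
#' @param object \code{fmul_lm}.
#' @param newdata feature table rows (defaults to the fitting data).
#' @param threshold count cut-off for healthy-like fitted scores.
#' @param ... unused.
#' @return list with \code{fitted} (named by subject where available) and
#'   \code{n_above} (count of predictions > threshold, NAs dropped).
#' @export
predict.fmul_lm <- function(object, newdata = NULL, threshold = 60, ...) {
  dat <- if (is.null(newdata)) object$data else newdata
  X <- as.matrix(dat[, object$selected, drop = FALSE])
  yhat <- drop(cbind(1, X) %*% object$B)
  if ("subject_id" %in% names(dat)) names(yhat) <- dat$subject_id
  list(fitted = yhat, n_above = sum(yhat > threshold, na.rm = TRUE))
}

#' @export
print.fmul_lm <- function(x, ...) {
  cat("Best-subset linear model of FMul\n")
  cat("  predictors:", paste(x$selected, collapse = ", "), "\n")
  cat(sprintf("  adjusted R^2 = %.3f, F = %.2f, model p = %s (n = %d)\n",
              x$r2_adj, x$f_stat, format.pval(x$p_model, digits = 3), x$n))
  if (!is.null(attr(x, "n_models")))
    cat(sprintf("  selected from %d candidate models\n", attr(x, "n_models")))
  invisible(x)
}

#' @export
summary.fmul_lm <- function(object, ...) {
  tab <- data.frame(term = names(object$B),
                    B = unname(object$B),
                    beta_std = c(NA, unname(object$beta_std)),
                    p_value = c(object$p_intercept, unname(object$p_coef)))
  out <- list(coefficients = tab, r2 = object$r2, r2_adj = object$r2_adj,
              f_stat = object$f_stat, p_model = object$p_model, n = object$n)
  class(out) <- "summary.fmul_lm"
  out
}

#' @export
print.summary.fmul_lm <- function(x, ...) {
  cat("Best-subset linear model of FMul\n")
  tab <- x$coefficients
  tab$B <- round(tab$B, 3); tab$beta_std <- round(tab$beta_std, 3)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("R^2 = %.3f, adjusted R^2 = %.3f, F = %.2f, p = %s, n = %d\n",
              x$r2, x$r2_adj, x$f_stat, format.pval(x$p_model, digits = 3), x$n))
  invisible(x)
}

#' @export
plot.fmul_lm <- function(x, newdata = NULL, ...) {
  pr <- predict(x, newdata = newdata)
  dat <- if (is.null(newdata)) x$data else newdata
  plot(dat$FMul, pr$fitted, xlab = "observed FMul", ylab = "fitted FMul",
       main = "FMul: fitted vs observed", ...)
  abline(0, 1, lty = 2)
  invisible(pr)
}
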