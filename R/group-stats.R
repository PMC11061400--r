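# Assumption-gated group comparisons: Shapiro-Wilk normality per sample plus
# Levene homoscedasticity across samples decide between parametric (t-tests,
# two-way ANOVA) and nonparametric tests (Mann-Whitney U, Wilcoxon
# signed-rank, Scheirer-Ray-Hare).  The Scheirer-Ray-Hare rank test is
# implemented here in full.

#' Assumption gate for parametric testing
#'
#' Parametric analysis is allowed only when every sample passes Shapiro-Wilk
#' normality at \code{alpha} and Levene's test across the samples passes at
#' \code{alpha}.  Samples with fewer than 3 observations force the
#' nonparametric branch (Shapiro-Wilk is undefined below n = 3).
#'
#' @param samples list of numeric vectors.
#' @param alpha significance level for both gate tests.
#' @return list with \code{parametric} (logical), \code{shapiro_p} (per
#'   sample), \code{levene_p}, \code{forced} (TRUE when small samples forced
#'   the decision).
#' @export
assumption_gate <- function(samples, alpha = 0.05) {
  stopifnot(is.list(samples), length(samples) >= 1L)
  ns <- lengths(samples)
  if (any(ns < 3L)) {
    return(list(parametric = FALSE, shapiro_p = rep(NA_real_, length(samples)),
                levene_p = NA_real_, forced = TRUE))
  }
  shapiro_p <- vapply(samples, function(x) {
    if (length(unique(x)) == 1L) return(0)   # degenerate: certainly non-normal
    shapiro.test(x)$p.value
  }, numeric(1))
  levene_p <- if (length(samples) >= 2L) {
    values <- unlist(samples)
    grp <- factor(rep(seq_along(samples), ns))
    car::leveneTest(values, grp)[1L, "Pr(>F)"]
  } else 1
  list(parametric = all(shapiro_p > alpha) && levene_p > alpha,
       shapiro_p = shapiro_p, levene_p = levene_p, forced = FALSE)
}

#' Two-sample comparison with assumption gating
#'
#' Dispatches an independent/paired t-test when the assumption gate passes
#' and a Mann-Whitney U / Wilcoxon signed-rank test otherwise; always
#' two-tailed.
#'
#' @param a,b numeric samples (equal length when \code{paired}).
#' @param paired paired comparison flag.
#' @param alpha gate significance level.
#' @return list of class \code{"comparison_result"}: \code{test_name},
#'   \code{statistic}, \code{p_value}, \code{gate}.
#' @export
compare_two_samples <- function(a, b, paired = FALSE, alpha = 0.05) {
  if (length(a) == 0L || length(b) == 0L)
    stop_strokesyn("empty sample", "strokesyn_stats_error")
  if (paired && length(a) != length(b))
    stop_strokesyn("paired comparison requires equal lengths", "strokesyn_stats_error")
  gate_input <- if (paired) list(a - b) else list(a, b)
  gate <- assumption_gate(gate_input, alpha = alpha)
  degenerate <- paired && all(a == b)
  if (gate$parametric && !degenerate) {
    ht <- t.test(a, b, paired = paired, var.equal = !paired)
    name <- if (paired) "paired t-test" else "independent t-test"
  } else if (degenerate) {
    return(structure(list(test_name = if (paired) "wilcoxon signed-rank" else "mann-whitney U",
                          statistic = NA_real_, p_value = NA_real_, gate = gate,
                          note = "all paired differences are zero"),
                     class = "comparison_result"))
  } else {
    ht <- suppressWarnings(wilcox.test(a, b, paired = paired, exact = FALSE))
    name <- if (paired) "wilcoxon signed-rank" else "mann-whitney U"
  }
  structure(list(test_name = name, statistic = unname(ht$statistic),
                 p_value = ht$p.value, gate = gate),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, p = %s\n", x$test_name,
              if (is.na(x$statistic)) "NA" else format(x$statistic, digits = 4),
              if (is.na(x$p_value)) "NA (degenerate)" else format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' Scheirer-Ray-Hare test
#'
#' Rank-based nonparametric analogue of the two-way ANOVA.  All N
#' observations are ranked jointly (mid-ranks on ties); two-way sums of
#' squares are computed on the ranks; each effect's statistic is
#' \code{H = SS_effect / MS_total} with \code{MS_total = SS_total / (N - 1)}
#' (the variance of the ranks), referred to a chi-square distribution at the
#' effect's degrees of freedom.  Mid-ranks already deflate \code{MS_total}
#' under ties, so no additional tie correction is applied.
#'
#' @param values numeric response.
#' @param factor_a,factor_b crossed factors (e.g. group and arm), each with
#'   at least two levels and at least one observation per cell.
#' @return object of class \code{"srh_test"}: data.frame \code{table} with
#'   rows for factor A, factor B and the interaction (columns \code{df},
#'   \code{SS}, \code{H}, \code{p_value}) plus \code{ms_total} and
#'   \code{degenerate} (TRUE when all observations are equal; H is then 0).
#' @export
scheirer_ray_hare <- function(values, factor_a, factor_b) {
  factor_a <- droplevels(as.factor(factor_a))
  factor_b <- droplevels(as.factor(factor_b))
  stopifnot(length(values) == length(factor_a), length(values) == length(factor_b))
  if (nlevels(factor_a) < 2L || nlevels(factor_b) < 2L)
    stop_strokesyn("both factors need at least two levels", "strokesyn_stats_error")
  if (any(table(factor_a, factor_b) == 0L))
    stop_strokesyn("empty cell in the two-way layout", "strokesyn_stats_error")
  N <- length(values)
  r <- rank(values)                     # mid-ranks under ties
  rbar <- mean(r)
  ss_total <- sum((r - rbar)^2)
  degenerate <- ss_total == 0
  ma <- tapply(r, factor_a, mean); na <- table(factor_a)
  mb <- tapply(r, factor_b, mean); nb <- table(factor_b)
  mc <- tapply(r, interaction(factor_a, factor_b, drop = TRUE), mean)
  nc <- table(interaction(factor_a, factor_b, drop = TRUE))
  ss_a <- sum(na * (ma - rbar)^2)
  ss_b <- sum(nb * (mb - rbar)^2)
  ss_cells <- sum(nc * (mc - rbar)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  df_a <- nlevels(factor_a) - 1L
  df_b <- nlevels(factor_b) - 1L
  df_ab <- df_a * df_b
  ms_total <- if (degenerate) NA_real_ else ss_total / (N - 1)
  H <- if (degenerate) c(0, 0, 0) else c(ss_a, ss_b, ss_ab) / ms_total
  p <- pchisq(H, df = c(df_a, df_b, df_ab), lower.tail = FALSE)
  if (degenerate) p <- rep(1, 3)
  tab <- data.frame(effect = c("factor_a", "factor_b", "interaction"),
                    df = c(df_a, df_b, df_ab), SS = c(ss_a, ss_b, ss_ab),
                    H = H, p_value = p, stringsAsFactors = FALSE)
  structure(list(table = tab, ms_total = ms_total, degenerate = degenerate,
                 n = N), class = "srh_test")
}

#' @export
print.srh_test <- function(x, ...) {
  cat(sprintf("Scheirer-Ray-Hare test (N = %d)%s\n", x$n,
              if (x$degenerate) " -- degenerate: all observations equal" else ""))
  tab <- x$table
  tab$H <- round(tab$H, 4); tab$SS <- round(tab$SS, 3)
  tab$p_value <- signif(tab$p_value, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}
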