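# End-to-end orchestration: sEMG preprocessing and per-lift synergy
# decomposition, synergy-count selection, control baselines, per-subject-arm
# indices, fNIRS beta maps and laterality indices, the feature table, group
# statistics and (when enough patients are available) the best-subset FMul
# regression.

#' Load the packaged patient characteristics table
#'
#' Demographic and clinical characteristics of the 15 stroke patients
#' (age, sex, lesion side, stroke type, days after stroke, FMul, FMarm,
#' Brunnstrom stage), shipped as a plain-text fixture.
#'
#' @return data.frame with one row per patient.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_patients.csv", package = "strokesyn")
  tab <- read.csv(path, stringsAsFactors = FALSE, colClasses = c(Patient = "character"))
  bad <- !tab$BS %in% c("I", "II", "III", "IV", "V", "VI")
  if (any(bad))
    stop_strokesyn(sprintf("malformed Brunnstrom stage '%s'", tab$BS[bad][1L]),
                   "strokesyn_io_error")
  tab
}

#' Demographic summary of a subject table
#'
#' Mean and sample (n-1) standard deviation of age, plus sex counts.
#'
#' @param table data.frame with \code{Age} and \code{Sex} columns.
#' @return list with \code{n}, \code{age_mean}, \code{age_sd} (NA, flagged,
#'   for single-row tables), \code{sex_counts}.
#' @export
table1_summary <- function(table) {
  n <- nrow(table)
  list(n = n,
       age_mean = mean(table$Age),
       age_sd = if (n >= 2L) sd(table$Age) else NA_real_,
       sd_defined = n >= 2L,
       sex_counts = table(table$Sex))
}

# internal: lift-level synergy fits for one subject-arm; returns per-lift
# n = 1 models plus the VAF curve over n = 1..n_max.  The count-selection
# scan only needs VAF to ~1e-3, so it runs at a looser tolerance than the
# n = 1 fits used for the indices.
fit_arm_synergies <- function(lifts, n_max = 5L) {
  models <- lapply(lifts, function(l) mcr_als(l$X, n = 1L))
  vaf_curve <- if (length(lifts) == 0L) rep(NA_real_, n_max) else {
    vapply(seq_len(n_max), function(n) {
      if (n == 1L) return(mean(vapply(models, function(m) m$vaf, numeric(1))))
      mean(vapply(lifts, function(l) mcr_als(l$X, n = n, tol = 1e-4,
                                             max_iter = 30L)$vaf, numeric(1)))
    }, numeric(1))
  }
  list(models = models, vaf_curve = vaf_curve)
}

#' Run the full analysis pipeline
#'
#' Accepts either a dataset directory (see \code{\link{read_dataset}}) or an
#' in-memory cohort plus sessions.  Stages: sEMG preprocessing and per-lift
#' MCR-ALS, synergy-count selection across groups, control baseline
#' synergies per hand, SSI/C_V/C_T per subject-arm, fNIRS preprocessing to
#' GLM betas, lesion-orientation normalization and laterality indices,
#' feature-table assembly, group statistics (assumption-gated pairwise tests
#' and Scheirer-Ray-Hare for group x arm), and the exhaustive best-subset
#' FMul regression when at least \code{min_regression_rows} complete patient
#' rows exist.
#'
#' @param data dataset path, or list with \code{subjects} and \code{sessions}.
#' @param region_map channel map for the fNIRS stage.
#' @param skip_fnirs when TRUE the fNIRS stage is skipped; LI columns are
#'   absent and the regression uses the remaining predictors.
#' @param subset_size predictors in the regression search.
#' @param min_regression_rows minimum complete patient rows to attempt the
#'   regression.
#' @param n_max largest synergy count scanned for the VAF criterion.
#' @return list of class \code{"strokesyn_results"}: \code{indices} (per
#'   subject-arm index table), \code{features}, \code{synergy_count},
#'   \code{baselines}, \code{stats}, \code{regression} (NULL when skipped),
#'   \code{log}.
#' @export
run_pipeline <- function(data, region_map = default_region_map(),
                         skip_fnirs = FALSE, subset_size = 4L,
                         min_regression_rows = 8L, n_max = 5L) {
  if (is.character(data)) data <- read_dataset(data)
  subjects <- data$subjects
  sessions <- data$sessions
  log <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_strokesyn(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                     "strokesyn_pipeline_error")
    })
  }

  # --- sEMG: preprocessing + per-lift synergies ------------------------------
  syn <- list()
  for (id in subjects$subject_id) {
    syn[[id]] <- list()
    for (arm in c("affected", "unaffected")) {
      es <- sessions[[id]]$emg[[arm]]
      if (is.null(es)) next
      pre <- stage("semg_preprocess", semg_preprocess(es))
      fits <- stage("muscle_synergy", fit_arm_synergies(pre$lifts, n_max = n_max))
      syn[[id]][[arm]] <- list(pre = pre, fits = fits,
                               mvc = mean(es$mvc_trials))
    }
  }

  # --- synergy count criterion ----------------------------------------------
  have_syn <- names(syn)[vapply(syn, length, integer(1)) > 0]
  vaf_mat <- t(vapply(have_syn, function(id) {
    curves <- lapply(syn[[id]], function(a) a$fits$vaf_curve)
    colMeans(do.call(rbind, curves), na.rm = TRUE)
  }, numeric(n_max)))
  rownames(vaf_mat) <- have_syn
  grp <- subjects$group[match(have_syn, subjects$subject_id)]
  count_sel <- stage("select_synergy_count", select_synergy_count(vaf_mat, grp))

  # --- baselines from controls (affected label = non-dominant hand) ---------
  controls <- subjects$subject_id[subjects$group == "control"]
  baseline_of <- function(arm, hand) {
    models <- lapply(controls, function(id) {
      a <- syn[[id]][[arm]]
      if (is.null(a)) list() else a$fits$models
    })
    names(models) <- controls
    stage("compute_baseline", compute_baseline(models, hand = hand))
  }
  baselines <- list(
    dominant = baseline_of("unaffected", "dominant"),
    nondominant = baseline_of("affected", "non-dominant"))

  # --- per subject-arm indices ----------------------------------------------
  rows <- list()
  for (id in subjects$subject_id) {
    si <- subjects[subjects$subject_id == id, ]
    rec <- list(subject_id = id, group = si$group, age = si$age,
                days_post_stroke = si$days_post_stroke, fmul = si$fmul_true)
    for (arm in c("affected", "unaffected")) {
      sfx <- if (arm == "affected") "af" else "un"
      a <- syn[[id]][[arm]]
      base <- if (arm == "affected") baselines$nondominant else baselines$dominant
      if (!is.null(a) && length(a$fits$models) > 0) {
        V_list <- lapply(a$fits$models, function(m) m$V[, 1L])
        T_list <- lapply(a$fits$models, function(m) m$T[1L, ])
        idx <- stage("synergy_indices",
                     aggregate_indices(V_list, T_list, base, arm = arm))
        rec[[paste0("ssi_", sfx)]] <- idx$ssi
        rec[[paste0("c_v_", sfx)]] <- idx$c_v
        rec[[paste0("c_t_", sfx)]] <- idx$c_t
        rec[[paste0("mvc_", sfx)]] <- a$mvc
        rec[[paste0("lifts_", sfx)]] <- idx$lifts_used
      } else {
        for (v in c("ssi_", "c_v_", "c_t_", "mvc_"))
          rec[[paste0(v, sfx)]] <- NA_real_
        rec[[paste0("lifts_", sfx)]] <- 0L
      }
      if (!skip_fnirs && !is.null(sessions[[id]]$fnirs[[arm]])) {
        fp <- stage("fnirs_pipeline", fnirs_pipeline(sessions[[id]]$fnirs[[arm]]))
        flip <- needs_flip(si$lesion_side,
                           if (is.na(si$dominant_hand)) "right" else si$dominant_hand)
        beta <- normalize_lesion_orientation(
          fp$beta_map$beta, if (flip) "left" else "none", region_map)
        li <- stage("laterality", laterality_index(beta, region_map, moving_arm = arm))
        rec[[paste0("li_pmc_", sfx)]] <- li$li[["PMC"]]
        rec[[paste0("li_m1_", sfx)]] <- li$li[["M1"]]
        rec[[paste0("li_s1_", sfx)]] <- li$li[["S1"]]
      } else {
        rec[[paste0("li_pmc_", sfx)]] <- NA_real_
        rec[[paste0("li_m1_", sfx)]] <- NA_real_
        rec[[paste0("li_s1_", sfx)]] <- NA_real_
      }
    }
    rows[[id]] <- as.data.frame(rec, stringsAsFactors = FALSE)
  }
  indices <- do.call(rbind, rows)
  rownames(indices) <- NULL

  # --- feature table ---------------------------------------------------------
  features <- stage("feature_table", build_feature_table(indices))
  if (skip_fnirs) {
    li_cols <- grep("^LI_", names(features), value = TRUE)
    features <- features[, setdiff(names(features), li_cols)]
    log <- c(log, "fNIRS stage skipped: LI columns absent")
  }

  # --- group statistics ------------------------------------------------------
  stats <- list()
  idx_names <- c("ssi", "c_v", "c_t",
                 if (!skip_fnirs) c("li_pmc", "li_m1", "li_s1"))
  pat <- indices$group == "patient"; ctl <- indices$group == "control"
  for (nm in idx_names) {
    af <- indices[[paste0(nm, "_af")]]; un <- indices[[paste0(nm, "_un")]]
    long <- data.frame(value = c(af, un),
                       group = rep(indices$group, 2L),
                       arm = rep(c("affected", "unaffected"), each = nrow(indices)))
    long <- long[!is.na(long$value), ]
    res <- list()
    if (all(table(long$group, long$arm) > 0) && nrow(long) >= 8L)
      res$srh <- stage("scheirer_ray_hare",
                       scheirer_ray_hare(long$value, long$group, long$arm))
    ok <- function(x) sum(!is.na(x)) >= 3
    if (ok(af[pat]) && ok(af[ctl]))
      res$patient_vs_control_af <- compare_two_samples(af[pat], af[ctl])
    if (ok(af[pat]) && ok(un[pat])) {
      cc <- !is.na(af[pat]) & !is.na(un[pat])
      res$affected_vs_unaffected <- compare_two_samples(af[pat][cc], un[pat][cc],
                                                        paired = TRUE)
    }
    stats[[nm]] <- res
  }

  # --- regression ------------------------------------------------------------
  regression <- NULL
  preds <- intersect(FEATURE_PREDICTORS, names(features))
  complete_pat <- sum(stats::complete.cases(
    features[features$group == "patient", c(preds, "FMul"), drop = FALSE]))
  if (complete_pat >= max(min_regression_rows, subset_size + 2L)) {
    regression <- stage("fmul_regression",
                        fmul_lm(features, subset_size = subset_size, predictors = preds))
  } else {
    log <- c(log, sprintf("regression skipped: only %d complete patient rows",
                          complete_pat))
  }

  structure(list(indices = indices, features = features,
                 synergy_count = count_sel, baselines = baselines,
                 stats = stats, regression = regression, log = log),
            class = "strokesyn_results")
}

#' @export
print.strokesyn_results <- function(x, ...) {
  cat(sprintf("pipeline results: %d subjects, synergy count n = %d\n",
              nrow(x$indices), x$synergy_count$n))
  if (!is.null(x$regression)) print(x$regression)
  if (length(x$log)) cat("log:", paste(x$log, collapse = "; "), "\n")
  invisible(x)
}

#' Write a results bundle to disk
#'
#' CSV for the index and feature tables, JSON for statistics, regression and
#' the run log.
#'
#' @param results \code{strokesyn_results}.
#' @param path output directory.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(results, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_csv_exact(results$indices, file.path(path, "indices.csv"))
  write_csv_exact(as.data.frame(results$features), file.path(path, "features.csv"))
  summ <- list(
    synergy_count = results$synergy_count,
    stats = lapply(results$stats, function(s) lapply(s, function(r) {
      if (inherits(r, "srh_test")) r$table else
        r[c("test_name", "statistic", "p_value")]
    })),
    regression = if (!is.null(results$regression)) {
      m <- results$regression
      list(selected = m$selected, B = as.list(m$B), beta_std = as.list(m$beta_std),
           p_coef = as.list(m$p_coef), p_model = m$p_model, r2_adj = m$r2_adj)
    },
    log = results$log)
  writeLines(jsonlite::toJSON(summ, auto_unbox = TRUE, digits = NA, null = "null"),
             file.path(path, "results.json"))
  invisible(path)
}
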