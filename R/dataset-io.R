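# Dataset directory layout: subjects.csv at the root; one directory per
# subject with emg_<arm>.csv (time_s + five muscle columns), force_<arm>.csv,
# fnirs_<arm>.csv (time_s, ch01_w830 ... ch24_w704), events_<arm>.csv (shared
# by both modalities: the fNIRS recording covers the full block timeline
# including the MVC preamble), manifest.yaml and ground_truth.json.

# internal: write a data.frame as CSV with full double precision (%.17g
# round-trips IEEE doubles exactly)
write_csv_exact <- function(df, path) {
  for (cn in names(df))
    if (is.double(df[[cn]])) df[[cn]] <- sprintf("%.17g", df[[cn]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Simulate sessions for every subject and arm
#'
#' @param cohort \code{cohort}.
#' @param modalities which modalities to simulate.
#' @return nested list \code{sessions[[subject_id]][[modality]][[arm]]}.
#' @export
simulate_sessions <- function(cohort, modalities = c("emg", "fnirs")) {
  out <- list()
  for (id in cohort$subjects$subject_id) {
    out[[id]] <- list()
    for (mod in modalities) {
      out[[id]][[mod]] <- list()
      for (arm in c("affected", "unaffected")) {
        out[[id]][[mod]][[arm]] <- if (mod == "emg")
          simulate_emg_session(cohort, id, arm)
        else simulate_fnirs_session(cohort, id, arm)
      }
    }
  }
  out
}

#' Write a synthetic dataset to disk
#'
#' @param cohort \code{cohort}.
#' @param sessions nested session list from \code{\link{simulate_sessions}}.
#' @param path target directory (created if needed).
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(cohort, sessions, path) {
  ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path))
    stop_strokesyn(sprintf("cannot create dataset directory '%s'", path),
                   "strokesyn_io_error")
  write_csv_exact(cohort$subjects, file.path(path, "subjects.csv"))
  manifest <- list(seed = cohort$config$seed,
                   emg_fs = cohort$config$emg_fs,
                   force_fs = cohort$config$force_fs,
                   fnirs_fs = cohort$config$fnirs_fs,
                   muscles = cohort$config$muscles,
                   subjects = list())
  for (id in names(sessions)) {
    sd <- file.path(path, id)
    dir.create(sd, showWarnings = FALSE)
    man_s <- list()
    for (arm in c("affected", "unaffected")) {
      es <- sessions[[id]]$emg[[arm]]
      if (!is.null(es)) {
        emg_df <- data.frame(time_s = (seq_len(ncol(es$emg)) - 1) / es$emg_fs,
                             t(es$emg))
        names(emg_df) <- c("time_s", es$muscle_names)
        write_csv_exact(emg_df, file.path(sd, sprintf("emg_%s.csv", arm)))
        write_csv_exact(data.frame(time_s = (seq_along(es$force) - 1) / es$force_fs,
                                   newtons = es$force),
                        file.path(sd, sprintf("force_%s.csv", arm)))
        write_csv_exact(es$events, file.path(sd, sprintf("events_%s.csv", arm)))
        man_s[[arm]] <- list(mvc_trials = es$mvc_trials,
                             target_force = es$target_force)
      }
      fs_ <- sessions[[id]]$fnirs[[arm]]
      if (!is.null(fs_)) {
        d <- dim(fs_$intensity)
        cols <- list(time_s = (seq_len(d[3]) - 1) / fs_$fs)
        for (ch in seq_len(d[1])) for (w in 1:2) {
          nm <- sprintf("ch%02d_w%d", ch, fs_$wavelengths[w])
          cols[[nm]] <- fs_$intensity[ch, w, ]
        }
        write_csv_exact(as.data.frame(cols), file.path(sd, sprintf("fnirs_%s.csv", arm)))
      }
    }
    manifest$subjects[[id]] <- man_s
  }
  yaml::write_yaml(manifest, file.path(path, "manifest.yaml"), precision = 17)
  truth_json <- jsonlite::toJSON(cohort$truth, auto_unbox = TRUE, digits = NA)
  writeLines(truth_json, file.path(path, "ground_truth.json"))
  invisible(path)
}

#' Read a dataset directory
#'
#' Parses the layout written by \code{\link{write_dataset}}, validating
#' presence of required files, sampling-rate consistency and channel counts.
#'
#' @param path dataset directory.
#' @return list with \code{subjects} (data.frame), \code{sessions} (nested
#'   list of \code{emg_session} / \code{fnirs_session}), \code{manifest}.
#' @export
read_dataset <- function(path) {
  sub_path <- file.path(path, "subjects.csv")
  if (!file.exists(sub_path))
    stop_strokesyn(sprintf("missing subjects.csv in '%s'", path), "strokesyn_io_error")
  subjects <- read.csv(sub_path, stringsAsFactors = FALSE)
  manifest <- yaml::read_yaml(file.path(path, "manifest.yaml"))
  muscles <- unlist(manifest$muscles)
  sessions <- list()
  for (id in subjects$subject_id) {
    sd <- file.path(path, id)
    sessions[[id]] <- list(emg = list(), fnirs = list())
    for (arm in c("affected", "unaffected")) {
      ef <- file.path(sd, sprintf("emg_%s.csv", arm))
      ff <- file.path(sd, sprintf("force_%s.csv", arm))
      vf <- file.path(sd, sprintf("events_%s.csv", arm))
      nf <- file.path(sd, sprintf("fnirs_%s.csv", arm))
      if (file.exists(ef)) {
        if (!file.exists(ff))
          stop_strokesyn(sprintf("missing force file '%s'", ff), "strokesyn_io_error")
        if (!file.exists(vf))
          stop_strokesyn(sprintf("missing events file '%s'", vf), "strokesyn_io_error")
        emg_df <- read.csv(ef)
        if (!all(muscles %in% names(emg_df)))
          stop_strokesyn(sprintf("'%s': missing muscle columns", ef), "strokesyn_io_error")
        force_df <- read.csv(ff)
        events <- read.csv(vf, stringsAsFactors = FALSE)
        man <- manifest$subjects[[id]][[arm]]
        emg <- t(as.matrix(emg_df[, muscles]))
        rownames(emg) <- muscles
        sessions[[id]]$emg[[arm]] <- emg_session(
          emg = emg, emg_fs = manifest$emg_fs,
          force = force_df$newtons, force_fs = manifest$force_fs,
          muscle_names = muscles, mvc_trials = unlist(man$mvc_trials),
          events = events, target_force = man$target_force)
      }
      if (file.exists(nf)) {
        fn_df <- read.csv(nf)
        chcols <- grep("^ch[0-9]+_w[0-9]+$", names(fn_df), value = TRUE)
        nch <- length(chcols) / 2L
        if (nch != 24L)
          stop_strokesyn(sprintf("'%s': expected 24 channels, found %g", nf, nch),
                         "strokesyn_io_error")
        ns <- nrow(fn_df)
        wl <- sort(unique(as.integer(sub("^ch[0-9]+_w", "", chcols))), decreasing = TRUE)
        arr <- array(NA_real_, c(24L, 2L, ns))
        for (ch in 1:24) for (w in 1:2)
          arr[ch, w, ] <- fn_df[[sprintf("ch%02d_w%d", ch, wl[w])]]
        events <- read.csv(file.path(sd, sprintf("events_%s.csv", arm)),
                           stringsAsFactors = FALSE)
        sessions[[id]]$fnirs[[arm]] <- fnirs_session(
          arr, fs = manifest$fnirs_fs, wavelengths = wl, events = events)
      }
    }
  }
  list(subjects = subjects, sessions = sessions, manifest = manifest)
}
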