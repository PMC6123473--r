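#' Write a typing session to a bundle directory
#'
#' A session bundle is a plain-text directory: `manifest.yaml` (identifiers,
#' intended sentence, mode, stream rates), `eeg.csv`
#' (`time,<ch1>,...,<chN>`), `gaze.csv` (`time,x,y`) and a tab-delimited
#' `events.tsv` (`onset`, `key`, `index`, plus any extra event columns such
#' as simulation ground truth). Floats are serialized with 9 significant
#' digits.
#'
#' @param session A [typing_session()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "typing_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) abort(sprintf("cannot create bundle directory %s", path))

  manifest <- list(
    subject_id = session$subject_id,
    sentence_id = session$sentence_id,
    intended = session$intended,
    mode = session$mode,
    dwell = session$dwell,
    eeg_rate = session$eeg$rate,
    gaze_rate = attr(session$gaze, "rate"),
    eeg_start = session$eeg$start_time
  )
  yaml::write_yaml(manifest, file.path(path, "manifest.yaml"))

  eeg_tab <- as.data.frame(t(session$eeg$samples))
  names(eeg_tab) <- session$eeg$channel_names
  eeg_tab <- cbind(time = eeg_times(session$eeg), eeg_tab)
  readr::write_csv(sig9(eeg_tab), file.path(path, "eeg.csv"), progress = FALSE)

  gz <- tibble(time = session$gaze$t, x = session$gaze$x, y = session$gaze$y)
  readr::write_csv(sig9(gz), file.path(path, "gaze.csv"), progress = FALSE)

  ev <- as.data.frame(session$events)
  readr::write_tsv(sig9(ev), file.path(path, "events.tsv"), progress = FALSE)
  invisible(path)
}

sig9 <- function(df) {
  df[] <- lapply(df, function(col) if (is.double(col)) signif(col, 9) else col)
  df
}

#' Read a typing session from a bundle directory
#'
#' Inverse of [write_session()]. Validates the reassembled session.
#'
#' @param path Bundle directory.
#' @return A [typing_session()].
#' @export
read_session <- function(path) {
  need <- c("manifest.yaml", "eeg.csv", "gaze.csv", "events.tsv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing)) {
    abort(sprintf("incomplete bundle: missing %s", paste(missing, collapse = ", ")))
  }
  man <- yaml::read_yaml(file.path(path, "manifest.yaml"))

  eeg_tab <- readr::read_csv(file.path(path, "eeg.csv"),
                             show_col_types = FALSE, progress = FALSE)
  if (ncol(eeg_tab) < 2 || names(eeg_tab)[1] != "time") {
    abort("malformed stream: eeg table must start with a time column")
  }
  eeg <- eeg_recording(
    samples = t(as.matrix(eeg_tab[-1])),
    rate = man$eeg_rate,
    channel_names = names(eeg_tab)[-1],
    start_time = man$eeg_start %||% eeg_tab$time[1]
  )

  gz <- readr::read_csv(file.path(path, "gaze.csv"),
                        show_col_types = FALSE, progress = FALSE)
  if (!all(c("time", "x", "y") %in% names(gz))) {
    abort("malformed stream: gaze table must have time, x, y columns")
  }
  gaze <- gaze_recording(gz$time, gz$x, gz$y, rate = man$gaze_rate)

  # trim_ws = FALSE and no NA strings: the space key must survive verbatim
  ev <- readr::read_tsv(file.path(path, "events.tsv"),
                        show_col_types = FALSE, progress = FALSE,
                        trim_ws = FALSE, na = character(0),
                        col_types = readr::cols(key = readr::col_character()))
  if (nrow(ev) == 0) {
    ev <- tibble(onset = numeric(0), key = character(0), index = integer(0))
  }

  typing_session(man$subject_id, man$sentence_id, man$intended, ev,
                 eeg, gaze, mode = man$mode, dwell = man$dwell %||% 0.5)
}

#' Write/read a list of sessions under one directory
#'
#' Each session is stored in a sub-directory named
#' `<subject_id>_<sentence_id>_<mode>`.
#'
#' @param sessions List of [typing_session()] objects.
#' @param path Parent directory.
#' @return `path` (write) / list of sessions (read), invisibly sorted by
#'   sub-directory name.
#' @export
write_sessions <- function(sessions, path) {
  for (s in sessions) {
    write_session(s, file.path(path, paste(s$subject_id, s$sentence_id,
                                           s$mode, sep = "_")))
  }
  invisible(path)
}

#' @rdname write_sessions
#' @export
read_sessions <- function(path) {
  dirs <- sort(list.dirs(path, recursive = FALSE))
  if (!length(dirs)) abort(sprintf("no session bundles under %s", path))
  lapply(dirs, read_session)
}
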