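#' EEG recording container
#'
#' A multichannel EEG stream on a common session clock. Potentials are in
#' microvolts, channels are rows of `samples`.
#'
#' @param samples Numeric matrix, channels x time.
#' @param rate Sampling rate in Hz (default 256).
#' @param channel_names Character vector of channel labels, one per row.
#' @param start_time Time (s, session clock) of the first sample.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, rate = 256, channel_names = NULL,
                          start_time = 0) {
  samples <- as.matrix(samples)
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(samples)))
  }
  if (!is_scalar_number(rate) || rate <= 0) {
    abort("malformed stream: `rate` must be a positive number")
  }
  if (length(channel_names) != nrow(samples)) {
    abort("malformed stream: channel_names must match the number of rows")
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    abort("malformed stream: EEG samples contain missing or non-finite values")
  }
  structure(
    list(samples = samples, rate = rate,
         channel_names = as.character(channel_names),
         start_time = start_time),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              ncol(x$samples) / x$rate))
  invisible(x)
}

eeg_times <- function(eeg) {
  eeg$start_time + (seq_len(ncol(eeg$samples)) - 1) / eeg$rate
}

eeg_span <- function(eeg) {
  c(eeg$start_time, eeg$start_time + (ncol(eeg$samples) - 1) / eeg$rate)
}

#' Gaze recording container
#'
#' On-screen gaze samples (pixels, origin top-left, x rightward, y downward)
#' on the session clock. Timestamps must be strictly increasing after
#' de-duplication.
#'
#' @param t Numeric vector of timestamps (s).
#' @param x,y Numeric screen coordinates (px); finite.
#' @param rate Nominal sampling rate in Hz (default 30).
#' @return An object of class `gaze_recording`: a tibble with columns
#'   `t`, `x`, `y` and a `rate` attribute.
#' @export
gaze_recording <- function(t, x, y, rate = 30) {
  if (!is_scalar_number(rate) || rate <= 0) {
    abort("malformed stream: gaze `rate` must be positive")
  }
  if (length(t) != length(x) || length(t) != length(y)) {
    abort("malformed stream: gaze t, x, y lengths differ")
  }
  if (is.unsorted(t)) {
    abort("malformed stream: gaze timestamps must be non-decreasing")
  }
  keep <- !duplicated(t)
  t <- t[keep]; x <- x[keep]; y <- y[keep]
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("malformed stream: gaze coordinates must be finite")
  }
  out <- tibble(t = t, x = x, y = y)
  attr(out, "rate") <- rate
  class(out) <- c("gaze_recording", class(out))
  out
}

gaze_span <- function(gaze) range(gaze$t)

#' Typing session container
#'
#' One sentence's worth of synchronized recordings: the intended text, the
#' key-registration events, and the concurrent EEG and gaze streams, all on
#' one session clock. `mode` distinguishes the error-aware recording protocol
#' (typos are ignored and retried; no backspace) from the regular-control
#' protocol (typos are corrected with backspace).
#'
#' @param subject_id,sentence_id Identifiers.
#' @param intended Intended sentence: non-empty lower-case text ending in a
#'   full stop.
#' @param events Tibble of key events with at least `onset` (s, strictly
#'   increasing), `key` (single character or `"BACKSPACE"`), `index`
#'   (0-based press order).
#' @param eeg An [eeg_recording()].
#' @param gaze A [gaze_recording()].
#' @param mode `"error-aware-recording"` or `"regular-control"`.
#' @param dwell Dwell time (s) used by the keyboard; consecutive onsets must
#'   be at least this far apart.
#' @return An object of class `typing_session`.
#' @export
typing_session <- function(subject_id, sentence_id, intended, events,
                           eeg, gaze,
                           mode = c("error-aware-recording", "regular-control"),
                           dwell = 0.5) {
  mode <- match.arg(mode)
  events <- as_tibble(events)
  s <- structure(
    list(subject_id = as.character(subject_id),
         sentence_id = as.character(sentence_id),
         intended = intended, events = events,
         eeg = eeg, gaze = gaze, mode = mode, dwell = dwell),
    class = "typing_session"
  )
  validate_session(s)
}

validate_session <- function(s) {
  if (!inherits(s$eeg, "eeg_recording")) abort("malformed stream: eeg is not an eeg_recording")
  if (!inherits(s$gaze, "gaze_recording")) abort("malformed stream: gaze is not a gaze_recording")
  if (!is.character(s$intended) || length(s$intended) != 1 || nchar(s$intended) == 0) {
    abort("intended sentence must be a non-empty string")
  }
  if (s$intended != tolower(s$intended)) {
    abort("intended sentence must be lower-case")
  }
  if (substring(s$intended, nchar(s$intended)) != ".") {
    abort("intended sentence must end in a full stop")
  }
  ev <- s$events
  if (!all(c("onset", "key", "index") %in% names(ev))) {
    abort("events table must have onset, key and index columns")
  }
  if (nrow(ev) > 0) {
    if (any(diff(ev$onset) <= 0)) abort("event onsets must be strictly increasing")
    if (any(diff(ev$onset) < s$dwell - 1e-9)) {
      abort("consecutive onsets must be at least one dwell apart")
    }
    es <- eeg_span(s$eeg); gs <- gaze_span(s$gaze)
    lo <- max(es[1], gs[1]); hi <- min(es[2], gs[2])
    if (any(ev$onset < lo - 1e-9) || any(ev$onset > hi + 1e-9)) {
      abort("unsynchronized events: onsets outside the recorded time span")
    }
  }
  s
}

#' @export
print.typing_session <- function(x, ...) {
  cat(sprintf("<typing_session> subject %s, sentence %s (%s)\n",
              x$subject_id, x$sentence_id, x$mode))
  cat(sprintf("  intended: \"%s\"\n", x$intended))
  cat(sprintf("  %d key events, EEG %d ch @ %g Hz, gaze @ %g Hz\n",
              nrow(x$events), nrow(x$eeg$samples), x$eeg$rate,
              attr(x$gaze, "rate")))
  invisible(x)
}

#' Letter (non-backspace) events of a session
#'
#' @param session A [typing_session()].
#' @return Tibble of events with `key != "BACKSPACE"`.
#' @export
letter_events <- function(session) {
  session$events[session$events$key != "BACKSPACE", , drop = FALSE]
}

#' Replay a key sequence, applying backspaces
#'
#' Reconstructs the committed text from a press sequence in which
#' `"BACKSPACE"` deletes the previously committed character.
#'
#' @param keys Character vector of pressed keys.
#' @return The committed string.
#' @export
replay_keys <- function(keys) {
  buf <- character(0)
  for (k in keys) {
    if (identical(k, "BACKSPACE")) {
      if (length(buf)) buf <- buf[-length(buf)]
    } else {
      buf <- c(buf, k)
    }
  }
  paste(buf, collapse = "")
}

#' Typed character sequence of a session
#'
#' The letter presses in order (backspaces excluded), as a character vector.
#'
#' @param session A [typing_session()].
#' @return Character vector of single characters.
#' @export
typed_characters <- function(session) {
  letter_events(session)$key
}
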