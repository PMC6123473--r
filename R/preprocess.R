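#' Zero-phase band-pass filter an EEG recording
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (`signal::filtfilt`; effective 8th order, zero phase) to every channel.
#' The error-related response lives in the low frequencies, hence the
#' 1--16 Hz default.
#'
#' @param eeg An [eeg_recording()].
#' @param low,high Band edges in Hz.
#' @return A filtered [eeg_recording()] of the same shape and rate.
#' @export
bandpass_filter <- function(eeg, low = 1, high = 16) {
  stopifnot(inherits(eeg, "eeg_recording"))
  if (high >= eeg$rate / 2) abort("band exceeds Nyquist")
  if (low <= 0 || low >= high) abort("invalid band: expected 0 < low < high")
  bf <- signal::butter(4, c(low, high) / (eeg$rate / 2), type = "pass")
  filtered <- t(apply(eeg$samples, 1, function(ch) signal::filtfilt(bf, ch)))
  eeg_recording(filtered, rate = eeg$rate, channel_names = eeg$channel_names,
                start_time = eeg$start_time)
}

#' Label typed characters against the intended sentence
#'
#' Greedy left-to-right scan: a pointer walks the intended text; each typed
#' character that matches the pointed character is labelled correct and
#' advances the pointer, anything else is labelled erroneous and the pointer
#' stays (previous errors are ignored, per the error-aware protocol). The
#' scan must consume the whole intended text.
#'
#' @param intended Intended sentence (string).
#' @param typed Typed characters: a character vector of single characters or
#'   one string.
#' @return Factor of per-press labels, levels `correct`, `erroneous`.
#' @export
#' @examples
#' label_key_events("my dog is brown.", strsplit("muyb dog ias browqn.", "")[[1]])
label_key_events <- function(intended, typed) {
  want <- strsplit(intended, "")[[1]]
  if (length(typed) == 1 && nchar(typed[1]) > 1) {
    typed <- strsplit(typed, "")[[1]]
  }
  ptr <- 1L
  lab <- character(length(typed))
  for (i in seq_along(typed)) {
    if (ptr <= length(want) && typed[i] == want[ptr]) {
      lab[i] <- "correct"
      ptr <- ptr + 1L
    } else {
      lab[i] <- "erroneous"
    }
  }
  if (ptr <= length(want)) {
    abort("protocol violation: intended sentence not completed")
  }
  factor(lab, levels = c("correct", "erroneous"))
}

#' Accumulated gaze-distance series
#'
#' Running length of the on-screen gaze trajectory: `s[1] = 0` and
#' `s[i] = s[i-1] +` the Euclidean distance between consecutive samples.
#'
#' @param x,y Gaze coordinates (px), equal length >= 1.
#' @return Numeric vector, same length, non-negative and non-decreasing.
#' @export
accumulated_distance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1) {
    abort("x and y must be non-empty vectors of equal length")
  }
  if (length(x) == 1) return(0)
  cumsum(c(0, sqrt(diff(x)^2 + diff(y)^2)))
}

# Anchored epoch indexing: the latency-0 sample is the first sample at or
# after the onset; an epoch takes floor(-w1*rate) samples before it and
# floor(w2*rate) from it on, i.e. 51 + 128 = 179 EEG samples and
# 6 + 15 = 21 gaze samples at the default rates and window.
epoch_index <- function(onset, start_time, rate, window) {
  i0 <- as.integer(ceiling((onset - start_time) * rate - 1e-9)) + 1L
  pre <- as.integer(floor(-window[1] * rate + 1e-9))
  post <- as.integer(floor(window[2] * rate + 1e-9))
  list(first = i0 - pre, last = i0 + post - 1L, n = pre + post, zero = pre + 1L)
}

#' Cut dual-modality epochs around key registrations
#'
#' One epoch per letter press (backspace presses never enter epoching),
#' spanning the half-open window around the registration instant in both
#' streams. Epochs whose window exceeds either recording are dropped with a
#' warning. Gaze gaps (`NA` samples) of at most 2 consecutive samples are
#' linearly interpolated; longer gaps drop the epoch with a warning. For
#' error-aware sessions labels come from [label_key_events()]; for other
#' sessions the simulation ground truth (`truth_error`) is used when
#' present.
#'
#' @param session A [typing_session()] with band-pass-filtered EEG.
#' @param window Epoch window `c(start, end)` in seconds, start < 0 < end.
#' @param label Assign labels (default `TRUE`).
#' @return An [epoch_set()].
#' @export
epochize <- function(session, window = c(-0.2, 0.5), label = TRUE) {
  stopifnot(inherits(session, "typing_session"))
  if (!(window[1] < 0 && window[2] > 0)) abort("invalid window: expected start < 0 < end")
  ev <- letter_events(session)
  erate <- session$eeg$rate
  grate <- attr(session$gaze, "rate")
  labels <- if (label && nrow(ev)) epoch_labels(session, ev) else
    factor(rep(NA_character_, nrow(ev)), levels = c("correct", "erroneous"))

  ei <- lapply(ev$onset, epoch_index, start_time = session$eeg$start_time,
               rate = erate, window = window)
  gi <- lapply(ev$onset, epoch_index, start_time = session$gaze$t[1],
               rate = grate, window = window)
  n_eeg <- as.integer(floor(-window[1] * erate + 1e-9) + floor(window[2] * erate + 1e-9))
  n_gaze <- as.integer(floor(-window[1] * grate + 1e-9) + floor(window[2] * grate + 1e-9))

  keep <- logical(nrow(ev))
  eeg_arr <- array(NA_real_, c(nrow(session$eeg$samples), n_eeg, nrow(ev)))
  gx <- gy <- gt <- matrix(NA_real_, nrow(ev), n_gaze)
  for (i in seq_len(nrow(ev))) {
    e <- ei[[i]]; g <- gi[[i]]
    if (e$first < 1 || e$last > ncol(session$eeg$samples) ||
        g$first < 1 || g$last > nrow(session$gaze)) {
      warn(sprintf("dropping epoch %d: window exceeds the recording", i))
      next
    }
    xs <- session$gaze$x[g$first:g$last]
    ys <- session$gaze$y[g$first:g$last]
    if (anyNA(xs) || anyNA(ys)) {
      filled <- fill_gaze_gaps(xs, ys)
      if (is.null(filled)) {
        warn(sprintf("dropping epoch %d: gaze gap longer than 2 samples", i))
        next
      }
      xs <- filled$x; ys <- filled$y
    }
    eeg_arr[, , i] <- session$eeg$samples[, e$first:e$last]
    gx[i, ] <- xs; gy[i, ] <- ys
    gt[i, ] <- session$gaze$t[g$first:g$last]
    keep[i] <- TRUE
  }

  dist <- t(vapply(seq_len(nrow(ev)), function(i) {
    if (keep[i]) accumulated_distance(gx[i, ], gy[i, ]) else rep(NA_real_, n_gaze)
  }, numeric(n_gaze)))

  meta <- ev
  meta$sentence_id <- session$sentence_id
  meta$subject_id <- session$subject_id

  epoch_set(
    eeg = eeg_arr[, , keep, drop = FALSE],
    channel_names = session$eeg$channel_names,
    eeg_rate = erate, gaze_rate = grate,
    gaze_x = gx[keep, , drop = FALSE], gaze_y = gy[keep, , drop = FALSE],
    gaze_t = gt[keep, , drop = FALSE],
    distance = dist[keep, , drop = FALSE],
    label = labels[keep],
    events = meta[keep, , drop = FALSE],
    window = window
  )
}

epoch_labels <- function(session, ev) {
  if (session$mode == "error-aware-recording") {
    label_key_events(session$intended, ev$key)
  } else if ("truth_error" %in% names(ev)) {
    factor(ifelse(ev$truth_error, "erroneous", "correct"),
           levels = c("correct", "erroneous"))
  } else {
    factor(rep(NA_character_, nrow(ev)), levels = c("correct", "erroneous"))
  }
}

# Linear interpolation of short gaze gaps; NULL when a gap exceeds 2 samples
# or an endpoint is missing.
fill_gaze_gaps <- function(x, y) {
  na <- is.na(x) | is.na(y)
  r <- rle(na)
  if (any(r$values & r$lengths > 2)) return(NULL)
  if (na[1] || na[length(na)]) return(NULL)
  idx <- seq_along(x)
  list(x = stats::approx(idx[!na], x[!na], xout = idx)$y,
       y = stats::approx(idx[!na], y[!na], xout = idx)$y)
}
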