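#' Dual-modality epoch set
#'
#' A collection of event-locked epochs: the EEG segments (channels x time x
#' epoch), the concurrent gaze samples, the accumulated-distance series
#' derived from them, per-epoch labels and the originating event metadata.
#' Usually built by [epochize()]; the constructor is exported so that
#' fully synthetic epoch sets can be assembled in code.
#'
#' @param eeg 3-d numeric array, channels x time x epoch.
#' @param channel_names Channel labels (length = dim 1 of `eeg`).
#' @param eeg_rate,gaze_rate Sampling rates (Hz).
#' @param gaze_x,gaze_y,gaze_t Matrices, epoch x gaze-sample.
#' @param distance Matrix, epoch x gaze-sample: accumulated distance,
#'   non-negative, non-decreasing, first column zero.
#' @param label Factor with levels `correct`, `erroneous` (NAs allowed).
#' @param events Tibble of per-epoch event metadata.
#' @param window Epoch window `c(start, end)` in seconds.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(eeg, channel_names, eeg_rate, gaze_rate,
                      gaze_x, gaze_y, gaze_t, distance, label, events,
                      window = c(-0.2, 0.5)) {
  n <- dim(eeg)[3]
  stopifnot(length(channel_names) == dim(eeg)[1],
            nrow(distance) == n, length(label) == n, nrow(events) == n)
  if (n > 0) {
    if (any(distance[, 1] != 0) || any(distance < 0) ||
        any(t(apply(distance, 1, diff)) < -1e-9)) {
      abort("distance series must be non-negative, non-decreasing, starting at 0")
    }
  }
  structure(
    list(eeg = eeg, channel_names = as.character(channel_names),
         eeg_rate = eeg_rate, gaze_rate = gaze_rate,
         gaze_x = gaze_x, gaze_y = gaze_y, gaze_t = gaze_t,
         distance = distance,
         label = factor(label, levels = c("correct", "erroneous")),
         events = as_tibble(events), window = window),
    class = "epoch_set"
  )
}

#' @export
length.epoch_set <- function(x) dim(x$eeg)[3]

#' @export
print.epoch_set <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<epoch_set> %d epochs, %d EEG channels x %d samples, %d gaze samples\n",
              n, dim(x$eeg)[1], dim(x$eeg)[2], ncol(x$distance)))
  if (n && !all(is.na(x$label))) {
    cat(sprintf("  labels: %d correct, %d erroneous\n",
                sum(x$label == "correct", na.rm = TRUE),
                sum(x$label == "erroneous", na.rm = TRUE)))
  }
  invisible(x)
}

#' Subset an epoch set
#'
#' @param x An [epoch_set()].
#' @param i Epoch indices (integer or logical).
#' @param ... Unused.
#' @return An [epoch_set()].
#' @export
`[.epoch_set` <- function(x, i, ...) {
  if (is.logical(i)) i <- which(i)
  epoch_set(
    eeg = x$eeg[, , i, drop = FALSE], channel_names = x$channel_names,
    eeg_rate = x$eeg_rate, gaze_rate = x$gaze_rate,
    gaze_x = x$gaze_x[i, , drop = FALSE], gaze_y = x$gaze_y[i, , drop = FALSE],
    gaze_t = x$gaze_t[i, , drop = FALSE],
    distance = x$distance[i, , drop = FALSE],
    label = x$label[i], events = x$events[i, , drop = FALSE],
    window = x$window
  )
}

#' Concatenate epoch sets
#'
#' @param ... [epoch_set()] objects with matching channels, rates and
#'   windows.
#' @return A single [epoch_set()].
#' @export
c.epoch_set <- function(...) {
  sets <- list(...)
  first <- sets[[1]]
  for (s in sets[-1]) {
    if (!identical(s$channel_names, first$channel_names) ||
        s$eeg_rate != first$eeg_rate || s$gaze_rate != first$gaze_rate ||
        !identical(s$window, first$window)) {
      abort("epoch sets are not compatible")
    }
  }
  bind3 <- function(arrs) {
    d <- dim(arrs[[1]])
    array(do.call(c, lapply(arrs, as.vector)),
          c(d[1], d[2], sum(vapply(arrs, function(a) dim(a)[3], 0))))
  }
  epoch_set(
    eeg = bind3(lapply(sets, `[[`, "eeg")),
    channel_names = first$channel_names,
    eeg_rate = first$eeg_rate, gaze_rate = first$gaze_rate,
    gaze_x = do.call(rbind, lapply(sets, `[[`, "gaze_x")),
    gaze_y = do.call(rbind, lapply(sets, `[[`, "gaze_y")),
    gaze_t = do.call(rbind, lapply(sets, `[[`, "gaze_t")),
    distance = do.call(rbind, lapply(sets, `[[`, "distance")),
    label = factor(unlist(lapply(sets, function(s) as.character(s$label))),
                   levels = c("correct", "erroneous")),
    events = dplyr::bind_rows(lapply(sets, `[[`, "events")),
    window = first$window
  )
}

#' Per-epoch metadata as a tibble
#'
#' @param x An [epoch_set()].
#' @param ... Unused.
#' @return Tibble: event metadata plus the assigned `label`.
#' @method as_tibble epoch_set
#' @export
as_tibble.epoch_set <- function(x, ...) {
  out <- x$events
  out$label <- x$label
  out
}

#' Preprocess a session into labelled epochs
#'
#' Band-pass filters the EEG and cuts labelled dual-modality epochs: the
#' standard front end for every detector in this package.
#'
#' @param session A [typing_session()].
#' @param config A [pipeline_config()].
#' @return An [epoch_set()].
#' @export
preprocess_session <- function(session, config = pipeline_config()) {
  session$eeg <- bandpass_filter(session$eeg, config$band[1], config$band[2])
  epochize(session, window = config$window)
}

#' @rdname preprocess_session
#' @param sessions List of sessions.
#' @return `preprocess_sessions()`: one concatenated [epoch_set()].
#' @export
preprocess_sessions <- function(sessions, config = pipeline_config()) {
  do.call(c, lapply(sessions, preprocess_session, config = config))
}
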