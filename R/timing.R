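#' Levenshtein edit distance
#'
#' Unit-cost insert/delete/substitute distance between two strings.
#'
#' @param a,b Strings.
#' @return Non-negative integer.
#' @export
edit_distance <- function(a, b) {
  as.integer(drop(adist(a, b)))
}

#' Estimate per-press times from regular-control recordings
#'
#' The average backspace press time `b_avg` (resp. letter press time
#' `l_avg`) is the mean inter-press interval that ends in a backspace
#' (resp. letter) registration, pooled over the supplied control sessions.
#'
#' @param sessions List of regular-control [typing_session()] objects.
#' @return One-row tibble: `b_avg`, `l_avg`, `n_backspace`, `n_letter`.
#' @export
estimate_press_times <- function(sessions) {
  if (inherits(sessions, "typing_session")) sessions <- list(sessions)
  iv <- purrr::map(sessions, function(s) {
    ev <- s$events
    if (nrow(ev) < 2) return(NULL)
    tibble(interval = diff(ev$onset), key = ev$key[-1])
  })
  iv <- dplyr::bind_rows(iv)
  if (nrow(iv) == 0) abort("no inter-press intervals available")
  back <- iv$interval[iv$key == "BACKSPACE"]
  lett <- iv$interval[iv$key != "BACKSPACE"]
  tibble(
    b_avg = if (length(back)) mean(back) else NaN,
    l_avg = if (length(lett)) mean(lett) else NaN,
    n_backspace = length(back), n_letter = length(lett)
  )
}

#' Total typing time, regular keyboard
#'
#' `T2 = t2 + d * b_avg`: the recorded first-to-last press span plus one
#' backspace penalty per residual edit.
#'
#' @param t2 First-to-last key-press span (s), > 0.
#' @param d Edit distance between committed and intended text, >= 0.
#' @param b_avg Mean backspace press time (s).
#' @return T2 (s).
#' @export
estimate_regular_time <- function(t2, d, b_avg) {
  if (t2 < 0 || d < 0 || b_avg < 0) abort("negative inputs")
  t2 + d * b_avg
}

#' Total typing time, error-aware keyboard
#'
#' `T1 = t1 + (d - k1) * b_avg + k2 * l_avg`: detected errors (`k1`) are
#' deleted automatically and cost nothing, the `d - k1` missed ones cost a
#' backspace each, and every falsely flagged correct press (`k2`) costs one
#' letter re-type.
#'
#' @param t1 First-to-last key-press span (s) of the error-aware recording.
#' @param d Edit distance between typed and intended text.
#' @param k1 Erroneous presses classified erroneous (0 <= k1 <= d).
#' @param k2 Correct presses classified erroneous (>= 0).
#' @param b_avg,l_avg Mean backspace / letter press times (s).
#' @return T1 (s).
#' @export
estimate_error_aware_time <- function(t1, d, k1, k2, b_avg, l_avg) {
  if (k1 > d) abort("more detected errors than errors")
  if (t1 < 0 || d < 0 || k1 < 0 || k2 < 0 || b_avg < 0 || l_avg < 0) {
    abort("negative inputs")
  }
  t1 + (d - k1) * b_avg + k2 * l_avg
}

#' Per-sentence typing-time report
#'
#' Simulates the error-aware keyboard off-line on one recorded sentence:
#' combines the error-aware recording (press span `t1`, typed text), its
#' matched regular-control recording (press span `t2`, committed text), the
#' detector's per-press predictions, and the empirical press-time estimates
#' into the T1/T2 totals and the time gain.
#'
#' @param aware_session Error-aware [typing_session()].
#' @param control_session Matched regular-control session (same intended
#'   sentence).
#' @param predictions Tibble with `truth` and `predicted` (factors
#'   `correct`/`erroneous`), one row per letter press of `aware_session`,
#'   e.g. the matching rows of [loso_cv()] output.
#' @param b_avg,l_avg Press-time estimates (s), see
#'   [estimate_press_times()].
#' @return One-row tibble: `sentence_id`, `t1`, `t2`, `d`, `k1`, `k2`,
#'   `b_avg`, `l_avg`, `T1`, `T2`, `gain_seconds`, `gain_percent`.
#' @export
timing_report <- function(aware_session, control_session, predictions,
                          b_avg, l_avg) {
  if (aware_session$intended != control_session$intended) {
    abort("unmatched sessions: intended sentences differ")
  }
  lev <- letter_events(aware_session)
  if (nrow(predictions) != nrow(lev)) {
    abort("unmatched sessions: one prediction per letter press required")
  }
  t1 <- diff(range(aware_session$events$onset))
  t2 <- diff(range(control_session$events$onset))
  typed <- paste(typed_characters(aware_session), collapse = "")
  d <- edit_distance(typed, aware_session$intended)
  committed <- replay_keys(control_session$events$key)
  d2 <- edit_distance(committed, control_session$intended)
  k1 <- sum(predictions$truth == "erroneous" & predictions$predicted == "erroneous")
  k2 <- sum(predictions$truth == "correct" & predictions$predicted == "erroneous")
  T1 <- estimate_error_aware_time(t1, d, min(k1, d), k2, b_avg, l_avg)
  T2 <- estimate_regular_time(t2, d2, b_avg)
  tibble(
    sentence_id = aware_session$sentence_id,
    t1 = t1, t2 = t2, d = d, d_control = d2, k1 = k1, k2 = k2,
    b_avg = b_avg, l_avg = l_avg, T1 = T1, T2 = T2,
    gain_seconds = T2 - T1, gain_percent = 100 * (T2 - T1) / T2
  )
}

#' Leave-one-sentence-out typing-time simulation
#'
#' Runs [loso_cv()] on the error-aware sessions, estimates press times from
#' the regular-control sessions, and assembles one [timing_report()] row
#' per sentence pair (matched by intended text).
#'
#' @param aware_sessions List of error-aware [typing_session()] objects.
#' @param control_sessions List of matched regular-control sessions.
#' @param mode Detector mode.
#' @param theta Decision threshold.
#' @param config A [pipeline_config()].
#' @param seed Master seed for the LOSO fits.
#' @return Tibble of class `eds_timing`, one row per sentence, with a
#'   `press_times` attribute.
#' @export
loso_timing <- function(aware_sessions, control_sessions, mode = "late",
                        theta = config$theta, config = pipeline_config(),
                        seed = NULL) {
  preds <- loso_cv(aware_sessions, mode, theta, config, seed)
  times <- estimate_press_times(control_sessions)
  control_by <- stats::setNames(control_sessions,
                                vapply(control_sessions, `[[`, "", "intended"))
  rows <- purrr::map(aware_sessions, function(s) {
    ctrl <- control_by[[s$intended]]
    if (is.null(ctrl)) abort("unmatched sessions: no control for a sentence")
    pr <- preds[preds$sentence_id == s$sentence_id, , drop = FALSE]
    timing_report(s, ctrl, pr, times$b_avg, times$l_avg)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("eds_timing", class(out))
  attr(out, "press_times") <- times
  out
}
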