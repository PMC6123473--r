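#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point facet_wrap
#'   labs theme_minimal vars
#' @export
ggplot2::autoplot

#' Plot a threshold sweep
#'
#' Mean sensitivity, specificity and utility gain against the decision
#' threshold, with the gain-maximizing threshold marked.
#'
#' @param object A [threshold_sweep()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eds_sweep
#' @export
autoplot.eds_sweep <- function(object, ...) {
  tab <- tidy(object)
  long <- tidyr::pivot_longer(tab, c("sensitivity", "specificity", "gain"),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$theta, y = .data$value)) +
    geom_line() +
    geom_point(data = dplyr::filter(long, .data$theta == best_threshold(object)),
               colour = "red") +
    facet_wrap(vars(.data$metric), scales = "free_y", ncol = 1) +
    labs(x = "decision threshold", y = NULL,
         title = sprintf("Threshold sweep (%s fusion)", attr(object, "mode")),
         subtitle = sprintf("best gain at theta = %g", best_threshold(object))) +
    theme_minimal()
}

#' Plot Monte-Carlo CV metric distributions
#'
#' @param object A [monte_carlo_cv()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eds_cv
#' @export
autoplot.eds_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics,
                              c("sensitivity", "specificity", "accuracy"),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    labs(x = NULL, y = NULL,
         title = sprintf("Monte-Carlo CV (%s, %d reps, theta = %g)",
                         object$mode, object$reps, object$theta)) +
    theme_minimal()
}

#' Plot class-average event-locked traces
#'
#' Grand-average EEG trace of one channel and mean eye-speed profile per
#' label, the event-locked summary of an epoch set.
#'
#' @param object A labelled [epoch_set()].
#' @param channel Channel to average (default `Cz` when present).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot epoch_set
#' @export
autoplot.epoch_set <- function(object, channel = NULL, ...) {
  if (is.null(channel)) {
    channel <- if ("Cz" %in% object$channel_names) "Cz" else object$channel_names[1]
  }
  ci <- match(channel, object$channel_names)
  if (is.na(ci)) abort(sprintf("channel %s not present", channel))
  nt <- dim(object$eeg)[2]
  tt <- object$window[1] + (seq_len(nt) - 1) / object$eeg_rate
  keep <- !is.na(object$label)
  labs_chr <- as.character(object$label[keep])
  eeg_tr <- t(object$eeg[ci, , keep])
  eeg_df <- dplyr::bind_rows(lapply(unique(labs_chr), function(l) {
    tibble(time = tt, value = colMeans(eeg_tr[labs_chr == l, , drop = FALSE]),
           label = l, panel = sprintf("EEG %s (uV)", channel))
  }))
  spd <- t(apply(object$distance[keep, , drop = FALSE], 1, diff)) * object$gaze_rate
  ts <- object$window[1] + (seq_len(ncol(spd))) / object$gaze_rate
  spd_df <- dplyr::bind_rows(lapply(unique(labs_chr), function(l) {
    tibble(time = ts, value = colMeans(spd[labs_chr == l, , drop = FALSE]),
           label = l, panel = "eye speed (px/s)")
  }))
  ggplot(dplyr::bind_rows(eeg_df, spd_df),
         aes(x = .data$time, y = .data$value, colour = .data$label)) +
    geom_line() +
    facet_wrap(vars(.data$panel), scales = "free_y", ncol = 1) +
    labs(x = "time from key registration (s)", y = NULL, colour = NULL) +
    theme_minimal()
}

#' Plot direction-conditioned sub-averages
#'
#' EEG and eye-speed sub-averages per gaze-direction group: the visual
#' check that the event-locked EEG shows no polarity inversion across
#' opposite movement directions.
#'
#' @param object A [direction_subaverages()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eds_directions
#' @export
autoplot.eds_directions <- function(object, ...) {
  k <- nrow(object$eeg_mean)
  tt <- object$window[1] + (seq_len(ncol(object$eeg_mean)) - 1) / object$eeg_rate
  ts <- object$window[1] + seq_len(ncol(object$speed_mean)) / object$gaze_rate
  df <- dplyr::bind_rows(lapply(seq_len(k), function(g) {
    dplyr::bind_rows(
      tibble(time = tt, value = object$eeg_mean[g, ], group = factor(g),
             panel = sprintf("EEG %s (uV)", object$channel)),
      tibble(time = ts, value = object$speed_mean[g, ], group = factor(g),
             panel = "eye speed (px/s)")
    )
  }))
  ggplot(df, aes(x = .data$time, y = .data$value, colour = .data$group)) +
    geom_line() +
    facet_wrap(vars(.data$panel), scales = "free_y", ncol = 1) +
    labs(x = "time from key registration (s)", y = NULL,
         colour = "direction group") +
    theme_minimal()
}
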