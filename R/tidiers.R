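#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a DSP filter: one row per channel weight
#'
#' @param x A [fit_dsp()] object.
#' @param ... Unused.
#' @return Tibble: `channel`, `weight`.
#' @method tidy dsp_filter
#' @export
tidy.dsp_filter <- function(x, ...) {
  tibble(channel = x$channel_names %||% paste0("ch", seq_len(x$channels)),
         weight = as.numeric(x$w))
}

#' @rdname tidy.dsp_filter
#' @return `glance()`: one row with `channels` and `fisher_value`.
#' @method glance dsp_filter
#' @export
glance.dsp_filter <- function(x, ...) {
  tibble(channels = x$channels, fisher_value = x$fisher_value)
}

#' Tidy a fitted detector: SVM weights per modality
#'
#' @param x An [fit_detector()] object.
#' @param ... Unused.
#' @return Tibble: `modality`, `term`, `estimate` (hyperplane weights; the
#'   intercept is the `(intercept)` term).
#' @method tidy eds_detector
#' @export
tidy.eds_detector <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$svms), function(m) {
    s <- x$svms[[m]]
    tibble(modality = m,
           term = c(paste0("f", seq_along(s$w)), "(intercept)"),
           estimate = c(s$w, s$b))
  }))
}

#' @rdname tidy.eds_detector
#' @return `glance()`: one row with mode, training size, class counts,
#'   threshold and per-SVM scale constants.
#' @method glance eds_detector
#' @export
glance.eds_detector <- function(x, ...) {
  tibble(mode = x$mode, n_train = x$n_train,
         n_correct = x$class_counts$correct %||% 0L,
         n_erroneous = x$class_counts$erroneous %||% 0L,
         theta = x$theta,
         scales = paste(sprintf("%s=%.3g", names(x$svms),
                                vapply(x$svms, `[[`, 0, "scale")),
                        collapse = ", "))
}

#' Tidy Monte-Carlo CV results: one row per repetition
#'
#' @param x An [monte_carlo_cv()] object.
#' @param ... Unused.
#' @method tidy eds_cv
#' @export
tidy.eds_cv <- function(x, ...) x$metrics

#' @rdname tidy.eds_cv
#' @return `glance()`: one row of averaged metrics.
#' @method glance eds_cv
#' @export
glance.eds_cv <- function(x, ...) {
  dplyr::bind_cols(tibble(mode = x$mode, theta = x$theta, reps = x$reps,
                          p_hat = x$p_hat), x$summary)
}

#' Tidy a threshold sweep
#'
#' @param x A [threshold_sweep()] result.
#' @param ... Unused.
#' @method tidy eds_sweep
#' @export
tidy.eds_sweep <- function(x, ...) as_tibble(unclass_sweep(x))

#' @rdname tidy.eds_sweep
#' @return `glance()`: the best-gain operating point.
#' @method glance eds_sweep
#' @export
glance.eds_sweep <- function(x, ...) {
  tab <- as_tibble(unclass_sweep(x))
  best <- tab[which.max(tab$gain), , drop = FALSE]
  best$p_hat <- attr(x, "p_hat")
  best$mode <- attr(x, "mode")
  best
}

unclass_sweep <- function(x) {
  class(x) <- setdiff(class(x), "eds_sweep")
  attr(x, "per_rep") <- NULL
  x
}

#' Best threshold of a sweep
#'
#' @param sweep A [threshold_sweep()] result.
#' @return The gain-maximizing threshold.
#' @export
best_threshold <- function(sweep) attr(sweep, "best_theta")
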