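#' Sensitivity, specificity and accuracy
#'
#' Erroneous presses are the positive class: sensitivity is the fraction of
#' erroneous presses flagged, specificity the fraction of correct presses
#' left unflagged. When a class is absent the corresponding rate is `NaN`
#' (never silently 0).
#'
#' @param predicted,truth Factors/characters with values `correct` /
#'   `erroneous`, equal length.
#' @return One-row tibble: `sensitivity`, `specificity`, `accuracy`, and
#'   the confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(predicted, truth) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (length(predicted) != length(truth)) abort("length mismatch")
  tp <- sum(predicted == "erroneous" & truth == "erroneous")
  fn <- sum(predicted == "correct" & truth == "erroneous")
  tn <- sum(predicted == "correct" & truth == "correct")
  fp <- sum(predicted == "erroneous" & truth == "correct")
  sens <- if (tp + fn == 0) NaN else tp / (tp + fn)
  spec <- if (tn + fp == 0) NaN else tn / (tn + fp)
  tibble(sensitivity = sens, specificity = spec,
         accuracy = (tp + tn) / length(truth),
         tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Utility gain of the error-detection system
#'
#' Expected-progress (renewal) model of dwell typing: every key selection
#' costs the same nominal time `T_s`. Without assistance, an erroneous press
#' (probability `p`) must be undone by one backspace, so the expected net
#' correct characters per selection is `(1 - p) / (1 + p)`. With the
#' detector, flagged errors (`p * se`) are deleted automatically, missed
#' errors (`p * (1 - se)`) still cost a backspace, and falsely deleted
#' correct presses (`(1 - p)(1 - sp)`) make no progress. The utility ratio
#' (detector on / off) is then
#' `gain = sp * (1 + p) / (1 + p * (1 - se))`; `T_s` cancels. The identities
#' `gain(se = 0, sp = 1) = 1` and `gain(p, 1, 1) = 1 + p` hold exactly, and
#' the gain is strictly increasing in both rates.
#'
#' @param p Per-press mistype probability, in \[0, 0.5).
#' @param sensitivity,specificity Detector operating point, each in
#'   \[0, 1\].
#' @return Numeric gain ratio (vectorized over the inputs).
#' @export
utility_gain <- function(p, sensitivity, specificity) {
  if (any(p < 0 | p >= 0.5)) abort("p must lie in [0, 0.5)")
  if (any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1)) {
    abort("sensitivity and specificity must lie in [0, 1]")
  }
  specificity * (1 + p) / (1 + p * (1 - sensitivity))
}

# Ratio-preserving Monte-Carlo test split: 10 erroneous epochs plus
# round(10 * (1 - p_hat) / p_hat) correct ones.
mc_split <- function(label, seed) {
  err <- which(label == "erroneous")
  cor <- which(label == "correct")
  p_hat <- length(err) / length(label)
  n_cor <- round(10 * (1 - p_hat) / p_hat)
  n_cor <- min(n_cor, length(cor) - 1L)
  with_seed_or_current(seed, {
    test <- c(sample(err, 10), sample(cor, n_cor))
  })
  list(test = test, train = setdiff(seq_along(label), test), p_hat = p_hat)
}

#' Monte-Carlo cross-validation of a detector
#'
#' Each repetition draws a test set of 10 erroneous epochs plus enough
#' correct ones to preserve the empirical class ratio, trains the detector
#' (SMOTE inside) on the remainder, and evaluates at threshold `theta`.
#'
#' @param epochs A labelled [epoch_set()] with at least 11 erroneous
#'   epochs.
#' @param mode Detector mode (see [fit_detector()]).
#' @param reps Number of repetitions (default from `config`).
#' @param seed Master seed; per-repetition seeds are spawned from it.
#' @param theta Decision threshold.
#' @param config A [pipeline_config()].
#' @return Object of class `eds_cv`: `metrics` (per-repetition tibble) and
#'   `summary` (means and SDs), plus the run parameters.
#' @export
monte_carlo_cv <- function(epochs, mode = "late", reps = config$mc_repetitions,
                           seed = NULL, theta = config$theta,
                           config = pipeline_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_err <- sum(epochs$label == "erroneous", na.rm = TRUE)
  if (n_err < 11) abort("insufficient minority instances")
  seeds <- derive_seeds(seed, 2 * reps)
  rows <- purrr::map(seq_len(reps), function(r) {
    sp <- mc_split(epochs$label, seeds[[r]])
    det <- fit_detector(epochs[sp$train], mode, config, seed = seeds[[reps + r]])
    pred <- classify_epochs(det, epochs[sp$test], theta)
    m <- confusion_metrics(pred, epochs$label[sp$test])
    m$rep <- r
    m$n_test_err <- sum(epochs$label[sp$test] == "erroneous")
    m$n_test_cor <- sum(epochs$label[sp$test] == "correct")
    m$pred_erroneous_rate <- mean(pred == "erroneous")
    m
  })
  metrics <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(
    metrics,
    dplyr::across(c("sensitivity", "specificity", "accuracy"),
                  list(mean = ~mean(.x, na.rm = TRUE), sd = ~sd(.x, na.rm = TRUE)))
  )
  structure(
    list(metrics = metrics, summary = summary, mode = mode, theta = theta,
         reps = reps, p_hat = n_err / length(epochs), n_epochs = length(epochs)),
    class = "eds_cv"
  )
}

#' @export
print.eds_cv <- function(x, ...) {
  cat(sprintf("<eds_cv> mode %s, %d reps, theta = %g, p_hat = %.3f\n",
              x$mode, x$reps, x$theta, x$p_hat))
  print(x$summary)
  invisible(x)
}

#' Threshold sweep with utility-gain scoring
#'
#' Repeats Monte-Carlo splits, fits the detector once per repetition, and
#' sweeps the decision threshold over a grid in \[-1, 1\] (endpoints
#' included) on the fixed test scores; per-threshold sensitivity and
#' specificity are averaged over repetitions and converted to a utility
#' gain at the dataset's empirical mistype rate. The reported `best_theta`
#' maximizes the mean gain (ties go to the lowest threshold).
#'
#' @inheritParams monte_carlo_cv
#' @param step Grid step (default 0.05).
#' @return A tibble of class `eds_sweep` with columns `theta`,
#'   `sensitivity`, `specificity`, `gain`; attributes `best_theta`,
#'   `p_hat`, `mode`, `per_rep` (repetition x threshold arrays).
#' @export
threshold_sweep <- function(epochs, mode = "late", step = 0.05,
                            reps = config$mc_repetitions, seed = NULL,
                            config = pipeline_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!is_scalar_number(step) || step <= 0 || step > 2) abort("invalid grid step")
  n_err <- sum(epochs$label == "erroneous", na.rm = TRUE)
  if (n_err < 11) abort("insufficient minority instances")
  grid <- unique(c(seq(-1, 1, by = step), 1))
  seeds <- derive_seeds(seed, 2 * reps)
  se_mat <- sp_mat <- matrix(NA_real_, reps, length(grid))
  p_hat <- n_err / length(epochs)
  for (r in seq_len(reps)) {
    sp <- mc_split(epochs$label, seeds[[r]])
    det <- fit_detector(epochs[sp$train], mode, config, seed = seeds[[reps + r]])
    sc <- score_epochs(det, epochs[sp$test])$score
    truth <- epochs$label[sp$test]
    for (j in seq_along(grid)) {
      pred <- ifelse(sc <= grid[j], "erroneous", "correct")
      m <- confusion_metrics(pred, truth)
      se_mat[r, j] <- m$sensitivity
      sp_mat[r, j] <- m$specificity
    }
  }
  out <- tibble(
    theta = grid,
    sensitivity = colMeans(se_mat),
    specificity = colMeans(sp_mat)
  )
  out$gain <- utility_gain(config$utility_p %||% p_hat,
                           out$sensitivity, out$specificity)
  best <- out$theta[which.max(out$gain)]
  structure(out,
            class = c("eds_sweep", class(out)),
            best_theta = best, p_hat = p_hat, mode = mode,
            per_rep = list(sensitivity = se_mat, specificity = sp_mat))
}

#' Leave-one-sentence-out cross-validation
#'
#' For each session (sentence), fits the detector on all other sessions'
#' epochs and predicts every key press of the held-out one: the unbiased
#' per-press labels used by the typing-time simulation.
#'
#' @param sessions List of labelled [typing_session()] objects (>= 2),
#'   error-aware recordings.
#' @param mode Detector mode.
#' @param theta Decision threshold.
#' @param config A [pipeline_config()].
#' @param seed Master seed.
#' @return Tibble: `sentence_id`, `index`, `onset`, `key`, `truth`,
#'   `predicted`, `score`.
#' @export
loso_cv <- function(sessions, mode = "late", theta = config$theta,
                    config = pipeline_config(), seed = NULL) {
  if (length(sessions) < 2) abort("at least 2 sessions are required")
  sets <- lapply(sessions, preprocess_session, config = config)
  seeds <- derive_seeds(seed, length(sessions))
  rows <- purrr::map(seq_along(sessions), function(i) {
    train <- do.call(c, sets[-i])
    if (sum(train$label == "erroneous", na.rm = TRUE) == 0) {
      abort("degenerate fold: no erroneous epochs in the training sentences")
    }
    det <- fit_detector(train, mode, config, seed = seeds[[i]])
    held <- sets[[i]]
    sc <- score_epochs(det, held)
    tibble(
      sentence_id = held$events$sentence_id,
      index = held$events$index,
      onset = held$events$onset,
      key = held$events$key,
      truth = held$label,
      predicted = classify_epochs(det, held, theta),
      score = sc$score
    )
  })
  dplyr::bind_rows(rows)
}

#' Direction-conditioned sub-averaging diagnostic
#'
#' Groups correct-press epochs by the direction of the aggregate gaze
#' displacement (k-means on the 2-d displacement integrated over the epoch
#' window) and sub-averages the EEG trace of a chosen channel and the
#' eye-speed profile within each group. If the event-locked EEG were driven
#' by ocular artefacts, opposite movement directions would show polarity
#' inversion; its absence supports a cortical origin.
#'
#' @param epochs An [epoch_set()]; only correct-labelled epochs are used
#'   when labels are present.
#' @param channel Channel to sub-average (default `"Cz"` when present).
#' @param k Number of direction groups (default 4).
#' @param seed Seed for k-means restarts.
#' @return Object of class `eds_directions`: `displacement` (n x 2),
#'   `membership`, `centers`, `eeg_mean` (k x EEG samples), `speed_mean`
#'   (k x gaze samples - 1), `channel`, `eeg_rate`, `gaze_rate`, `window`.
#' @export
direction_subaverages <- function(epochs, channel = NULL, k = 4, seed = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!all(is.na(epochs$label))) {
    epochs <- epochs[epochs$label == "correct" & !is.na(epochs$label)]
  }
  n <- length(epochs)
  if (k > n) abort("k exceeds the number of correct epochs")
  if (is.null(channel)) {
    channel <- if ("Cz" %in% epochs$channel_names) "Cz" else epochs$channel_names[1]
  }
  ci <- match(channel, epochs$channel_names)
  if (is.na(ci)) abort(sprintf("channel %s not present", channel))

  disp <- cbind(
    epochs$gaze_x[, ncol(epochs$gaze_x)] - epochs$gaze_x[, 1],
    epochs$gaze_y[, ncol(epochs$gaze_y)] - epochs$gaze_y[, 1]
  )
  km <- with_seed_or_current(seed, kmeans(disp, centers = k, nstart = 10))
  speed <- t(apply(epochs$distance, 1, diff)) * epochs$gaze_rate
  eeg_tr <- t(epochs$eeg[ci, , ])
  eeg_mean <- do.call(rbind, lapply(seq_len(k), function(g) {
    colMeans(eeg_tr[km$cluster == g, , drop = FALSE])
  }))
  speed_mean <- do.call(rbind, lapply(seq_len(k), function(g) {
    colMeans(speed[km$cluster == g, , drop = FALSE])
  }))
  structure(
    list(displacement = disp, membership = km$cluster, centers = km$centers,
         eeg_mean = eeg_mean, speed_mean = speed_mean, channel = channel,
         eeg_rate = epochs$eeg_rate, gaze_rate = epochs$gaze_rate,
         window = epochs$window),
    class = "eds_directions"
  )
}
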