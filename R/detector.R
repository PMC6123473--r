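#' Fit an error detector on labelled epochs
#'
#' The training pipeline, strictly confined to the supplied (training)
#' epochs: (1) SMOTE balances the classes on the raw representations --
#' band-pass-filtered EEG epochs (vectorized channels x time) and, paired
#' through the same interpolation triplets, the accumulated gaze-distance
#' series -- so that the label-aware spatial filter benefits from the
#' augmentation; (2) a DSP spatial filter is fitted on the augmented EEG and
#' projects each epoch to the post-onset virtual-sensor vector (128 values
#' at 256 Hz); (3) Hjorth descriptors summarize each distance series; (4)
#' features are z-scored with constants fitted on the augmented training
#' set; (5) linear SVMs (cost from `config`) are trained per mode: one for
#' `eeg`, one for `gaze`, one on the concatenated normalized features for
#' `early`, and the two unimodal ones for `late` fusion. Each SVM's raw
#' decision values are rescaled by the maximum absolute training decision
#' value, so training scores span \[-1, 1\]; positive scores are evidence
#' for a correct press.
#'
#' @param epochs A labelled [epoch_set()] (both classes present).
#' @param mode `"eeg"`, `"gaze"`, `"early"` or `"late"`.
#' @param config A [pipeline_config()].
#' @param seed Optional integer seed (drives SMOTE).
#' @return An object of class `eds_detector`.
#' @export
fit_detector <- function(epochs, mode = c("late", "eeg", "gaze", "early"),
                         config = pipeline_config(), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(epochs, "epoch_set"))
  lab <- epochs$label
  if (anyNA(lab)) abort("degenerate training set: unlabelled epochs")
  counts <- table(lab)
  if (any(counts == 0)) abort("degenerate training set: a class is missing")

  aug <- augment_epochs(epochs, mode, config, seed)
  y <- aug$label
  need_eeg <- mode %in% c("eeg", "early", "late")
  need_gaze <- mode %in% c("gaze", "early", "late")

  filter <- NULL; norm <- list(); svms <- list()
  feats <- list()
  if (need_eeg) {
    filter <- fit_dsp(aug$eeg[, , y == "erroneous", drop = FALSE],
                      aug$eeg[, , y == "correct", drop = FALSE])
    fe <- apply_dsp(filter, aug$eeg, rate = epochs$eeg_rate,
                    window = epochs$window)
    norm$eeg <- fit_znorm(fe)
    feats$eeg <- apply_znorm(fe, norm$eeg)
  }
  if (need_gaze) {
    gf <- as.matrix(gaze_feature_vector(aug$distance,
                                        rate = epochs$gaze_rate)[c("activity", "mobility", "complexity")])
    norm$gaze <- fit_znorm(gf)
    feats$gaze <- apply_znorm(gf, norm$gaze)
  }
  if (mode %in% c("eeg", "gaze")) {
    svms[[mode]] <- fit_linear_svm(feats[[mode]], y, config$svm_cost)
  } else if (mode == "early") {
    svms$early <- fit_linear_svm(cbind(feats$eeg, feats$gaze), y,
                                 config$svm_cost)
  } else {
    svms$eeg <- fit_linear_svm(feats$eeg, y, config$svm_cost)
    svms$gaze <- fit_linear_svm(feats$gaze, y, config$svm_cost)
  }

  structure(
    list(mode = mode, filter = filter, norm = norm, svms = svms,
         theta = config$theta, config = config,
         eeg_rate = epochs$eeg_rate, gaze_rate = epochs$gaze_rate,
         window = epochs$window, n_train = length(epochs),
         class_counts = as.list(counts)),
    class = "eds_detector"
  )
}

# SMOTE the minority class up to the majority count on the raw
# representations, sharing interpolation triplets across modalities so that
# synthetic EEG epochs stay paired with synthetic distance series.
augment_epochs <- function(epochs, mode, config, seed) {
  lab <- epochs$label
  counts <- table(lab)
  minority <- names(which.min(counts))
  n_syn <- as.integer(max(counts) - min(counts))
  min_idx <- which(lab == minority)

  eeg_flat <- eeg_as_matrix(epochs)
  ref <- if (mode == "gaze") epochs$distance[min_idx, , drop = FALSE] else
    eeg_flat[min_idx, , drop = FALSE]
  plan <- smote_plan(ref, n_syn, k = config$smote_k, seed = seed)

  syn_eeg <- smote_interpolate(eeg_flat[min_idx, , drop = FALSE], plan)
  syn_dist <- smote_interpolate(epochs$distance[min_idx, , drop = FALSE], plan)

  nch <- dim(epochs$eeg)[1]; nt <- dim(epochs$eeg)[2]
  eeg_aug <- array(c(epochs$eeg, t(syn_eeg)), c(nch, nt, length(lab) + n_syn))
  list(
    eeg = eeg_aug,
    distance = rbind(epochs$distance, syn_dist),
    label = factor(c(as.character(lab), rep(minority, n_syn)),
                   levels = c("correct", "erroneous"))
  )
}

eeg_as_matrix <- function(epochs) {
  d <- dim(epochs$eeg)
  t(matrix(epochs$eeg, d[1] * d[2], d[3]))
}

fit_znorm <- function(x) {
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  s[!is.finite(s) | s == 0] <- 1
  list(mean = m, sd = s)
}

apply_znorm <- function(x, nz) {
  sweep(sweep(x, 2, nz$mean), 2, nz$sd, "/")
}

# Linear SVM reduced to its separating hyperplane, oriented so that
# positive decision values are evidence for the correct class, with the
# train-score normalization constant (max |raw decision value|).
fit_linear_svm <- function(x, y, cost = 1) {
  x <- as.matrix(x)
  m <- e1071::svm(x = x, y = y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(crossprod(m$coefs, m$SV))
  b <- -m$rho
  dv <- drop(x %*% w) + b
  if (mean(dv[y == "correct"]) < mean(dv[y == "erroneous"])) {
    w <- -w; b <- -b; dv <- -dv
  }
  scale <- max(abs(dv))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  list(w = unname(w), b = unname(b), scale = scale)
}

svm_score <- function(svm, x) {
  (drop(as.matrix(x) %*% svm$w) + svm$b) / svm$scale
}

detector_features <- function(object, epochs) {
  out <- list()
  if (!is.null(object$filter)) {
    fe <- apply_dsp(object$filter, epochs)
    out$eeg <- apply_znorm(fe, object$norm$eeg)
  }
  if (!is.null(object$norm$gaze)) {
    gf <- as.matrix(gaze_feature_vector(epochs)[c("activity", "mobility", "complexity")])
    out$gaze <- apply_znorm(gf, object$norm$gaze)
  }
  out
}

#' Normalized detector scores
#'
#' Raw SVM decision values divided by the training scale constant, so
#' training scores lie in \[-1, 1\] (test scores may exceed that range and
#' are not clipped). Positive scores are evidence for a correct press,
#' negative for an erroneous one. For late fusion the per-press decision is
#' carried by the dominant modality: the one with the larger absolute
#' score (ties go to EEG).
#'
#' @param object A fitted [fit_detector()] bundle.
#' @param epochs An [epoch_set()].
#' @return Tibble, one row per epoch: per-modality score columns, the
#'   decision `score`, and (for late fusion) the dominant `modality`.
#' @export
score_epochs <- function(object, epochs) {
  stopifnot(inherits(object, "eds_detector"))
  if (inherits(epochs, "epoch_set") &&
      !identical(dim(epochs$eeg)[1], object$filter$channels %||% dim(epochs$eeg)[1])) {
    abort("channel mismatch")
  }
  f <- detector_features(object, epochs)
  switch(object$mode,
    eeg = {
      s <- svm_score(object$svms$eeg, f$eeg)
      tibble(score_eeg = s, score = s)
    },
    gaze = {
      s <- svm_score(object$svms$gaze, f$gaze)
      tibble(score_gaze = s, score = s)
    },
    early = {
      s <- svm_score(object$svms$early, cbind(f$eeg, f$gaze))
      tibble(score_early = s, score = s)
    },
    late = {
      se <- svm_score(object$svms$eeg, f$eeg)
      sg <- svm_score(object$svms$gaze, f$gaze)
      dominant <- ifelse(abs(sg) > abs(se), "gaze", "eeg")
      tibble(score_eeg = se, score_gaze = sg, modality = dominant,
             score = ifelse(dominant == "gaze", sg, se))
    }
  )
}

#' Classify epochs at a decision threshold
#'
#' An epoch is classified erroneous when its decision score is at or below
#' `theta` (for late fusion, the dominant modality's score). Raising
#' `theta` trades specificity for sensitivity; `theta = -1` is the most
#' conservative setting on the training scale.
#'
#' @param object A fitted [fit_detector()] bundle.
#' @param epochs An [epoch_set()].
#' @param theta Threshold in \[-1, 1\]; defaults to the fitted bundle's.
#' @return Factor of predicted labels, levels `correct`, `erroneous`.
#' @export
classify_epochs <- function(object, epochs, theta = object$theta) {
  if (!is_scalar_number(theta) || theta < -1 || theta > 1) {
    abort("invalid threshold: theta must lie in [-1, 1]")
  }
  sc <- score_epochs(object, epochs)
  factor(ifelse(sc$score <= theta, "erroneous", "correct"),
         levels = c("correct", "erroneous"))
}

#' @export
#' @rdname classify_epochs
#' @param ... Passed on.
#' @param type `"label"` (default) or `"score"`.
predict.eds_detector <- function(object, epochs, theta = object$theta,
                                 type = c("label", "score"), ...) {
  type <- match.arg(type)
  if (type == "score") score_epochs(object, epochs) else
    classify_epochs(object, epochs, theta)
}

#' @export
print.eds_detector <- function(x, ...) {
  cat(sprintf("<eds_detector> mode %s, %d training epochs (%d correct / %d erroneous)\n",
              x$mode, x$n_train, x$class_counts$correct %||% 0,
              x$class_counts$erroneous %||% 0))
  cat(sprintf("  theta = %g; SVMs: %s\n", x$theta,
              paste(names(x$svms), collapse = ", ")))
  invisible(x)
}
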