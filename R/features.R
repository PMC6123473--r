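#' Fit a Discriminant Spatial Pattern (DSP) filter
#'
#' Finds the channel weighting `w` that maximizes the Fisher separability
#' ratio between the energy of the class-mean difference and the pooled
#' within-class (noise) covariance:
#' the leading generalized eigenvector of
#' `(Xbar - Ybar)(Xbar - Ybar)^T w = lambda (Cx + Cy + eps I) w`,
#' where `Xbar`, `Ybar` are the class-average channels x time responses over
#' the full epoch window and `Cx`, `Cy` the average spatial covariances of
#' the epochs after subtracting their class mean. `w` is unit-norm with its
#' sign fixed so that the time-summed projection of `Xbar - Ybar` is
#' non-negative. A small Tikhonov ridge (`eps = eps_scale * trace/channels`)
#' keeps the noise pool invertible; single-channel data yield the scalar
#' filter 1.
#'
#' @param error_epochs,correct_epochs 3-d arrays, channels x time x epoch
#'   (>= 2 epochs per class), on the same channel set, spanning the full
#'   epoch window.
#' @param eps_scale Relative ridge strength (default `1e-6`).
#' @return Object of class `dsp_filter`: `w`, `Xbar`, `Ybar`, `Cx`, `Cy`,
#'   `fisher_value`, `channels` (channel count), `channel_names` when known.
#' @export
fit_dsp <- function(error_epochs, correct_epochs, eps_scale = 1e-6) {
  x <- check_epoch_array(error_epochs, "error_epochs")
  y <- check_epoch_array(correct_epochs, "correct_epochs")
  if (dim(x)[1] != dim(y)[1] || dim(x)[2] != dim(y)[2]) {
    abort("error and correct epochs must share channels and samples")
  }
  nch <- dim(x)[1]
  xbar <- rowMeans(x, dims = 2)
  ybar <- rowMeans(y, dims = 2)
  cx <- class_noise_cov(x, xbar)
  cy <- class_noise_cov(y, ybar)

  d <- xbar - ybar
  s <- tcrossprod(d)
  b <- cx + cy
  eps <- eps_scale * sum(diag(b)) / nch
  if (eps <= 0) eps <- eps_scale  # fully degenerate noise pool
  breg <- b + diag(eps, nch)

  if (nch == 1) {
    w <- 1
  } else {
    eb <- eigen(breg, symmetric = TRUE)
    whiten <- eb$vectors %*% (t(eb$vectors) / sqrt(pmax(eb$values, eps * 1e-6)))
    em <- eigen(whiten %*% s %*% whiten, symmetric = TRUE)
    w <- drop(whiten %*% em$vectors[, 1])
    w <- w / sqrt(sum(w^2))
  }
  if (sum(w * rowSums(d)) < 0) w <- -w

  fisher <- drop(crossprod(w, s %*% w) / crossprod(w, breg %*% w))
  structure(
    list(w = w, Xbar = xbar, Ybar = ybar, Cx = cx, Cy = cy,
         fisher_value = fisher, channels = nch,
         channel_names = dimnames(x)[[1]]),
    class = "dsp_filter"
  )
}

check_epoch_array <- function(a, name) {
  if (inherits(a, "epoch_set")) a <- a$eeg
  if (length(dim(a)) != 3) abort(sprintf("`%s` must be a channels x time x epoch array", name))
  if (dim(a)[3] < 2) abort(sprintf("`%s` needs at least 2 epochs", name))
  a
}

# Average over epochs of the spatial covariance (over time) of the epoch
# after subtracting the class mean; population normalization.
class_noise_cov <- function(arr, class_mean) {
  nch <- dim(arr)[1]; nt <- dim(arr)[2]; n <- dim(arr)[3]
  centered <- arr - as.vector(class_mean)  # recycles over the epoch dim
  big <- matrix(centered, nch)
  tcrossprod(big) / (nt * n)
}

# Regularized Fisher ratio of a candidate direction; the objective fit_dsp
# maximizes.
dsp_objective <- function(filter, w) {
  d <- filter$Xbar - filter$Ybar
  s <- tcrossprod(d)
  b <- filter$Cx + filter$Cy
  eps <- 1e-6 * sum(diag(b)) / filter$channels
  drop(crossprod(w, s %*% w) / crossprod(w, (b + diag(eps, filter$channels)) %*% w))
}

#' @export
print.dsp_filter <- function(x, ...) {
  cat(sprintf("<dsp_filter> %d channels, Fisher value %.4g\n",
              x$channels, x$fisher_value))
  invisible(x)
}

#' Apply a DSP filter: the virtual-sensor feature vector
#'
#' Projects each epoch through `w` and keeps only the post-onset part of the
#' window, \[0, 0.5) s -- 128 samples at 256 Hz: the spatial filter is fitted
#' on the full window but activated only after the key registration.
#'
#' @param filter A fitted [fit_dsp()] object.
#' @param epochs An [epoch_set()] or a channels x time x epoch array (or a
#'   single channels x time matrix) spanning the full epoch window.
#' @param rate EEG sampling rate; taken from the epoch set when available.
#' @param window Epoch window; taken from the epoch set when available.
#' @return Numeric matrix, epoch x feature (`floor(end * rate)` columns).
#' @export
apply_dsp <- function(filter, epochs, rate = 256, window = c(-0.2, 0.5)) {
  stopifnot(inherits(filter, "dsp_filter"))
  if (inherits(epochs, "epoch_set")) {
    rate <- epochs$eeg_rate
    window <- epochs$window
    epochs <- epochs$eeg
  }
  if (length(dim(epochs)) == 2) epochs <- array(epochs, c(dim(epochs), 1))
  if (dim(epochs)[1] != filter$channels) abort("channel mismatch")
  pre <- as.integer(floor(-window[1] * rate + 1e-9))
  post <- as.integer(floor(window[2] * rate + 1e-9))
  if (dim(epochs)[2] < pre + post) abort("epochs shorter than the fit window")
  nch <- dim(epochs)[1]; n <- dim(epochs)[3]
  seg <- epochs[, (pre + 1):(pre + post), , drop = FALSE]
  big <- matrix(seg, nch)            # columns: time within epoch, then epoch
  proj <- drop(filter$w %*% big)
  t(matrix(proj, post, n))
}

#' Hjorth descriptors of a time series
#'
#' Activity is the population variance of the series; mobility is the
#' square root of the variance ratio of the first derivative to the series;
#' complexity is the mobility of the derivative over the mobility of the
#' series. Derivatives are forward first differences scaled by the sampling
#' rate. A constant series is degenerate (activity 0, mobility/complexity
#' undefined); a series with a constant derivative has mobility 0 and an
#' undefined complexity.
#'
#' @param series Numeric vector, length >= 3.
#' @param rate Sampling rate (Hz) of the series.
#' @return One-row tibble: `activity`, `mobility`, `complexity`,
#'   `degenerate` (logical; `TRUE` when any descriptor is undefined;
#'   undefined entries are `NaN`).
#' @export
hjorth_descriptors <- function(series, rate = 30) {
  if (length(series) < 3) abort("series must have at least 3 samples")
  v0 <- pop_var(series)
  if (v0 == 0) {
    return(tibble(activity = 0, mobility = NaN, complexity = NaN,
                  degenerate = TRUE))
  }
  d1 <- diff(series) * rate
  v1 <- pop_var(d1)
  mobility <- sqrt(v1 / v0)
  if (v1 == 0) {
    return(tibble(activity = v0, mobility = 0, complexity = NaN,
                  degenerate = TRUE))
  }
  d2 <- diff(d1) * rate
  v2 <- pop_var(d2)
  complexity <- sqrt(v2 / v1) / mobility
  tibble(activity = v0, mobility = mobility, complexity = complexity,
         degenerate = FALSE)
}

#' Gaze feature vectors: Hjorth descriptors of the distance series
#'
#' Applies [hjorth_descriptors()] to every epoch's accumulated-distance
#' series. Degenerate epochs (constant series or constant derivative) map to
#' zero-filled undefined entries with the degeneracy indicator set, so the
#' downstream classifiers always receive finite features.
#'
#' @param epochs An [epoch_set()], or a matrix epoch x sample of distance
#'   series.
#' @param rate Gaze sampling rate; taken from the epoch set when available.
#' @return Tibble with one row per epoch: `activity`, `mobility`,
#'   `complexity` (finite), `degenerate`.
#' @export
gaze_feature_vector <- function(epochs, rate = 30) {
  if (inherits(epochs, "epoch_set")) {
    rate <- epochs$gaze_rate
    epochs <- epochs$distance
  }
  if (is.null(dim(epochs))) epochs <- matrix(epochs, nrow = 1)
  out <- dplyr::bind_rows(lapply(seq_len(nrow(epochs)), function(i) {
    hjorth_descriptors(epochs[i, ], rate)
  }))
  bad <- !is.finite(out$mobility) | !is.finite(out$complexity)
  out$degenerate <- out$degenerate | bad
  out$mobility[!is.finite(out$mobility)] <- 0
  out$complexity[!is.finite(out$complexity)] <- 0
  out
}
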