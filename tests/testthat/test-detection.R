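test_that("SMOTE balances counts and synthesizes on minority segments", {
  withr::local_seed(1)
  x <- matrix(rnorm(12 * 5), 12, 5)
  out <- smote_oversample(x, 30, k = 5, seed = 2)
  expect_equal(nrow(out), 30)
  expect_equal(attr(out, "n_original"), 12)
  syn <- out[13:30, , drop = FALSE]
  par <- attr(out, "parents"); nbr <- attr(out, "neighbours"); u <- attr(out, "u")
  dm <- as.matrix(dist(x))
  for (j in seq_len(nrow(syn))) {
    seg <- x[nbr[j], ] - x[par[j], ]
    resid <- syn[j, ] - x[par[j], ] - u[j] * seg
    expect_lt(max(abs(resid)), 1e-9)           # collinear and between
    expect_true(u[j] >= 0 && u[j] <= 1)
    # the neighbour is one of the parent's 5 nearest minority points
    expect_true(nbr[j] %in% order(dm[par[j], ])[2:6])
  }
})

test_that("SMOTE edge cases: balanced input, tiny minorities, bad target", {
  x <- matrix(1:10, 5, 2)
  expect_equal(nrow(smote_oversample(x, 5)), 5)       # target = n: no synthetics
  expect_error(smote_oversample(x, 3), "target below minority size")
  expect_warning(out1 <- smote_oversample(x[1, , drop = FALSE], 4, seed = 1),
                 "duplication")
  expect_true(all(apply(out1, 1, identical, out1[1, ])))
  # k reduced to n - 1 when n <= k: all neighbours drawn from the other 2 rows
  out3 <- smote_oversample(matrix(rnorm(9), 3), 10, k = 5, seed = 3)
  expect_true(all(attr(out3, "neighbours") %in% 1:3))
  # determinism
  a <- smote_oversample(x, 9, seed = 7)
  b <- smote_oversample(x, 9, seed = 7)
  expect_identical(a, b)
})

test_that("detectors separate the high-snr fixture perfectly at theta 0", {
  ep <- fixture_epochs()
  for (mode in c("eeg", "early", "late")) {
    det <- fit_detector(ep, mode, seed = 5)
    pred <- classify_epochs(det, ep, theta = 0)
    m <- confusion_metrics(pred, ep$label)
    expect_equal(m$sensitivity, 1)
    expect_gt(m$specificity, 0.95)
  }
  # the gaze modality is sensitivity-heavy: small post-press movement flags
  # errors well, but adjacent-key sentences blur specificity
  det_g <- fit_detector(ep, "gaze", seed = 5)
  m_g <- confusion_metrics(classify_epochs(det_g, ep, 0), ep$label)
  expect_gte(m_g$sensitivity, 0.9)
  expect_gt(m_g$specificity, 0.5)
})

test_that("early fusion concatenates 128 EEG + 3 Hjorth features", {
  det <- fixture_detector("early")
  expect_equal(length(det$svms$early$w), 131)
  expect_equal(length(fixture_detector("eeg")$svms$eeg$w), 128)
  expect_equal(length(fixture_detector("late")$svms$gaze$w), 3)
})

test_that("refitting with an identical seed reproduces the bundle", {
  ep <- fixture_epochs()
  a <- fit_detector(ep, "late", seed = 42)
  b <- fit_detector(ep, "late", seed = 42)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("single-class training is rejected", {
  ep <- fixture_epochs()
  only_cor <- ep[ep$label == "correct"]
  expect_error(fit_detector(only_cor, "eeg"), "degenerate training set")
})

test_that("scores match an independent recomputation from stored weights", {
  ep <- fixture_epochs()
  det <- fixture_detector("late")
  sc <- score_epochs(det, ep)
  # oracle: rebuild features and apply the linear forms by hand
  fe <- apply_dsp(det$filter, ep)
  fe_n <- sweep(sweep(fe, 2, det$norm$eeg$mean), 2, det$norm$eeg$sd, "/")
  s_eeg <- (drop(fe_n %*% det$svms$eeg$w) + det$svms$eeg$b) / det$svms$eeg$scale
  expect_equal(sc$score_eeg, s_eeg, tolerance = 1e-12)
  gf <- as.matrix(gaze_feature_vector(ep)[c("activity", "mobility", "complexity")])
  gf_n <- sweep(sweep(gf, 2, det$norm$gaze$mean), 2, det$norm$gaze$sd, "/")
  s_gaze <- (drop(gf_n %*% det$svms$gaze$w) + det$svms$gaze$b) / det$svms$gaze$scale
  expect_equal(sc$score_gaze, unname(s_gaze), tolerance = 1e-12)
})

test_that("training scores span [-1, 1] and hit +/-1 at the scale-setting epoch", {
  ep <- fixture_epochs()
  det <- fixture_detector("eeg")
  sc <- score_epochs(det, ep)$score
  # the detector was trained on augmented data; real training epochs stay within
  expect_lte(max(abs(sc)), 1 + 1e-9)
})

test_that("threshold semantics: extremes flip all predictions", {
  ep <- fixture_epochs()
  det <- fixture_detector("late")
  sc <- score_epochs(det, ep)$score
  th_lo <- max(-1, min(sc) - 0.01)
  if (min(sc) > th_lo) {
    expect_true(all(classify_epochs(det, ep, th_lo) == "correct"))
  }
  if (max(sc) <= 1) {
    expect_true(all(classify_epochs(det, ep, 1) == "erroneous" | sc > 1))
  }
  expect_error(classify_epochs(det, ep, 1.2), "invalid threshold")
})

test_that("late fusion equals the dominant-score oracle", {
  ep <- fixture_epochs()
  det <- fixture_detector("late")
  sc <- score_epochs(det, ep)
  theta <- -0.3
  oracle <- ifelse(
    ifelse(abs(sc$score_gaze) > abs(sc$score_eeg), sc$score_gaze, sc$score_eeg)
    <= theta, "erroneous", "correct")
  expect_identical(as.character(classify_epochs(det, ep, theta)), oracle)
  expect_identical(sc$modality,
                   ifelse(abs(sc$score_gaze) > abs(sc$score_eeg), "gaze", "eeg"))
})

test_that("fitting never touches held-out epochs", {
  ep <- fixture_epochs()
  err <- which(ep$label == "erroneous"); corr <- which(ep$label == "correct")
  test_i <- c(err[1:4], corr[1:30])
  train <- ep[-test_i]
  det1 <- fit_detector(train, "late", seed = 9)
  # corrupt every test label and every test feature, refit identically
  ep2 <- ep
  ep2$label[test_i] <- factor(
    ifelse(ep$label[test_i] == "correct", "erroneous", "correct"),
    levels = c("correct", "erroneous"))
  ep2$eeg[, , test_i] <- 0
  ep2$distance[test_i, ] <- 0
  det2 <- fit_detector(ep2[-test_i], "late", seed = 9)
  expect_identical(serialize(det1, NULL), serialize(det2, NULL))
})

test_that("degenerate (constant-gaze) epochs still classify", {
  ep <- fixture_epochs()
  flat <- ep[1:12]
  flat$distance[, ] <- 0
  flat$label <- factor(rep(c("correct", "erroneous"), 6),
                       levels = c("correct", "erroneous"))
  det <- fit_detector(flat, "gaze", seed = 2)
  pred <- classify_epochs(det, flat)
  expect_equal(length(pred), 12)
  expect_false(anyNA(pred))
})
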