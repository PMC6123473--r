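long_sentence <- function(n_words = 60) {
  words <- c("the", "quick", "brown", "fox", "jumps", "over", "a", "lazy",
             "dog", "while", "rain", "falls", "on", "old", "roofs")
  paste0(paste(rep(words, length.out = n_words), collapse = " "), ".")
}

test_that("typing simulation matches the error-aware protocol", {
  spec0 <- small_spec(p = 0)
  out <- simulate_typing("my dog is brown.", spec0, seed = 1)
  expect_identical(paste(out$typed, collapse = ""), "my dog is brown.")
  expect_false(any(out$events$truth_error))
  expect_true(all(diff(out$events$onset) >= spec0$dwell))

  # intended is always a subsequence of typed; labels recover the truth
  spec <- small_spec(p = 0.25)
  out2 <- simulate_typing(long_sentence(20), spec, seed = 2)
  lab <- label_key_events(long_sentence(20), out2$typed)
  expect_identical(lab == "erroneous", out2$events$truth_error)
})

test_that("insertion fraction is binomial at rate p", {
  spec <- small_spec(p = 0.1)
  sent <- long_sentence(2000)  # ~10,000 presses
  out <- simulate_typing(sent, spec, seed = 33)
  n <- nrow(out$events)
  expect_gt(n, 9000)
  frac <- mean(out$events$truth_error)
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(frac - 0.1), 3 * se)
})

test_that("regular-control mode corrects every typo with a backspace", {
  spec <- small_spec(p = 0.2)
  out <- simulate_typing(long_sentence(30), spec, "regular-control", seed = 4)
  ev <- out$events
  after_error <- which(ev$truth_error) + 1
  expect_true(all(ev$key[after_error] == "BACKSPACE"))
  expect_identical(out$committed, long_sentence(30))
  expect_error(sim_spec(p = 0.5), "error rate too high")
})

test_that("ERP templates have the class-specific biphasic morphology", {
  spec <- small_spec()
  err <- make_erp_template("error", spec)
  cor <- make_erp_template("correct", spec)
  tt <- (seq_len(ncol(err$waveform)) - 1) / spec$eeg_rate
  dom_e <- err$waveform[match(err$dominant_channel, err$channels), ]
  expect_true(tt[which.min(dom_e)] >= 0.25 && tt[which.min(dom_e)] <= 0.35)
  expect_true(tt[which.max(dom_e)] >= 0.35 && tt[which.max(dom_e)] <= 0.45)
  dom_c <- cor$waveform[match(cor$dominant_channel, cor$channels), ]
  expect_true(tt[which.max(dom_c)] >= 0.15 && tt[which.max(dom_c)] <= 0.25)
  expect_true(tt[which.min(dom_c)] >= 0.25 && tt[which.min(dom_c)] <= 0.35)

  expect_identical(err, make_erp_template("error", spec))  # deterministic
  expect_error(make_erp_template("wiggly", spec), "unknown kind")
})

test_that("event-locked averaging recovers the template at high snr", {
  spec <- small_spec(p = 0.4, snr = 10)
  sent <- long_sentence(60)
  s <- simulate_session(sent, spec, seed = 7)
  ep <- epochize(s)  # unfiltered: template shape must survive averaging
  err <- ep$label == "erroneous"
  expect_gt(sum(err), 100)
  tpl <- make_erp_template("error", spec)
  dom <- match(tpl$dominant_channel, ep$channel_names)
  post <- (179 - 128 + 1):179
  avg <- rowMeans(ep$eeg[dom, post, err])
  expect_gt(cor(avg, tpl$waveform[match(tpl$dominant_channel, tpl$channels), ]),
            0.95)
})

test_that("snr = 0 leaves no event-locked class difference", {
  spec <- small_spec(p = 0.4, snr = 0)
  s <- simulate_session(long_sentence(40), spec, seed = 8)
  ep <- epochize(s)
  err <- which(ep$label == "erroneous"); cor_i <- which(ep$label == "correct")
  d <- rowMeans(ep$eeg[, , err, drop = FALSE], dims = 2) -
    rowMeans(ep$eeg[, , cor_i, drop = FALSE], dims = 2)
  floor_rms <- spec$noise_scale * sqrt(1 / length(err) + 1 / length(cor_i))
  expect_lt(sqrt(mean(d^2)), 2.5 * floor_rms)
})

test_that("post-press gaze displacement separates correct from erroneous", {
  spec <- small_spec(p = 0.3)
  typ <- simulate_typing(long_sentence(120), spec, seed = 10)
  expect_gt(nrow(typ$events), 500)
  gaze <- simulate_gaze(typ$events, spec, seed = 11)
  disp <- vapply(seq_len(nrow(typ$events)), function(i) {
    w <- gaze$t >= typ$events$onset[i] & gaze$t < typ$events$onset[i] + 0.5
    sum(sqrt(diff(gaze$x[w])^2 + diff(gaze$y[w])^2))
  }, 0)
  expect_gt(mean(disp[!typ$events$truth_error]),
            mean(disp[typ$events$truth_error]))
})

test_that("degenerate gaze settings produce the expected traces", {
  spec <- small_spec(jitter_sd = 0, fixation_offset_sd = 0)
  ev <- tibble::tibble(onset = 1, key = "g", index = 0L, target = "g",
                       truth_error = FALSE, press_type = "letter")
  gaze <- simulate_gaze(ev, spec, seed = 1, duration = 2)
  expect_equal(sd(gaze$x), 0)  # stationary target, no jitter: constant gaze
  expect_equal(sd(gaze$y), 0)

  spec_j <- small_spec(jitter_sd = 2, fixation_offset_sd = 0)
  gaze_j <- simulate_gaze(ev, spec_j, seed = 2, duration = 2)
  w <- gaze_j$t >= 1 & gaze_j$t < 1.5
  path <- sum(sqrt(diff(gaze_j$x[w])^2 + diff(gaze_j$y[w])^2))
  # pure jitter: path of ~15 steps of N(0, 2) increments stays small
  expect_lt(path, 15 * 4 * 2 * sqrt(2))
})

test_that("ground-truth error flags equal pipeline labels on every session", {
  spec <- small_spec(p = 0.15)
  for (i in 1:8) {
    s <- simulate_session(example_sentences(8)[i], spec, seed = 400 + i)
    ep <- preprocess_session(s)
    expect_identical(ep$label == "erroneous", letter_events(s)$truth_error)
  }
})

test_that("identical spec and seed reproduce a session bit-identically", {
  a <- simulate_session("my dog is brown.", small_spec(), seed = 99)
  b <- simulate_session("my dog is brown.", small_spec(), seed = 99)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- simulate_session("my dog is brown.", small_spec(), seed = 100)
  expect_false(identical(a$eeg$samples, c2$eeg$samples))
})

test_that("detector accuracy is monotone in snr (3-seed majority)", {
  snrs <- c(0, 1, 3, 10)
  acc <- matrix(NA_real_, 3, length(snrs))
  for (si in 1:3) {
    for (ki in seq_along(snrs)) {
      spec <- small_spec(p = 0.25, snr = snrs[ki])
      sess <- simulate_sessions(example_sentences(4), spec, seed = 500 + si)
      ep <- preprocess_sessions(sess)
      err <- which(ep$label == "erroneous"); corr <- which(ep$label == "correct")
      test_i <- c(err[seq(1, length(err), by = 2)],
                  corr[seq(1, length(corr), by = 2)])
      det <- fit_detector(ep[-test_i], "eeg", seed = 1)
      pred <- classify_epochs(det, ep[test_i])
      acc[si, ki] <- mean(pred == ep$label[test_i])
    }
  }
  for (ki in seq_len(length(snrs) - 1)) {
    n_ok <- sum(acc[, ki + 1] >= acc[, ki] - 0.02)
    expect_gte(n_ok, 2)
  }
})
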