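#' Simulation specification for synthetic typing sessions
#'
#' Collects every dial of the synthetic-session generator. The defaults are
#' the study conditions this package models: a dwell-time qwerty keyboard
#' sampled at 30 Hz by the eye tracker and 256 Hz by a 64-channel EEG
#' amplifier, a per-press mistype probability of 0.1 (roughly one typo in
#' ten characters), spatially mixed 1/f background EEG, and event-locked
#' templates whose morphology follows the error-related potential: a
#' frontocentral negativity near 300 ms followed by a centro-parietal
#' positivity near 400 ms after an erroneous registration, and a central
#' biphasic response (positive near 200 ms, negative near 300 ms) after a
#' correct one.
#'
#' @param p Per-press mistype probability, in \[0, 0.5).
#' @param snr Template-to-noise amplitude ratio (>= 0): peak template
#'   amplitude divided by per-channel noise RMS. 0 means no event-locked
#'   signal.
#' @param n_channels Number of EEG channels (<= 64, midline-first subset of
#'   the 10-10 montage).
#' @param eeg_rate,gaze_rate Sampling rates (Hz).
#' @param dwell Dwell time (s) for key registration.
#' @param noise_exponent Spectral exponent of the 1/f background noise.
#' @param noise_scale Per-channel noise RMS in microvolts.
#' @param saccade_speed Saccade speed (px/s) of post-registration gaze moves.
#' @param jitter_sd Per-sample fixation jitter SD (px).
#' @param fixation_offset_sd SD (px) of the per-fixation offset from the key
#'   centre.
#' @param letter_overhead,backspace_overhead Length-2 vectors
#'   `c(meanlog, sdlog)` of the log-normal inter-key overhead (time beyond
#'   the dwell) for letter and backspace presses; backspace is slower by
#'   default.
#' @param gaze_informative If `FALSE`, the gaze stream is pure fixation
#'   jitter, carrying no information about typing outcomes (a null-control
#'   dial for the gaze modality).
#' @param key_pitch Keyboard key pitch in px.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(p = 0.1,
                     snr = 10,
                     n_channels = 64,
                     eeg_rate = 256,
                     gaze_rate = 30,
                     dwell = 0.5,
                     noise_exponent = 1,
                     noise_scale = 10,
                     saccade_speed = 1500,
                     jitter_sd = 4,
                     fixation_offset_sd = 8,
                     letter_overhead = c(meanlog = log(0.35), sdlog = 0.35),
                     backspace_overhead = c(meanlog = log(0.6), sdlog = 0.35),
                     gaze_informative = TRUE,
                     key_pitch = 100) {
  spec <- list(p = p, snr = snr, n_channels = as.integer(n_channels),
               eeg_rate = eeg_rate, gaze_rate = gaze_rate, dwell = dwell,
               noise_exponent = noise_exponent, noise_scale = noise_scale,
               saccade_speed = saccade_speed, jitter_sd = jitter_sd,
               fixation_offset_sd = fixation_offset_sd,
               letter_overhead = letter_overhead,
               backspace_overhead = backspace_overhead,
               gaze_informative = isTRUE(gaze_informative),
               key_pitch = key_pitch)
  if (!is_scalar_number(spec$p) || spec$p < 0 || spec$p >= 0.5) {
    abort("error rate too high for correction model: p must lie in [0, 0.5)")
  }
  if (!is_scalar_number(spec$snr) || spec$snr < 0) abort("snr must be >= 0")
  if (spec$dwell <= 0) abort("dwell must be positive")
  if (spec$n_channels < 1 || spec$n_channels > 64) abort("n_channels must be 1-64")
  class(spec) <- "sim_spec"
  spec
}

#' On-screen qwerty keyboard layout
#'
#' Key centres in screen pixels (origin top-left, y downward), including
#' space, full stop and a backspace key. Used both for synthesizing gaze
#' traces and for drawing wrong keys from the neighbourhood of a target.
#'
#' @param pitch Key pitch in px.
#' @return Tibble with columns `key`, `x`, `y`.
#' @export
keyboard_layout <- function(pitch = 100) {
  rows <- list(
    list(keys = strsplit("qwertyuiop", "")[[1]], off = 0),
    list(keys = strsplit("asdfghjkl", "")[[1]], off = 0.5),
    list(keys = c(strsplit("zxcvbnm", "")[[1]], "."), off = 1)
  )
  tabs <- lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    tibble(key = r$keys,
           x = 60 + (seq_along(r$keys) - 1 + r$off) * pitch,
           y = 250 + (i - 1) * pitch)
  })
  out <- dplyr::bind_rows(tabs)
  dplyr::bind_rows(
    out,
    tibble(key = " ", x = 60 + 4.5 * pitch, y = 250 + 3 * pitch),
    tibble(key = "BACKSPACE", x = 60 + 10.5 * pitch, y = 250 - pitch)
  )
}

key_position <- function(layout, key) {
  i <- match(key, layout$key)
  if (anyNA(i)) {
    abort(sprintf("key(s) not on the keyboard: %s",
                  paste(unique(key[is.na(i)]), collapse = ", ")))
  }
  cbind(layout$x[i], layout$y[i])
}

# Wrong-key candidates: keys within 1.5 key pitches of the target
# (the 8-neighbourhood on the staggered grid), backspace excluded.
key_neighbours <- function(layout, key, pitch) {
  p0 <- key_position(layout, key)
  d <- sqrt((layout$x - p0[1])^2 + (layout$y - p0[2])^2)
  cand <- layout$key[d > 1e-9 & d <= 1.5 * pitch & layout$key != "BACKSPACE"]
  if (!length(cand)) cand <- setdiff(layout$key, c(key, "BACKSPACE"))
  cand
}

#' Example study sentences
#'
#' Twenty short lower-case sentences ending in a full stop, in the spirit of
#' the memorize-and-type protocol. All characters are typable on
#' [keyboard_layout()].
#'
#' @param n Number of sentences (1--20).
#' @return Character vector.
#' @export
example_sentences <- function(n = 20) {
  s <- c(
    "my dog is brown.",
    "the sun rises early.",
    "birds sing in spring.",
    "we walk to the park.",
    "coffee keeps me awake.",
    "rain fell all night.",
    "she reads old books.",
    "the cat sleeps a lot.",
    "music makes me calm.",
    "bread smells so good.",
    "he paints small boats.",
    "stars shine at night.",
    "the train was on time.",
    "apples taste sweet.",
    "children play outside.",
    "the lake is frozen.",
    "i like quiet rooms.",
    "wind moves the trees.",
    "snow covers the roof.",
    "dinner is almost ready."
  )
  if (!is_scalar_number(n) || n < 1 || n > length(s)) {
    abort(sprintf("`n` must be between 1 and %d", length(s)))
  }
  s[seq_len(n)]
}

#' Build a synthetic event-related template
#'
#' Deterministic class-specific EEG templates spanning \[0, 0.5) s at the
#' EEG rate, built as sums of Gaussian-windowed bumps with fixed spatial
#' weight profiles over the montage. The error template has a negative
#' extremum near 0.30 s (frontocentral profile) followed by a positive one
#' near 0.40 s (centro-parietal profile); the correct template has a
#' positive extremum near 0.20 s and a negative one near 0.30 s (central
#' profile). Waveforms are peak-normalized to unit absolute amplitude.
#'
#' @param kind `"error"` or `"correct"`.
#' @param spec A [sim_spec()].
#' @return List of class `erp_template`: `kind`, `waveform` (channels x
#'   time), `channels`, `rate`, `dominant_channel`.
#' @export
make_erp_template <- function(kind, spec = sim_spec()) {
  if (!kind %in% c("error", "correct")) {
    abort(sprintf("unknown kind: %s", kind))
  }
  montage <- eeg_montage(spec$n_channels)
  nt <- floor(0.5 * spec$eeg_rate)
  tt <- (seq_len(nt) - 1) / spec$eeg_rate
  bump <- function(lat, sd = 0.04) exp(-(tt - lat)^2 / (2 * sd^2))
  if (kind == "error") {
    w_fc <- spatial_profile(montage, c(0, 0.35), sd = 0.5)
    w_cp <- spatial_profile(montage, c(0, -0.30), sd = 0.5)
    wave <- outer(w_fc, -1.0 * bump(0.30)) + outer(w_cp, 0.8 * bump(0.40))
  } else {
    w_c <- spatial_profile(montage, c(0, 0), sd = 0.45)
    wave <- outer(w_c, 0.7 * (bump(0.20) - bump(0.30)))
  }
  wave <- wave / max(abs(wave))
  dom <- which.max(apply(abs(wave), 1, max))
  out <- structure(
    list(kind = kind, waveform = wave, channels = montage$channel,
         rate = spec$eeg_rate, dominant_channel = montage$channel[dom]),
    class = "erp_template"
  )
  check_template_morphology(out)
  out
}

check_template_morphology <- function(tpl) {
  tt <- (seq_len(ncol(tpl$waveform)) - 1) / tpl$rate
  v <- tpl$waveform[match(tpl$dominant_channel, tpl$channels), ]
  in_win <- function(t0, t1) tt >= t0 & tt <= t1
  if (tpl$kind == "error") {
    ok <- in_win(0.25, 0.35)[which.min(v)] && in_win(0.35, 0.45)[which.max(v)]
  } else {
    ok <- in_win(0.15, 0.25)[which.max(v)] && in_win(0.25, 0.35)[which.min(v)]
  }
  if (!ok) abort("template morphology check failed")
  invisible(tpl)
}

#' Simulate the key-press stream of one sentence
#'
#' Each press of an intended character fails independently with probability
#' `p`, in which case a wrong key is drawn uniformly from the target's
#' keyboard neighbourhood and the press is retried. In the error-aware
#' recording protocol typos are simply ignored (the intended text is a
#' subsequence of the typed text); in the regular-control protocol every
#' typo is immediately followed by a backspace press, so the committed text
#' equals the intended text. Onsets accumulate dwell plus a log-normal
#' press-type-specific overhead.
#'
#' @param intended Intended sentence (typable on the layout).
#' @param spec A [sim_spec()].
#' @param mode `"error-aware-recording"` or `"regular-control"`.
#' @param seed Optional integer seed.
#' @return List with `events` (tibble: `onset`, `key`, `index`, `target`,
#'   `truth_error`, `press_type`), `typed` (letter presses, character
#'   vector) and `committed` (text after applying backspaces).
#' @export
simulate_typing <- function(intended, spec = sim_spec(),
                            mode = c("error-aware-recording", "regular-control"),
                            seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "sim_spec"))
  layout <- keyboard_layout(spec$key_pitch)
  chars <- strsplit(intended, "")[[1]]
  key_position(layout, unique(chars))  # errors early on untypable characters

  with_seed_or_current(seed, {
    keys <- character(0); targets <- character(0)
    truth <- logical(0); ptype <- character(0)
    for (ch in chars) {
      repeat {
        if (runif(1) < spec$p) {
          wrong <- sample(key_neighbours(layout, ch, spec$key_pitch), 1)
          keys <- c(keys, wrong); targets <- c(targets, ch)
          truth <- c(truth, TRUE); ptype <- c(ptype, "letter")
          if (mode == "regular-control") {
            keys <- c(keys, "BACKSPACE"); targets <- c(targets, ch)
            truth <- c(truth, FALSE); ptype <- c(ptype, "backspace")
          }
        } else {
          keys <- c(keys, ch); targets <- c(targets, ch)
          truth <- c(truth, FALSE); ptype <- c(ptype, "letter")
          break
        }
      }
    }
    overhead <- ifelse(
      ptype == "backspace",
      rlnorm(length(keys), spec$backspace_overhead[1], spec$backspace_overhead[2]),
      rlnorm(length(keys), spec$letter_overhead[1], spec$letter_overhead[2])
    )
    onsets <- cumsum(spec$dwell + overhead)
    events <- tibble(onset = onsets, key = keys,
                     index = seq_along(keys) - 1L, target = targets,
                     truth_error = truth, press_type = ptype)
    list(events = events,
         typed = keys[keys != "BACKSPACE"],
         committed = replay_keys(keys))
  })
}

#' Simulate the gaze stream for a press sequence
#'
#' The gaze fixates the to-be-pressed key throughout each dwell period.
#' After a registration it saccades (at `saccade_speed`) towards the next
#' pressed key: after a correct press that key is usually far away (the next
#' character of the sentence), while after a typo it is the nearby intended
#' key, producing only a small within-neighbourhood adjustment. Per-fixation
#' offsets and per-sample jitter are superimposed; sampling is at the gaze
#' rate. With `gaze_informative = FALSE` the trace is pure jitter around the
#' screen centre.
#'
#' @param events Event tibble from [simulate_typing()].
#' @param spec A [sim_spec()].
#' @param seed Optional integer seed.
#' @param duration Recording length (s); default one second past the last
#'   onset.
#' @return A [gaze_recording()].
#' @export
simulate_gaze <- function(events, spec = sim_spec(), seed = NULL,
                          duration = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  layout <- keyboard_layout(spec$key_pitch)
  if (is.null(duration)) {
    duration <- if (nrow(events)) max(events$onset) + 1 else 1
  }
  tg <- seq(0, duration, by = 1 / spec$gaze_rate)

  with_seed_or_current(seed, {
    if (!spec$gaze_informative || nrow(events) == 0) {
      ctr <- c(60 + 5 * spec$key_pitch, 250 + 1.5 * spec$key_pitch)
      x <- ctr[1] + rnorm(length(tg), 0, spec$jitter_sd)
      y <- ctr[2] + rnorm(length(tg), 0, spec$jitter_sd)
      return(gaze_recording(tg, x, y, rate = spec$gaze_rate))
    }
    pos <- key_position(layout, events$key)
    pos <- pos + matrix(rnorm(2 * nrow(pos), 0, spec$fixation_offset_sd),
                        ncol = 2)
    # Piecewise-linear knots: hold during each dwell, saccade to the next
    # fixation at saccade_speed, then hold again.
    kt <- c(); kx <- c(); ky <- c()
    add <- function(t, p) {
      if (length(kt) && t <= kt[length(kt)]) t <- kt[length(kt)] + 1e-6
      kt <<- c(kt, t); kx <<- c(kx, p[1]); ky <<- c(ky, p[2])
    }
    add(0, pos[1, ])
    n <- nrow(events)
    for (i in seq_len(n)) {
      add(events$onset[i] - spec$dwell, pos[i, ])
      add(events$onset[i], pos[i, ])
      if (i < n) {
        gap_end <- events$onset[i + 1] - spec$dwell
        dist <- sqrt(sum((pos[i + 1, ] - pos[i, ])^2))
        add(min(events$onset[i] + dist / spec$saccade_speed, gap_end),
            pos[i + 1, ])
      }
    }
    add(duration, pos[n, ])
    x <- stats::approx(kt, kx, xout = tg, rule = 2)$y +
      rnorm(length(tg), 0, spec$jitter_sd)
    y <- stats::approx(kt, ky, xout = tg, rule = 2)$y +
      rnorm(length(tg), 0, spec$jitter_sd)
    gaze_recording(tg, x, y, rate = spec$gaze_rate)
  })
}

# Spatially mixed 1/f noise: channels x n matrix, each channel RMS-normalized
# to spec$noise_scale.
coloured_noise <- function(n_channels, n, rate, exponent, scale) {
  sources <- matrix(0, n_channels, n)
  f <- (seq_len(n) - 1) / n * rate
  f <- pmin(f, rate - f)               # two-sided spectrum
  amp <- 1 / pmax(f, 1)^(exponent / 2) # 1 Hz floor keeps DC finite
  for (k in seq_len(n_channels)) {
    w <- fft(rnorm(n))
    sources[k, ] <- Re(fft(w * amp, inverse = TRUE)) / n
  }
  mix <- qr.Q(qr(matrix(rnorm(n_channels^2), n_channels)))
  out <- mix %*% sources
  rms <- sqrt(rowMeans(out^2))
  out * (scale / rms)
}

#' Simulate the EEG stream for a press sequence
#'
#' Spatially mixed 1/f background noise plus, at each letter registration,
#' the class-matching event-related template scaled so that its peak
#' amplitude is `snr` times the per-channel noise RMS. Backspace presses add
#' no event-locked signal.
#'
#' @param events Event tibble from [simulate_typing()] (needs
#'   `truth_error`, `press_type`).
#' @param spec A [sim_spec()].
#' @param seed Optional integer seed.
#' @param duration Recording length (s); default one second past the last
#'   onset.
#' @param templates Optional list with elements `error` and `correct`
#'   ([make_erp_template()]); built from `spec` when omitted.
#' @return An [eeg_recording()].
#' @export
simulate_eeg <- function(events, spec = sim_spec(), seed = NULL,
                         duration = NULL, templates = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  if (is.null(templates)) {
    templates <- list(error = make_erp_template("error", spec),
                      correct = make_erp_template("correct", spec))
  }
  for (tpl in templates) {
    if (tpl$rate != spec$eeg_rate) abort("template rate mismatch")
  }
  if (is.null(duration)) {
    duration <- if (nrow(events)) max(events$onset) + 1 else 1
  }
  n <- ceiling(duration * spec$eeg_rate)
  montage <- eeg_montage(spec$n_channels)

  with_seed_or_current(seed, {
    x <- coloured_noise(spec$n_channels, n, spec$eeg_rate,
                        spec$noise_exponent, spec$noise_scale)
    if (spec$snr > 0 && nrow(events)) {
      amp <- spec$snr * spec$noise_scale
      lev <- events[events$press_type != "backspace", , drop = FALSE]
      nt <- ncol(templates$error$waveform)
      for (i in seq_len(nrow(lev))) {
        tpl <- if (lev$truth_error[i]) templates$error else templates$correct
        i0 <- as.integer(ceiling(lev$onset[i] * spec$eeg_rate - 1e-9)) + 1L
        idx <- i0:(i0 + nt - 1L)
        keep <- idx <= n
        x[, idx[keep]] <- x[, idx[keep]] + amp * tpl$waveform[, keep]
      }
    }
    eeg_recording(x, rate = spec$eeg_rate, channel_names = montage$channel,
                  start_time = 0)
  })
}

#' Simulate a complete typing session
#'
#' Composes [simulate_typing()], [simulate_gaze()] and [simulate_eeg()]
#' into a validated [typing_session()]. Given the same `spec` and `seed`
#' the result is bit-identical.
#'
#' @inheritParams simulate_typing
#' @param subject_id,sentence_id Identifiers stored in the session.
#' @return A [typing_session()].
#' @export
simulate_session <- function(intended, spec = sim_spec(),
                             mode = c("error-aware-recording", "regular-control"),
                             seed = NULL, subject_id = "S01",
                             sentence_id = "s01") {
  mode <- match.arg(mode)
  seeds <- derive_seeds(seed, 3)
  typ <- simulate_typing(intended, spec, mode, seed = seeds[[1]])
  duration <- max(typ$events$onset) + 1
  gaze <- simulate_gaze(typ$events, spec, seed = seeds[[2]], duration = duration)
  eeg <- simulate_eeg(typ$events, spec, seed = seeds[[3]], duration = duration)
  typing_session(subject_id, sentence_id, intended, typ$events, eeg, gaze,
                 mode = mode, dwell = spec$dwell)
}

#' Simulate a set of sessions (one per sentence)
#'
#' @param sentences Character vector of intended sentences.
#' @inheritParams simulate_session
#' @return List of [typing_session()] objects, sentence ids `s01`, `s02`, ...
#' @export
simulate_sessions <- function(sentences, spec = sim_spec(),
                              mode = c("error-aware-recording", "regular-control"),
                              seed = NULL, subject_id = "S01") {
  mode <- match.arg(mode)
  seeds <- derive_seeds(seed, length(sentences))
  purrr::map2(sentences, seq_along(sentences), function(s, i) {
    simulate_session(s, spec, mode, seed = seeds[[i]],
                     subject_id = subject_id,
                     sentence_id = sprintf("s%02d", i))
  })
}
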