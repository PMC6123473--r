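# Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small but separable study: 8 channels, high snr, 6 sentences.
small_spec <- function(...) {
  do.call(sim_spec, utils::modifyList(list(n_channels = 8, snr = 10),
                                      list(...)))
}

fixture_sessions <- function() {
  cached("sessions", function() {
    simulate_sessions(example_sentences(6), small_spec(), seed = 42)
  })
}

fixture_epochs <- function() {
  cached("epochs", function() preprocess_sessions(fixture_sessions()))
}

fixture_detector <- function(mode = "late") {
  cached(paste0("detector_", mode), function() {
    fit_detector(fixture_epochs(), mode, seed = 11)
  })
}

# Hand-built epoch set with prescribed per-epoch EEG matrices and distance
# series; gaze traces are straight lines matching the distance increments.
toy_epoch_set <- function(eeg_list, distance = NULL, labels = NULL,
                          eeg_rate = 256, gaze_rate = 30,
                          window = c(-0.2, 0.5)) {
  n <- length(eeg_list)
  nch <- nrow(eeg_list[[1]])
  nt <- ncol(eeg_list[[1]])
  ng <- floor(-window[1] * gaze_rate) + floor(window[2] * gaze_rate)
  if (is.null(distance)) {
    distance <- matrix(rep(0:(ng - 1), each = n), n, ng)
  }
  if (is.null(labels)) labels <- rep(NA_character_, n)
  gaze_x <- t(apply(distance, 1, identity))  # distance realized along x
  epoch_set(
    eeg = array(unlist(eeg_list), c(nch, nt, n)),
    channel_names = paste0("ch", seq_len(nch)),
    eeg_rate = eeg_rate, gaze_rate = gaze_rate,
    gaze_x = gaze_x, gaze_y = matrix(0, n, ng),
    gaze_t = matrix(rep(seq(0, by = 1 / gaze_rate, length.out = ng), each = n), n, ng),
    distance = distance,
    label = labels,
    events = tibble::tibble(onset = seq_len(n), key = rep("a", n),
                            index = seq_len(n) - 1L),
    window = window
  )
}

# Independent dynamic-programming Levenshtein oracle (tests only).
dp_edit_distance <- function(a, b) {
  sa <- strsplit(a, "")[[1]]; sb <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(sa) + 1, length(sb) + 1)
  d[, 1] <- 0:length(sa); d[1, ] <- 0:length(sb)
  for (i in seq_along(sa)) {
    for (j in seq_along(sb)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (sa[i] != sb[j]))
    }
  }
  d[length(sa) + 1, length(sb) + 1]
}

# Uniform random unit vectors (columns), for grid maximization oracles.
random_unit_vectors <- function(d, n) {
  g <- matrix(rnorm(d * n), d, n)
  g / rep(sqrt(colSums(g^2)), each = d)
}
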