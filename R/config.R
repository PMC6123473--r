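#' Pipeline configuration
#'
#' Bundles the tunable parameters of the detection pipeline. Defaults follow
#' the recording protocol this package models: a 1--16 Hz zero-phase
#' band-pass for the EEG, epochs spanning \[-0.2, 0.5) s around each key
#' registration, a 0.5 s dwell time, 100 Monte-Carlo repetitions, SMOTE with
#' k = 5 neighbours, a linear SVM with cost 1 and a decision threshold of 0.
#'
#' @param band Length-2 numeric, band-pass edges in Hz (low < high).
#' @param window Length-2 numeric, epoch window in seconds relative to key
#'   registration (start < 0 < end).
#' @param dwell Dwell time in seconds.
#' @param smote_k Number of SMOTE nearest neighbours.
#' @param svm_cost Linear SVM cost parameter C.
#' @param theta Decision threshold on the normalized score scale, in
#'   \[-1, 1\]. Scores at or below `theta` are classified erroneous.
#' @param mc_repetitions Monte-Carlo cross-validation repetitions.
#' @param seed Optional integer seed recorded with the configuration.
#' @param utility_p Optional mistype probability used by the utility model;
#'   when `NULL` it is estimated from the data at hand.
#' @param selection_time Nominal time per key selection `T_s` (s) in the
#'   utility model (cancels in the gain ratio).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(band = c(1, 16),
                            window = c(-0.2, 0.5),
                            dwell = 0.5,
                            smote_k = 5,
                            svm_cost = 1,
                            theta = 0,
                            mc_repetitions = 100,
                            seed = NULL,
                            utility_p = NULL,
                            selection_time = 0.5) {
  cfg <- list(band = as.numeric(band), window = as.numeric(window),
              dwell = dwell, smote_k = as.integer(smote_k),
              svm_cost = svm_cost, theta = theta,
              mc_repetitions = as.integer(mc_repetitions), seed = seed,
              utility_p = utility_p, selection_time = selection_time)
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (length(cfg$band) != 2 || cfg$band[1] >= cfg$band[2] || any(cfg$band <= 0)) {
    abort("invalid band: expected 0 < low < high")
  }
  if (length(cfg$window) != 2 || !(cfg$window[1] < 0 && cfg$window[2] > 0)) {
    abort("invalid window: expected start < 0 < end")
  }
  if (cfg$dwell <= 0) abort("invalid dwell: must be positive")
  if (!is_scalar_number(cfg$theta) || cfg$theta < -1 || cfg$theta > 1) {
    abort("invalid threshold: theta must lie in [-1, 1]")
  }
  if (cfg$mc_repetitions < 1) abort("mc_repetitions must be >= 1")
  if (cfg$smote_k < 1) abort("smote_k must be >= 1")
  if (cfg$svm_cost <= 0) abort("svm_cost must be positive")
  if (cfg$selection_time <= 0) abort("selection_time must be positive")
  if (!is.null(cfg$utility_p) &&
      (!is_scalar_number(cfg$utility_p) || cfg$utility_p < 0 || cfg$utility_p >= 0.5)) {
    abort("utility_p must lie in [0, 0.5)")
  }
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys absent from the file take the [pipeline_config()] defaults; an empty
#' file yields the full default configuration.
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  band: %g-%g Hz, window: [%g, %g] s, dwell: %g s\n",
              x$band[1], x$band[2], x$window[1], x$window[2], x$dwell))
  cat(sprintf("  smote_k: %d, svm_cost: %g, theta: %g, reps: %d\n",
              x$smote_k, x$svm_cost, x$theta, x$mc_repetitions))
  invisible(x)
}
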