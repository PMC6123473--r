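#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats var rnorm runif rlnorm fft kmeans predict sd
#' @importFrom utils adist head tail
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL means: use (and advance) the current RNG stream.
with_seed_or_current <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), force(code))
  }
}

# Deterministically spawn `n` child seeds from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  if (is.null(seed)) {
    return(rep(list(NULL), n))
  }
  as.list(with_seed_or_current(seed, sample.int(.Machine$integer.max - 1L, n)))
}

# Population (biased) variance; the convention used by the Hjorth descriptors.
pop_var <- function(x) {
  mean((x - mean(x))^2)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stop_if_not_scalar <- function(x, name) {
  if (!is_scalar_number(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
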