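#' SMOTE minority oversampling
#'
#' Synthesizes minority-class instances on the segments between minority
#' points and their k nearest minority neighbours (Euclidean): each
#' synthetic row is `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)`, a parent
#' `x` drawn uniformly from the minority set and `x_nn` one of its k nearest
#' neighbours. `k` is reduced to `n - 1` when the minority set is smaller
#' than `k + 1`; a singleton minority set is duplicated with a warning.
#' Deterministic given `seed`.
#'
#' @param x Numeric matrix of minority instances (rows).
#' @param target_count Desired minority count after augmentation
#'   (>= `nrow(x)`).
#' @param k Number of nearest neighbours (default 5).
#' @param seed Optional integer seed.
#' @return Matrix of `target_count` rows: the originals followed by the
#'   synthetics, with attributes `n_original`, `parents`, `neighbours`, `u`
#'   describing how each synthetic row was built.
#' @export
smote_oversample <- function(x, target_count, k = 5, seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 1) abort("minority set is empty")
  if (target_count < n) abort("target below minority size")
  plan <- smote_plan(x, target_count - n, k, seed)
  syn <- smote_interpolate(x, plan)
  out <- rbind(x, syn)
  attr(out, "n_original") <- n
  attr(out, "parents") <- plan$parent
  attr(out, "neighbours") <- plan$neighbour
  attr(out, "u") <- plan$u
  out
}

# Draw the (parent, neighbour, u) triplets in a reference feature space.
# Shared plans let paired modalities (EEG epoch + gaze distance series) be
# interpolated coherently with the same triplets.
smote_plan <- function(x, n_syn, k = 5, seed = NULL) {
  n <- nrow(x)
  if (n_syn == 0) {
    return(list(parent = integer(0), neighbour = integer(0), u = numeric(0)))
  }
  if (n == 1) {
    warn("single minority instance: SMOTE degenerates to duplication")
    return(list(parent = rep(1L, n_syn), neighbour = rep(1L, n_syn),
                u = rep(0, n_syn)))
  }
  k_eff <- min(k, n - 1)
  dm <- as.matrix(stats::dist(x))
  nn <- matrix(0L, n, k_eff)
  for (i in seq_len(n)) nn[i, ] <- order(dm[i, ])[2:(k_eff + 1)]
  with_seed_or_current(seed, {
    parent <- sample.int(n, n_syn, replace = TRUE)
    pick <- sample.int(k_eff, n_syn, replace = TRUE)
    u <- runif(n_syn)
    list(parent = parent,
         neighbour = nn[cbind(parent, pick)],
         u = u)
  })
}

smote_interpolate <- function(x, plan) {
  if (!length(plan$parent)) {
    return(x[integer(0), , drop = FALSE])
  }
  xp <- x[plan$parent, , drop = FALSE]
  xn <- x[plan$neighbour, , drop = FALSE]
  xp + plan$u * (xn - xp)
}
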