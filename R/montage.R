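#' Approximate 10-10 electrode montage
#'
#' A 64-channel scalp layout (10-10 naming) with idealized planar
#' coordinates: `x` grows to the subject's right, `y` to the front, both on a
#' unit-head scale. The coordinates are only used to shape the spatial weight
#' profiles of the synthetic ERP templates and to pick channel subsets; they
#' are not meant for source analysis.
#'
#' @param n_channels Number of channels to keep (1--64). Subsets are chosen
#'   midline-first so that the frontocentral and centro-parietal sites that
#'   carry the error-related response are always present.
#' @return A tibble with columns `channel`, `x`, `y`, in montage order.
#' @export
#' @examples
#' eeg_montage(8)
eeg_montage <- function(n_channels = 64) {
  full <- montage_table()
  if (!is_scalar_number(n_channels) || n_channels < 1 || n_channels > nrow(full)) {
    abort(sprintf("`n_channels` must be between 1 and %d", nrow(full)))
  }
  n_channels <- as.integer(n_channels)
  keep <- montage_priority()[seq_len(n_channels)]
  full[full$channel %in% keep, , drop = FALSE]
}

montage_table <- function() {
  row_def <- list(
    list(y = 1.00, w = 0.50, ch = c("Fp1", "Fpz", "Fp2")),
    list(y = 0.80, w = 0.80, ch = c("AF7", "AF3", "AFz", "AF4", "AF8")),
    list(y = 0.60, w = 1.00, ch = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8")),
    list(y = 0.35, w = 1.05, ch = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8")),
    list(y = 0.00, w = 1.10, ch = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8")),
    list(y = -0.35, w = 1.05, ch = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8")),
    list(y = -0.60, w = 1.00, ch = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8")),
    list(y = -0.80, w = 0.80, ch = c("PO7", "PO3", "POz", "PO4", "PO8")),
    list(y = -1.00, w = 0.50, ch = c("O1", "Oz", "O2")),
    list(y = -0.70, w = 1.20, ch = c("P9", "P10")),
    list(y = -1.15, w = 0.10, ch = c("Iz"))
  )
  rows <- lapply(row_def, function(r) {
    m <- length(r$ch)
    x <- if (m == 1) 0 else seq(-1, 1, length.out = m) * r$w
    if (identical(r$ch, c("P9", "P10"))) x <- c(-1.2, 1.2)
    tibble(channel = r$ch, x = x, y = r$y)
  })
  dplyr::bind_rows(rows)
}

# Channel order used when subsetting: midline and pericentral sites first.
montage_priority <- function() {
  all_ch <- montage_table()$channel
  first <- c(
    "FCz", "Cz", "CPz", "Fz", "Pz", "AFz", "POz", "Fpz", "Oz", "Iz",
    "FC1", "FC2", "C1", "C2", "CP1", "CP2", "F1", "F2", "P1", "P2",
    "FC3", "FC4", "C3", "C4", "CP3", "CP4", "F3", "F4", "P3", "P4",
    "AF3", "AF4", "PO3", "PO4", "FC5", "FC6", "C5", "C6", "CP5", "CP6"
  )
  c(first, setdiff(all_ch, first))
}

# Gaussian spatial weight profile over a montage, peak-normalized to 1.
spatial_profile <- function(montage, center, sd = 0.5) {
  d2 <- (montage$x - center[1])^2 + (montage$y - center[2])^2
  w <- exp(-d2 / (2 * sd^2))
  w / max(w)
}
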