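#' Cycle-by-cycle Fourier series analysis (CFSA) baseline
#'
#' Segments the record at cycle boundaries and reconstructs each cycle
#' from a truncated Fourier series computed over that cycle: the cycle
#' mean plus `n_harmonics` sine/cosine pairs at multiples of the cycle
#' frequency. Components not resolved by the series — including most
#' of the in-cycle artifact — are cancelled by the coefficient
#' integrals, which are evaluated as plain discrete sums over the
#' cycle's samples. Samples before the first and after the last mark
#' pass through unchanged. The method needs accurate per-cycle period
#' knowledge; [detect_cycle_marks()] provides boundaries when none are
#' given, and per-cycle low-frequency trends shorter than a cycle
#' largely survive the reconstruction (its known weakness).
#'
#' @param data A data frame with a `value` column, or a numeric vector.
#' @param cycle_marks Strictly increasing sample indices (1-based) of
#'   cycle boundaries; `NULL` detects them from the signal.
#' @param n_harmonics Number of harmonic pairs retained per cycle. Each
#'   cycle must contain at least `2 * n_harmonics + 1` samples.
#' @param fs Sampling frequency in Hz.
#' @return A tibble of class `ppg_enhanced` with columns `time`,
#'   `input`, `artifact` and `enhanced`.
#' @export
cfsa_enhance <- function(data, cycle_marks = NULL, n_harmonics = 8,
                         fs = signal_fs(data)) {
  u <- pull_values(data)
  if (is.null(cycle_marks)) {
    cycle_marks <- detect_cycle_marks(u, fs = fs)
    if (length(cycle_marks) < 2) {
      abort("No cycles detected; supply `cycle_marks` explicitly.")
    }
  }
  m <- as.integer(cycle_marks)
  if (any(diff(m) <= 0)) abort("`cycle_marks` must be strictly increasing.")
  if (m[1] < 1 || m[length(m)] > length(u)) {
    abort("`cycle_marks` must lie within the record.")
  }
  if (any(diff(m) < 2 * n_harmonics + 1)) {
    abort(paste0("Every cycle must span at least 2 * n_harmonics + 1 = ",
                 2 * n_harmonics + 1, " samples."))
  }
  y <- u
  for (i in seq_len(length(m) - 1)) {
    idx <- m[i]:(m[i + 1] - 1)
    y[idx] <- fourier_series_fit(u[idx], n_harmonics)
  }
  enhanced_result_untracked(u, u - y, fs, method = "cfsa")
}

# Truncated Fourier-series reconstruction of one cycle: coefficients by
# rectangle-rule sums, which are exact under discrete orthogonality
# when the retained frequencies are k / L cycles per sample.
fourier_series_fit <- function(x, n_harmonics) {
  l <- length(x)
  t <- seq_len(l) - 1
  y <- rep(mean(x), l)
  for (k in seq_len(n_harmonics)) {
    ck <- cos(2 * pi * k * t / l)
    sk <- sin(2 * pi * k * t / l)
    y <- y + (2 / l) * sum(x * ck) * ck + (2 / l) * sum(x * sk) * sk
  }
  y
}

#' Detect cycle boundaries from a quasi-periodic signal
#'
#' Band-passes the signal to the plausible heart-rate band, detects
#' systolic peaks, and marks the trough (local minimum) preceding each
#' peak as a cycle boundary. Returns an empty vector with a warning
#' when no cycles can be found.
#'
#' @param data A data frame with a `value` column, or a numeric vector.
#' @param band Band (Hz) used to isolate the fundamental before peak
#'   picking.
#' @param min_distance Minimum inter-peak distance in seconds.
#' @param fs Sampling frequency in Hz.
#' @return Integer vector of 1-based sample indices (possibly empty).
#' @export
detect_cycle_marks <- function(data, band = c(0.5, 3), min_distance = 0.33,
                               fs = signal_fs(data)) {
  u <- pull_values(data)
  if (sd(u) == 0) {
    warn("Constant signal: no cycles detected.")
    return(integer(0))
  }
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  x <- as.numeric(signal::filtfilt(bf, u))
  peaks <- detect_peaks(x, min_distance = min_distance, fs = fs)
  if (length(peaks) == 0) {
    warn("No cycles detected.")
    return(integer(0))
  }
  troughs <- detect_peaks(-x, min_distance = min_distance, fs = fs)
  marks <- vapply(peaks, function(p) {
    prev <- troughs[troughs < p]
    if (length(prev) == 0) NA_integer_ else prev[length(prev)]
  }, integer(1))
  unique(marks[!is.na(marks)])
}
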