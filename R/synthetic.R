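#' Synthetic quasi-periodic PPG model
#'
#' Describes a clean PPG-like signal as a sum of `K` harmonics of an
#' instantaneous heart rate that evolves as a reflected Gaussian random
#' walk: `clean(n) = sum_k A_k sin(k * phi(n) + phase_k)` with `phi`
#' the cumulative phase of the walk. The default harmonic amplitudes
#' `c(1, 0.5, 0.2)` give the decaying harmonic structure typical of a
#' fingertip PPG; the walk standard deviation of 0.05 Hz per sqrt(s)
#' yields a few tenths of a Hz of heart-rate drift over a minute.
#'
#' @param duration Record duration in seconds.
#' @param fs Sampling frequency in Hz; must exceed twice the highest
#'   harmonic of the maximum heart rate.
#' @param hr Mean heart rate in Hz (0.5--3).
#' @param hr_walk_sd Random-walk standard deviation in Hz per sqrt(s);
#'   0 gives a constant heart rate.
#' @param hr_limits Reflection limits (Hz) of the random walk.
#' @param amplitudes Per-harmonic amplitudes (length `K >= 1`).
#' @param phases Per-harmonic phases in rad; default all zero.
#' @param baseline_amplitude Amplitude of an additive 0.1 Hz baseline
#'   wander component; default 0 (none).
#' @return An object of class `ppg_model`.
#' @export
ppg_model <- function(duration = 60, fs = 100, hr = 1.2, hr_walk_sd = 0.05,
                      hr_limits = c(0.8, 2.5),
                      amplitudes = c(1, 0.5, 0.2), phases = NULL,
                      baseline_amplitude = 0) {
  if (hr < 0.5 || hr > 3) abort("`hr` must lie in [0.5, 3] Hz.")
  k <- length(amplitudes)
  if (k < 1) abort("`amplitudes` must have at least one entry.")
  if (fs <= 2 * k * max(hr, hr_limits[2])) {
    abort("`fs` must exceed twice the highest harmonic frequency.")
  }
  if (is.null(phases)) phases <- rep(0, k)
  if (length(phases) != k) {
    abort("`phases` must match `amplitudes` in length.")
  }
  structure(
    list(duration = duration, fs = fs, hr = hr, hr_walk_sd = hr_walk_sd,
         hr_limits = hr_limits, amplitudes = amplitudes, phases = phases,
         baseline_amplitude = baseline_amplitude),
    class = "ppg_model"
  )
}

#' Simulate a clean PPG record with known ground truth
#'
#' Draws the seeded heart-rate random walk, integrates it into a phase,
#' and synthesises the harmonic waveform. The true instantaneous
#' fundamental frequency is returned per sample (column `theta`,
#' rad/sample) and the per-cycle systolic maxima of the clean waveform
#' are attached as `attr(, "true_peaks")` (also via [true_peaks()]).
#' The same seed always reproduces the same record.
#'
#' @param model A [ppg_model()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `ppg_signal` tibble with columns `time`, `value`, `theta`
#'   and `hr_hz`, plus attribute `true_peaks`.
#' @examples
#' sim <- simulate_ppg(ppg_model(duration = 10), seed = 1)
#' true_peaks(sim)
#' @export
simulate_ppg <- function(model, seed = NULL) {
  n <- round(model$duration * model$fs)
  hr_t <- with_seed_maybe(seed, {
    if (model$hr_walk_sd > 0) {
      steps <- rnorm(n, sd = model$hr_walk_sd / sqrt(model$fs))
      reflect_walk(model$hr + cumsum(steps), model$hr_limits)
    } else {
      rep(model$hr, n)
    }
  })
  theta <- 2 * pi * hr_t / model$fs
  phi <- cumsum(theta) - theta[1] # phase origin at the first sample
  value <- rep(0, n)
  for (k in seq_along(model$amplitudes)) {
    value <- value +
      model$amplitudes[k] * sin(k * phi + model$phases[k])
  }
  if (model$baseline_amplitude > 0) {
    value <- value + model$baseline_amplitude *
      sin(2 * pi * 0.1 * (seq_len(n) - 1) / model$fs)
  }
  out <- tibble::tibble(
    time = (seq_len(n) - 1) / model$fs,
    value = value,
    theta = theta,
    hr_hz = hr_t
  )
  out <- new_ppg_signal(out, model$fs)
  attr(out, "true_peaks") <- detect_peaks(value, min_distance = 0.33,
                                          fs = model$fs)
  out
}

# Reflect a random walk into [lo, hi] (billiard reflection).
reflect_walk <- function(x, limits) {
  lo <- limits[1]
  hi <- limits[2]
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

#' True peak locations of a simulated record
#'
#' @param sim A tibble returned by [simulate_ppg()].
#' @return Integer vector of 1-based sample indices.
#' @export
true_peaks <- function(sim) {
  p <- attr(sim, "true_peaks", exact = TRUE)
  if (is.null(p)) abort("`sim` carries no true-peak annotation.")
  p
}

#' Band-limited colored noise emulating motion artifact
#'
#' Draws seeded white Gaussian noise and restricts it to the given band
#' with a zero-phase spectral band-pass (all Fourier components outside
#' the band, including DC, are removed), emulating motion artifact
#' whose energy overlaps the feasible heart-rate range. The result has
#' exactly zero mean and (up to numerical precision) all of its power
#' inside the band.
#'
#' @param duration Duration in seconds.
#' @param fs Sampling frequency in Hz.
#' @param band Passband `c(low, high)` in Hz, inside `(0, fs/2)`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `ppg_signal` tibble with columns `time` and `value`.
#' @export
colored_noise <- function(duration, fs, band = c(0.5, 2), seed = NULL) {
  check_fs(fs)
  if (band[1] <= 0 || band[1] >= band[2] || band[2] >= fs / 2) {
    abort("`band` must satisfy 0 < low < high < fs/2.")
  }
  n <- round(duration * fs)
  white <- with_seed_maybe(seed, rnorm(n))
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq) # two-sided bin frequencies
  mask <- freq >= band[1] & freq <= band[2]
  x <- Re(fft(fft(white) * mask, inverse = TRUE)) / n
  ppg_signal(x, fs = fs)
}

#' Mix a clean signal with noise at an exact signal-to-noise ratio
#'
#' Scales the noise so that `10 * log10(var(clean) / var(g * noise))`
#' equals `snr_db` exactly, and returns `clean + g * noise`. An
#' infinite `snr_db` returns the clean signal unchanged.
#'
#' @param clean,noise Data frames with `value` columns (or numeric
#'   vectors) of equal length.
#' @param snr_db Target input SNR in dB (may be `Inf`).
#' @param fs Sampling frequency in Hz.
#' @return A `ppg_signal` tibble with columns `time` and `value`.
#' @export
mix_at_snr <- function(clean, noise, snr_db, fs = signal_fs(clean)) {
  x <- pull_values(clean)
  e <- pull_values(noise)
  if (length(x) != length(e)) {
    abort("`clean` and `noise` must have equal lengths.")
  }
  if (is.infinite(snr_db) && snr_db > 0) {
    return(ppg_signal(x, fs = fs))
  }
  if (var(e) == 0) abort("`noise` has zero variance.")
  g <- sqrt(var(x) / (var(e) * 10^(snr_db / 10)))
  ppg_signal(x + g * e, fs = fs)
}

#' Write a simulated record and its ground truth to CSV
#'
#' Writes `<prefix>_signal.csv` (`time`, `value`) and
#' `<prefix>_truth.csv` (`time`, `theta`, `hr_hz`, `is_peak`).
#'
#' @param sim A tibble from [simulate_ppg()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the two file paths.
#' @export
write_simulation <- function(sim, dir, prefix = "ppg") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sig_path <- file.path(dir, paste0(prefix, "_signal.csv"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.csv"))
  write_signal(sim, sig_path)
  truth <- data.frame(
    time = sim$time,
    theta = sim$theta,
    hr_hz = sim$hr_hz,
    is_peak = seq_len(nrow(sim)) %in% true_peaks(sim)
  )
  utils::write.csv(truth, truth_path, row.names = FALSE, quote = FALSE)
  invisible(c(sig_path, truth_path))
}
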