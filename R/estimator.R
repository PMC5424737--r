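#' Configuration of the adaptive notch frequency tracker
#'
#' The instantaneous fundamental frequency (heart rate) is tracked by a
#' constrained second-order adaptive IIR notch filter whose single
#' adapted parameter is `cos(theta)`. The squared notch output is
#' minimised by a normalised stochastic-gradient update; the estimate is
#' clamped to a feasible heart-rate band. The input is mean-removed and
#' variance-normalised before adaptation, and the gradient step is
#' divided by a running power estimate of the regressor, so `step_size`
#' is scale-free.
#'
#' @param step_size Adaptation step size (unitless, > 0).
#' @param contraction Pole contraction of the tracking notch, in (0, 1).
#'   Values closer to 1 give a sharper notch: lower estimation variance
#'   and less pull from the signal's higher harmonics, at the price of
#'   slower adaptation. The default 0.98 keeps the harmonic-induced
#'   bias on a multi-harmonic pulse waveform near 1%.
#' @param initial_hz Initial frequency guess in Hz.
#' @param band Feasible frequency band `c(f_min, f_max)` in Hz; every
#'   emitted estimate is clamped to it.
#' @param smooth Optional trailing moving-average window (samples)
#'   applied to the raw track; 0 disables smoothing.
#' @return An object of class `estimator_config`.
#' @export
estimator_config <- function(step_size = 5e-3, contraction = 0.98,
                             initial_hz = 1.5, band = c(0.5, 3.0),
                             smooth = 0) {
  if (step_size <= 0) abort("`step_size` must be positive.")
  if (contraction <= 0 || contraction >= 1) {
    abort("`contraction` must lie in (0, 1).")
  }
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2]) {
    abort("`band` must be c(f_min, f_max) with 0 < f_min < f_max.")
  }
  if (initial_hz < band[1] || initial_hz > band[2]) {
    abort("`initial_hz` must lie inside `band`.")
  }
  structure(
    list(step_size = step_size, contraction = contraction,
         initial_hz = initial_hz, band = band, smooth = as.integer(smooth)),
    class = "estimator_config"
  )
}

#' Track the instantaneous fundamental frequency (heart rate)
#'
#' Runs the adaptive notch tracker over the signal and returns the
#' causal per-sample estimate `theta(n)` in rad/sample (column `theta`)
#' together with its Hz equivalent (`hr_hz`). Each estimate depends
#' only on samples up to `n`, so the track is real-time admissible. The
#' tracker needs roughly 10 s to converge from its initial guess;
#' analyses typically discard that burn-in.
#'
#' On an all-zero or constant input the tracker cannot adapt: the track
#' is pinned at the initial guess, a warning is raised, and the result
#' carries `attr(, "converged") = FALSE`.
#'
#' @param data A data frame with a `value` column, or a numeric vector.
#' @param config An [estimator_config()].
#' @param fs Sampling frequency in Hz. Must satisfy
#'   `band[2] < fs / 2`.
#' @return The input as a tibble with added columns `theta`
#'   (rad/sample) and `hr_hz`, attribute `fs`, and attribute
#'   `converged`.
#' @examples
#' s <- ppg_signal(sin(2 * pi * 1.2 * seq(0, 30, by = 0.01)), fs = 100)
#' tail(estimate_heart_rate(s)$hr_hz)
#' @export
estimate_heart_rate <- function(data, config = estimator_config(),
                                fs = signal_fs(data)) {
  u <- pull_values(data)
  check_fs(fs)
  if (config$band[2] >= fs / 2) {
    abort("`band[2]` must be below the Nyquist frequency fs/2.")
  }
  s <- sd(u)
  converged <- TRUE
  if (!is.finite(s) || s == 0) {
    warn("Constant input: frequency tracker cannot adapt; track pinned at the initial guess.")
    theta <- rep(2 * pi * config$initial_hz / fs, length(u))
    converged <- FALSE
  } else {
    un <- (u - mean(u)) / s
    # cos() is decreasing on (0, pi): the band upper edge bounds c below
    cmin <- cos(2 * pi * config$band[2] / fs)
    cmax <- cos(2 * pi * config$band[1] / fs)
    state <- c(0, 0, 1, cos(2 * pi * config$initial_hz / fs))
    fit <- alnf_cpp(un, config$step_size, config$contraction,
                    cmin, cmax, state)
    theta <- fit$theta
    if (config$smooth > 1) theta <- trailing_mean(theta, config$smooth)
  }
  out <- tibble::tibble(
    time = (seq_along(u) - 1) / fs,
    value = u,
    theta = theta,
    hr_hz = theta * fs / (2 * pi)
  )
  out <- new_ppg_signal(out, fs)
  attr(out, "converged") <- converged
  out
}

# Trailing (causal) moving average; the first w-1 samples use the
# partial window so the output stays causal and the same length.
trailing_mean <- function(x, w) {
  cs <- cumsum(x)
  n <- length(x)
  out <- numeric(n)
  idx <- seq_len(n)
  lead <- pmax(idx - w, 0)
  out <- (cs - c(0, cs)[lead + 1]) / (idx - lead)
  out
}

#' Reverse a fundamental-frequency track
#'
#' The backward pass of the zero-phase enhancer filters the
#' time-reversed signal, so its time-variant impulse response must be
#' reversed too: the track is re-indexed as `theta(N - 1 - n)`.
#' Reversing twice is the identity.
#'
#' @param theta Numeric per-sample track (rad/sample).
#' @return The reversed track.
#' @export
reverse_track <- function(theta) {
  stopifnot(is.numeric(theta))
  rev(theta)
}
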