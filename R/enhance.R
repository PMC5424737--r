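#' Adaptive comb filter enhancement (single forward pass)
#'
#' The causal line enhancer: the time-variant harmonic notch filter
#' removes the quasi-periodic component from the input, so its residual
#' `v` is the motion-artifact estimate, and the enhanced signal is the
#' exact sample-wise difference `y = u - v`. The identity `y + v = u`
#' holds bit-exactly. Being a single causal IIR pass, the ACF distorts
#' the phase of the retained component whenever the frequency estimate
#' is imperfect; [enhance_zle()] removes that distortion.
#'
#' @param data A data frame with a `value` column (and optionally a
#'   `theta` column), or a numeric vector.
#' @param bank A [notch_bank()].
#' @param config An [estimator_config()]; used when no frequency track
#'   is supplied.
#' @param theta Optional per-sample fundamental-frequency track in
#'   rad/sample.
#' @param f0 Optional constant fundamental frequency in Hz.
#' @param fs Sampling frequency in Hz.
#' @return A tibble of class `ppg_enhanced` with columns `time`,
#'   `input`, `theta`, `artifact` and `enhanced`; attributes `fs` and
#'   `method`.
#' @examples
#' sim <- simulate_ppg(ppg_model(duration = 30), seed = 1)
#' enhance_acf(sim, f0 = 1.2)
#' @export
enhance_acf <- function(data, bank = notch_bank(),
                        config = estimator_config(),
                        theta = NULL, f0 = NULL, fs = signal_fs(data)) {
  u <- pull_values(data)
  theta <- resolve_track_or_estimate(data, theta, f0, fs, config)
  check_bank_theta(theta, bank)
  v <- tv_notch_cpp(u, theta, bank$r)
  enhanced_result(u, theta, v, fs, method = "acf")
}

#' Zero-phase line enhancement (forward-backward, batch)
#'
#' The zero-phase line enhancer applies the time-variant harmonic notch
#' filter in four steps: (i) forward filtering with the track
#' `theta(n)`, (ii) time reversal, (iii) a second filtering pass with
#' the reversed track `theta(N - 1 - n)` (the impulse response of the
#' backward pass must be time-reversed), and (iv) time reversal. The
#' chained output `w` is the motion-artifact estimate; the enhanced
#' signal is `y = u - w` exactly. For a constant track the composite
#' input-to-`w` map has squared magnitude response `|H|^2` and exactly
#' zero phase, which is the point of the method: frequency-estimation
#' error no longer translates into phase distortion of the enhanced
#' waveform. Both passes start from zero filter state.
#'
#' This is a batch operation — it needs the whole record. For blockwise
#' real-time use see [enhance_zle_windowed()] and [zle_stream()].
#'
#' @inheritParams enhance_acf
#' @return A tibble of class `ppg_enhanced` with columns `time`,
#'   `input`, `theta`, `artifact` and `enhanced`.
#' @examples
#' sim <- simulate_ppg(ppg_model(duration = 30), seed = 1)
#' enhance_zle(sim, f0 = 1.2)
#' @export
enhance_zle <- function(data, bank = notch_bank(),
                        config = estimator_config(),
                        theta = NULL, f0 = NULL, fs = signal_fs(data)) {
  u <- pull_values(data)
  theta <- resolve_track_or_estimate(data, theta, f0, fs, config)
  check_bank_theta(theta, bank)
  w <- zle_artifact(u, theta, bank)
  enhanced_result(u, theta, w, fs, method = "zle")
}

# Four-step forward-backward chain on plain vectors; both passes start
# from zero state.
zle_artifact <- function(u, theta, bank) {
  v <- tv_notch_cpp(u, theta, bank$r)
  p <- rev(v)
  q <- tv_notch_cpp(p, reverse_track(theta), bank$r)
  rev(q)
}

resolve_track_or_estimate <- function(data, theta, f0, fs, config) {
  n <- length(pull_values(data))
  has_explicit <- !is.null(theta) || !is.null(f0) ||
    (is.data.frame(data) && "theta" %in% names(data))
  if (has_explicit) {
    return(resolve_track(data, theta, f0, fs, n))
  }
  est <- estimate_heart_rate(pull_values(data), config = config, fs = fs)
  est$theta
}

enhanced_result <- function(u, theta, artifact, fs, method) {
  out <- tibble::tibble(
    time = (seq_along(u) - 1) / fs,
    input = u,
    theta = theta,
    artifact = artifact,
    enhanced = u - artifact
  )
  out <- new_ppg_signal(out, fs)
  attr(out, "method") <- method
  class(out) <- unique(c("ppg_enhanced", class(out)))
  out
}

# Result wrapper shared with the baseline methods, which have no
# frequency track.
enhanced_result_untracked <- function(u, artifact, fs, method) {
  out <- tibble::tibble(
    time = (seq_along(u) - 1) / fs,
    input = u,
    artifact = artifact,
    enhanced = u - artifact
  )
  out <- new_ppg_signal(out, fs)
  attr(out, "method") <- method
  class(out) <- unique(c("ppg_enhanced", class(out)))
  out
}
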