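#' Harmonic notch filter bank parameters
#'
#' The enhancer removes a quasi-periodic component by cascading `P`
#' second-order IIR notch sections placed at the harmonics `j * theta`,
#' `j = 1..P`, of the instantaneous fundamental frequency `theta`
#' (rad/sample). The j-th section
#' \deqn{H_j(z) = \frac{1+r_j}{2}\,
#'   \frac{1 - 2\cos(j\theta) z^{-1} + z^{-2}}
#'        {1 - (1+r_j)\cos(j\theta) z^{-1} + r_j z^{-2}}}
#' has unit-circle zeros at `j * theta` and poles contracted by the
#' factor `r_j = 1 - j * delta`, so higher harmonics get progressively
#' wider notches — they absorb the amplified frequency-estimation jitter
#' at `j` times the fundamental. Stability requires every
#' `r_j` in (0, 1), i.e. `P * delta < 1`.
#'
#' @param n_harmonics Number of harmonic sections `P` (integer >= 1).
#' @param delta Pole-zero contraction increment (typically 0.02--0.04).
#' @return An object of class `notch_bank` with fields `P`, `delta` and
#'   the contraction factors `r`.
#' @examples
#' notch_bank(8, 0.02)$r
#' @export
notch_bank <- function(n_harmonics = 8, delta = 0.03) {
  r <- contraction_factors(n_harmonics, delta)
  structure(
    list(P = as.integer(n_harmonics), delta = delta, r = r),
    class = "notch_bank"
  )
}

#' @export
print.notch_bank <- function(x, ...) {
  cat("<notch_bank> P =", x$P, ", delta =", x$delta, "\n")
  cat("  r:", paste(format(x$r), collapse = " "), "\n")
  invisible(x)
}

#' Pole-zero contraction factors of the harmonic notch bank
#'
#' Computes `r_j = 1 - j * delta` for `j = 1..P`. The factors are
#' strictly decreasing, widening the notch bandwidth with harmonic
#' order.
#'
#' @inheritParams notch_bank
#' @return Numeric vector of length `n_harmonics`, each in (0, 1).
#' @export
contraction_factors <- function(n_harmonics, delta) {
  if (!is.numeric(n_harmonics) || length(n_harmonics) != 1 ||
      n_harmonics < 1 || n_harmonics != round(n_harmonics)) {
    abort("`n_harmonics` must be a positive integer.")
  }
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0) {
    abort("`delta` must be a positive number.")
  }
  if (n_harmonics * delta >= 1) {
    abort(paste0(
      "Unstable bank: P * delta = ", n_harmonics * delta,
      " >= 1 would place a contraction factor outside (0, 1)."
    ))
  }
  1 - seq_len(n_harmonics) * delta
}

#' Coefficients of one second-order notch section
#'
#' Evaluates the direct-form coefficients of the section at harmonic
#' order `j`: `a1 = (1 + r) cos(j theta)`, `a2 = -r`,
#' `b1 = -2 cos(j theta)`, `k = (1 + r) / 2`, for the realization
#' `H(z) = k (1 + b1 z^-1 + z^-2) / (1 - a1 z^-1 - a2 z^-2)`.
#'
#' @param theta Fundamental frequency in rad/sample (`0 < j*theta < pi`).
#' @param harmonic Harmonic order `j` (vectorized).
#' @param r Contraction factor in (0, 1) (vectorized with `harmonic`).
#' @return A tibble with columns `harmonic`, `a1`, `a2`, `b1`, `k`.
#' @examples
#' section_coefficients(pi / 3, 1, 0.98)
#' @export
section_coefficients <- function(theta, harmonic, r) {
  if (any(r <= 0 | r >= 1)) abort("`r` must lie in (0, 1).")
  if (any(harmonic * theta <= 0 | harmonic * theta >= pi)) {
    abort("Each harmonic notch frequency j * theta must lie in (0, pi).")
  }
  cj <- cos(harmonic * theta)
  tibble::tibble(
    harmonic = as.integer(harmonic),
    a1 = (1 + r) * cj,
    a2 = -r,
    b1 = -2 * cj,
    k = (1 + r) / 2
  )
}

#' Frequency response of the harmonic notch bank at fixed theta
#'
#' Evaluates `H(e^{i omega}, theta)`, the product of the `P` section
#' responses, on a grid of digital frequencies. The response has exact
#' zeros at every harmonic `j * theta` and unit gain at DC and (when no
#' notch sits there) at Nyquist.
#'
#' @param theta Fundamental frequency in rad/sample.
#' @param bank A [notch_bank()].
#' @param omega Grid of digital frequencies in rad/sample; defaults to
#'   512 points on `[0, pi]`.
#' @param fs Optional sampling frequency; when supplied a `frequency_hz`
#'   column is added.
#' @return A tibble with columns `omega`, `response` (complex),
#'   `magnitude` and `phase`.
#' @export
notch_frequency_response <- function(theta, bank = notch_bank(),
                                     omega = NULL, fs = NULL) {
  if (is.null(omega)) omega <- seq(0, pi, length.out = 512)
  check_bank_theta(theta, bank)
  z1 <- exp(-1i * omega)
  z2 <- exp(-2i * omega)
  h <- rep(1 + 0i, length(omega))
  for (j in seq_len(bank$P)) {
    cj <- cos(j * theta)
    r <- bank$r[j]
    num <- 1 - 2 * cj * z1 + z2
    den <- 1 - (1 + r) * cj * z1 + r * z2
    h <- h * ((1 + r) / 2) * num / den
  }
  out <- tibble::tibble(
    omega = omega,
    response = h,
    magnitude = Mod(h),
    phase = Arg(h)
  )
  if (!is.null(fs)) out$frequency_hz <- omega * fs / (2 * pi)
  out
}

# Validate that the whole bank stays below Nyquist for the given
# theta(s): the P-th harmonic notch must sit strictly inside (0, pi).
check_bank_theta <- function(theta, bank) {
  if (!is.numeric(theta) || !all(is.finite(theta))) {
    abort("`theta` must be finite numeric (rad/sample).")
  }
  if (any(theta <= 0) || any(bank$P * theta >= pi)) {
    abort(paste0(
      "Fundamental frequency track leaves the admissible band: need ",
      "0 < theta and P * theta < pi (highest harmonic below Nyquist)."
    ))
  }
  invisible(theta)
}

#' Apply the time-variant harmonic notch filter
#'
#' Runs the P-section cascade with per-sample coefficients rebuilt from
#' the instantaneous fundamental-frequency track, in direct form 2 with
#' per-section state carried through the recursion. Sections are
#' cascaded in ascending harmonic order with zero-initialised state.
#' For a constant track the output is identical to filtering with the
#' corresponding time-invariant cascade. The residual is the
#' motion-artifact estimate; subtracting it from the input yields the
#' enhanced signal (see [enhance_acf()]).
#'
#' @param data A data frame with a `value` column, or a numeric vector.
#'   A `theta` column (rad/sample), if present, supplies the track.
#' @param bank A [notch_bank()].
#' @param theta Optional per-sample track in rad/sample (overrides any
#'   `theta` column in `data`).
#' @param f0 Optional constant fundamental frequency in Hz, converted to
#'   rad/sample via `2 * pi * f0 / fs`.
#' @param fs Sampling frequency in Hz.
#' @return A tibble with columns `time`, `value` (the input), `theta`
#'   and `residual` (the notch output), with attribute `fs`.
#' @export
apply_notch <- function(data, bank = notch_bank(), theta = NULL, f0 = NULL,
                        fs = signal_fs(data)) {
  u <- pull_values(data)
  theta <- resolve_track(data, theta, f0, fs, length(u))
  check_bank_theta(theta, bank)
  v <- tv_notch_cpp(u, theta, bank$r)
  out <- tibble::tibble(
    time = (seq_along(u) - 1) / fs,
    value = u,
    theta = theta,
    residual = v
  )
  new_ppg_signal(out, fs)
}

# Resolve the frequency track from (in order of precedence) an explicit
# per-sample `theta`, a constant `f0` in Hz, or a `theta` column.
resolve_track <- function(data, theta, f0, fs, n) {
  if (!is.null(theta)) {
    if (length(theta) == 1) theta <- rep(theta, n)
    if (length(theta) != n) {
      abort("`theta` must have one entry per input sample.")
    }
    return(as.numeric(theta))
  }
  if (!is.null(f0)) {
    if (!is.numeric(f0) || length(f0) != 1 || f0 <= 0) {
      abort("`f0` must be a single positive frequency in Hz.")
    }
    return(rep(2 * pi * f0 / fs, n))
  }
  if (is.data.frame(data) && "theta" %in% names(data)) {
    return(as.numeric(data$theta))
  }
  abort(paste0(
    "No frequency track: supply `theta` (rad/sample), `f0` (Hz), or a ",
    "`theta` column (e.g. from `estimate_heart_rate()`)."
  ))
}
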