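#' Moving-window scheme for blockwise zero-phase enhancement
#'
#' The batch zero-phase enhancer needs the whole record, so real-time
#' operation processes overlapping windows instead. Forward-backward
#' filtering has edge transients at both ends of each window; the scheme
#' discards a transient segment at each end and emits only the central
#' filtering segment. Consecutive windows therefore overlap by twice
#' the transient duration, and the hop equals the filtering duration.
#'
#' @param transient Transient duration in samples discarded at each end
#'   of every window.
#' @param filtering Filtering (kept) duration in samples.
#' @return An object of class `window_scheme` with fields `transient`,
#'   `filtering`, `window` (`filtering + 2 * transient`), `hop`
#'   (`= filtering`) and `overlap` (`= 2 * transient`).
#' @examples
#' window_scheme() # 100 + 300 + 100 = 500-sample windows, hop 300
#' @export
window_scheme <- function(transient = 100, filtering = 300) {
  if (transient < 1 || filtering < 1) {
    abort("`transient` and `filtering` must be positive sample counts.")
  }
  structure(
    list(
      transient = as.integer(transient),
      filtering = as.integer(filtering),
      window = as.integer(filtering + 2 * transient),
      hop = as.integer(filtering),
      overlap = as.integer(2 * transient)
    ),
    class = "window_scheme"
  )
}

#' @export
print.window_scheme <- function(x, ...) {
  cat("<window_scheme> window =", x$window, "samples (transient",
      x$transient, "| filtering", x$filtering, "| transient",
      x$transient, "), hop =", x$hop, "\n")
  invisible(x)
}

#' Window/keep geometry of the blockwise scheme
#'
#' Enumerates the windows covering a record of `n_samples` samples and
#' the central segment kept from each. Kept segments are disjoint,
#' contiguous and each lies at least `transient` samples from both ends
#' of its window. The leading transient of the first window, the
#' trailing transient of the last, and any trailing samples that cannot
#' fill a complete window are never emitted.
#'
#' @param n_samples Record length in samples; must be at least one full
#'   window.
#' @param scheme A [window_scheme()].
#' @return A tibble with one row per window and 1-based inclusive
#'   columns `window_start`, `window_end`, `keep_start`, `keep_end`.
#' @examples
#' window_plan(800, window_scheme())
#' @export
window_plan <- function(n_samples, scheme = window_scheme()) {
  if (n_samples < scheme$window) {
    abort(paste0(
      "Record too short for the window scheme: need at least ",
      scheme$window, " samples, got ", n_samples, "."
    ))
  }
  starts <- as.integer(seq(1L, as.integer(n_samples) - scheme$window + 1L,
                           by = scheme$hop))
  tibble::tibble(
    window_start = starts,
    window_end = starts + scheme$window - 1L,
    keep_start = starts + scheme$transient,
    keep_end = starts + scheme$transient + scheme$filtering - 1L
  )
}

#' Blockwise (real-time) zero-phase line enhancement
#'
#' Applies [enhance_zle()] per window of the moving-window scheme and
#' concatenates the kept filtering segments. Each window is processed
#' using only its own samples, so the scheme is real-time admissible
#' with a latency of one window. The frequency tracker is causal and
#' runs continuously over the whole record (state carried across
#' windows); only the forward-backward notch filtering is windowed.
#'
#' @inheritParams enhance_acf
#' @param scheme A [window_scheme()].
#' @return A tibble of class `ppg_enhanced` covering the kept interior
#'   of the record (shorter than the input by at least one overlap);
#'   the `time` column preserves the original time axis.
#' @export
enhance_zle_windowed <- function(data, scheme = window_scheme(),
                                 bank = notch_bank(),
                                 config = estimator_config(),
                                 theta = NULL, f0 = NULL,
                                 fs = signal_fs(data)) {
  u <- pull_values(data)
  theta <- resolve_track_or_estimate(data, theta, f0, fs, config)
  check_bank_theta(theta, bank)
  plan <- window_plan(length(u), scheme)
  pieces <- purrr::pmap(plan, function(window_start, window_end,
                                       keep_start, keep_end) {
    idx <- window_start:window_end
    w <- zle_artifact(u[idx], theta[idx], bank)
    keep <- (keep_start:keep_end) - window_start + 1L
    tibble::tibble(
      time = (keep_start:keep_end - 1L) / fs,
      input = u[keep_start:keep_end],
      theta = theta[keep_start:keep_end],
      artifact = w[keep],
      enhanced = u[keep_start:keep_end] - w[keep]
    )
  })
  out <- dplyr::bind_rows(pieces)
  out <- new_ppg_signal(out, fs)
  attr(out, "method") <- "zle_windowed"
  class(out) <- unique(c("ppg_enhanced", class(out)))
  out
}

#' Streaming interface to the blockwise zero-phase enhancer
#'
#' Creates a push-based processor: the caller feeds sample chunks of
#' arbitrary size with `$push()` and receives emitted enhanced blocks
#' (as `ppg_enhanced` tibbles, possibly empty) whenever complete
#' windows become available. The frequency tracker state, its running
#' input normalisation, and the window position are carried across
#' pushes, so feeding a record chunk by chunk emits exactly the kept
#' segments of the moving-window plan.
#'
#' @param fs Sampling frequency in Hz.
#' @param scheme A [window_scheme()].
#' @param bank A [notch_bank()].
#' @param config An [estimator_config()].
#' @param f0 Optional constant fundamental frequency in Hz; when given,
#'   the adaptive tracker is bypassed.
#' @return An object of class `zle_stream`: a list with functions
#'   `push(samples)` (returns the newly emitted block) and `result()`
#'   (returns everything emitted so far).
#' @examples
#' s <- zle_stream(fs = 100, f0 = 1.2)
#' x <- sin(2 * pi * 1.2 * seq(0, 10, by = 0.01))
#' out <- s$push(x)
#' @export
zle_stream <- function(fs, scheme = window_scheme(), bank = notch_bank(),
                       config = estimator_config(), f0 = NULL) {
  check_fs(fs)
  buffer <- numeric(0)
  track <- numeric(0)
  emitted <- list()
  next_start <- 1L
  # running normalisation (Welford) + tracker state
  n_seen <- 0
  mean_seen <- 0
  m2_seen <- 0
  cmin <- cos(2 * pi * config$band[2] / fs)
  cmax <- cos(2 * pi * config$band[1] / fs)
  est_state <- c(0, 0, 1, cos(2 * pi * config$initial_hz / fs))

  push <- function(samples) {
    check_samples(samples)
    samples <- as.numeric(samples)
    buffer <<- c(buffer, samples)
    if (!is.null(f0)) {
      track <<- c(track, rep(2 * pi * f0 / fs, length(samples)))
    } else {
      for (x in samples) {
        n_seen <<- n_seen + 1
        d <- x - mean_seen
        mean_seen <<- mean_seen + d / n_seen
        m2_seen <<- m2_seen + d * (x - mean_seen)
      }
      s <- if (n_seen > 1) sqrt(m2_seen / (n_seen - 1)) else 0
      un <- if (s > 0) (samples - mean_seen) / s else samples * 0
      fit <- alnf_cpp(un, config$step_size, config$contraction,
                      cmin, cmax, est_state)
      est_state <<- fit$state
      track <<- c(track, fit$theta)
    }
    new_blocks <- list()
    while (length(buffer) >= next_start + scheme$window - 1L) {
      idx <- next_start:(next_start + scheme$window - 1L)
      th <- track[idx]
      check_bank_theta(th, bank)
      w <- zle_artifact(buffer[idx], th, bank)
      keep_abs <- (next_start + scheme$transient):
        (next_start + scheme$transient + scheme$filtering - 1L)
      keep_rel <- keep_abs - next_start + 1L
      block <- tibble::tibble(
        time = (keep_abs - 1L) / fs,
        input = buffer[keep_abs],
        theta = track[keep_abs],
        artifact = w[keep_rel],
        enhanced = buffer[keep_abs] - w[keep_rel]
      )
      new_blocks[[length(new_blocks) + 1L]] <- block
      next_start <<- next_start + scheme$hop
    }
    out <- dplyr::bind_rows(new_blocks)
    emitted[[length(emitted) + 1L]] <<- out
    out <- new_ppg_signal(out, fs)
    attr(out, "method") <- "zle_windowed"
    class(out) <- unique(c("ppg_enhanced", class(out)))
    out
  }

  result <- function() {
    out <- dplyr::bind_rows(emitted)
    out <- new_ppg_signal(out, fs)
    attr(out, "method") <- "zle_windowed"
    class(out) <- unique(c("ppg_enhanced", class(out)))
    out
  }

  structure(list(push = push, result = result), class = "zle_stream")
}
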