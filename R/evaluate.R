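#' Detect peaks of a quasi-periodic signal
#'
#' Finds local maxima (a flat-topped maximum counts once, at the middle
#' of its plateau), then enforces a minimum inter-peak distance by
#' keeping taller peaks first (as MATLAB's `findpeaks` does with
#' `MinPeakDistance`). The default distance of 0.33 s corresponds
#' to the maximum plausible heart rate of 3 Hz and suppresses
#' dicrotic-notch doubles; no prominence threshold is applied.
#'
#' @param data A data frame with a `value` column, or a numeric vector.
#' @param min_distance Minimum distance between accepted peaks, in
#'   seconds; 0 disables the constraint.
#' @param fs Sampling frequency in Hz (needed when `min_distance > 0`).
#' @return Integer vector of 1-based peak indices, ascending.
#' @examples
#' detect_peaks(c(0, 1, 0, 2, 0), min_distance = 0)
#' @export
detect_peaks <- function(data, min_distance = 0.33,
                         fs = if (min_distance > 0) signal_fs(data) else NULL) {
  x <- pull_values(data)
  if (length(x) < 3) return(integer(0))
  # run-length collapse so a flat-topped maximum (two or more equal
  # samples straddling the true peak) counts once, at the plateau middle
  r <- rle(x)
  nr <- length(r$values)
  if (nr < 3) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  core <- 2:(nr - 1)
  is_peak <- r$values[core] > r$values[core - 1] &
    r$values[core] > r$values[core + 1]
  runs <- core[is_peak]
  peaks <- as.integer(starts[runs] + (r$lengths[runs] - 1L) %/% 2L)
  if (min_distance > 0 && length(peaks) > 1) {
    check_fs(fs)
    min_samples <- min_distance * fs
    keep <- logical(length(peaks))
    for (i in order(x[peaks], decreasing = TRUE)) {
      if (!any(keep & abs(peaks - peaks[i]) < min_samples)) {
        keep[i] <- TRUE
      }
    }
    peaks <- peaks[keep]
  }
  sort(peaks)
}

#' Match detected peaks against reference peaks
#'
#' Pairs detected with reference peaks one-to-one when they fall within
#' the acceptance tolerance (default +/-75 ms); all other detections
#' are false positives and unmatched reference peaks are false
#' negatives. Matching is greedy nearest-first: candidate pairs are
#' taken in order of absolute timing offset, ties broken toward the
#' earlier reference index.
#'
#' @param reference,detected Sorted integer sample indices.
#' @param fs Sampling frequency in Hz.
#' @param tolerance_ms Acceptance tolerance in milliseconds.
#' @return An object of class `peak_match`: a list with a `pairs`
#'   tibble (`reference`, `detected`, `offset` in samples),
#'   `false_positives`, `false_negatives`, `fs` and `tolerance_ms`.
#' @examples
#' match_peaks(c(100, 200, 300), c(101, 205, 450), fs = 100)
#' @export
match_peaks <- function(reference, detected, fs, tolerance_ms = 75) {
  check_fs(fs)
  reference <- as.integer(reference)
  detected <- as.integer(detected)
  tol <- tolerance_ms / 1000 * fs
  cand <- expand.grid(ri = seq_along(reference), di = seq_along(detected))
  if (nrow(cand) > 0) {
    cand$offset <- detected[cand$di] - reference[cand$ri]
    cand <- cand[abs(cand$offset) <= tol, , drop = FALSE]
    cand <- cand[order(abs(cand$offset), cand$ri, cand$di), , drop = FALSE]
  }
  ref_free <- rep(TRUE, length(reference))
  det_free <- rep(TRUE, length(detected))
  pairs <- list()
  for (i in seq_len(nrow(cand))) {
    ri <- cand$ri[i]
    di <- cand$di[i]
    if (ref_free[ri] && det_free[di]) {
      ref_free[ri] <- FALSE
      det_free[di] <- FALSE
      pairs[[length(pairs) + 1L]] <- c(reference[ri], detected[di])
    }
  }
  pairs <- if (length(pairs)) {
    m <- do.call(rbind, pairs)
    tibble::tibble(reference = m[, 1], detected = m[, 2],
                   offset = m[, 2] - m[, 1])
  } else {
    tibble::tibble(reference = integer(0), detected = integer(0),
                   offset = integer(0))
  }
  pairs <- dplyr::arrange(pairs, .data$reference)
  structure(
    list(pairs = pairs,
         false_positives = detected[det_free],
         false_negatives = reference[ref_free],
         fs = fs, tolerance_ms = tolerance_ms),
    class = "peak_match"
  )
}

#' @export
print.peak_match <- function(x, ...) {
  cat("<peak_match> TP:", nrow(x$pairs),
      " FP:", length(x$false_positives),
      " FN:", length(x$false_negatives),
      " (tolerance +/-", x$tolerance_ms, "ms)\n")
  invisible(x)
}

#' @rdname match_peaks
#' @param x A `peak_match` object.
#' @param ... Unused.
#' @export
tidy.peak_match <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$pairs, status = "tp"),
    tibble::tibble(reference = NA_integer_, detected = x$false_positives,
                   offset = NA_integer_, status = "fp"),
    tibble::tibble(reference = x$false_negatives, detected = NA_integer_,
                   offset = NA_integer_, status = "fn")
  )
}

#' @rdname match_peaks
#' @export
glance.peak_match <- function(x, ...) peak_metrics(x)

#' Peak-detection performance metrics
#'
#' Computes, from a [match_peaks()] result, the sensitivity
#' `Se = TP / (TP + FN) * 100`, positive predictive value
#' `PPV = TP / (TP + FP) * 100`, their harmonic-mean combination
#' `F1 = 2 TP / (2 TP + FN + FP) * 100`, and the mean absolute timing
#' error of matched peaks in milliseconds. With no true positives,
#' `Se` and `F1` are 0, `PPV` is reported as 0 with a warning, and
#' `MAE` is undefined and reported as `NA`.
#'
#' @param match A `peak_match` object.
#' @return A one-row tibble with columns `n_tp`, `n_fp`, `n_fn`, `se`,
#'   `ppv`, `f1` (percent) and `mae_ms`.
#' @examples
#' peak_metrics(match_peaks(c(100, 200, 300), c(101, 205, 450), fs = 100))
#' @export
peak_metrics <- function(match) {
  stopifnot(inherits(match, "peak_match"))
  tp <- nrow(match$pairs)
  fp <- length(match$false_positives)
  fn <- length(match$false_negatives)
  if (tp == 0) {
    warn("No true positives: PPV reported as 0, MAE as NA.")
    se <- if (fn > 0) 0 else NA_real_
    return(tibble::tibble(n_tp = 0L, n_fp = fp, n_fn = fn,
                          se = se, ppv = 0, f1 = 0, mae_ms = NA_real_))
  }
  tibble::tibble(
    n_tp = tp, n_fp = fp, n_fn = fn,
    se = tp / (tp + fn) * 100,
    ppv = tp / (tp + fp) * 100,
    f1 = 2 * tp / (2 * tp + fn + fp) * 100,
    mae_ms = mean(abs(match$pairs$offset)) / match$fs * 1000
  )
}

#' Pearson correlation between two signals
#'
#' @param a,b Data frames with `value` columns, or numeric vectors, of
#'   equal length and nonzero variance.
#' @return The Pearson correlation coefficient.
#' @export
signal_correlation <- function(a, b) {
  x <- pull_values(a)
  y <- pull_values(b)
  if (length(x) != length(y)) abort("Signals must have equal lengths.")
  if (var(x) == 0 || var(y) == 0) {
    abort("Correlation undefined for zero-variance input.")
  }
  cor(x, y)
}

#' Periodogram power spectral density
#'
#' One-sided periodogram of the mean-removed signal, scaled so that the
#' integral of the density over frequency equals the signal's mean
#' square (Parseval).
#'
#' @param data A data frame with a `value` column, or a numeric vector.
#' @param fs Sampling frequency in Hz.
#' @return A tibble with columns `frequency` (Hz) and `power`
#'   (density, units^2 / Hz).
#' @export
signal_psd <- function(data, fs = signal_fs(data)) {
  x <- pull_values(data)
  if (length(x) < 2) abort("Need at least 2 samples.")
  x <- x - mean(x)
  n <- length(x)
  xf <- fft(x)
  n_keep <- floor(n / 2) + 1
  dens <- Mod(xf[seq_len(n_keep)])^2 / (n * fs)
  # double all interior bins (one-sided); DC and (even n) Nyquist not
  scale <- rep(2, n_keep)
  scale[1] <- 1
  if (n %% 2 == 0) scale[n_keep] <- 1
  tibble::tibble(
    frequency = (seq_len(n_keep) - 1) * fs / n,
    power = dens * scale
  )
}
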