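#' Construct a uniformly sampled signal
#'
#' A signal is an ordinary tibble with a `time` column (seconds) and a
#' `value` column, plus a sampling-frequency attribute retrievable with
#' [signal_fs()]. All enhancement and evaluation verbs in this package
#' take such a data frame as their first argument and return a tibble,
#' so calls compose with the pipe.
#'
#' @param value Numeric vector of samples. All values must be finite.
#' @param fs Sampling frequency in Hz (positive scalar).
#' @param start Time of the first sample in seconds.
#' @return A tibble with columns `time` and `value` and attribute `fs`,
#'   of class `ppg_signal`.
#' @examples
#' ppg_signal(sin(2 * pi * 1.2 * seq(0, 10, by = 0.01)), fs = 100)
#' @export
ppg_signal <- function(value, fs, start = 0) {
  check_samples(value)
  check_fs(fs)
  out <- tibble::tibble(
    time = start + (seq_along(value) - 1) / fs,
    value = as.numeric(value)
  )
  new_ppg_signal(out, fs)
}

new_ppg_signal <- function(data, fs) {
  attr(data, "fs") <- as.numeric(fs)
  class(data) <- unique(c("ppg_signal", class(data)))
  data
}

#' Coerce a data frame to a signal
#'
#' @param data A data frame with a `value` column (and optionally `time`).
#' @param fs Sampling frequency in Hz; if missing, taken from the `fs`
#'   attribute of `data`.
#' @return A `ppg_signal` tibble.
#' @export
as_ppg_signal <- function(data, fs = signal_fs(data)) {
  if (!is.data.frame(data) || !"value" %in% names(data)) {
    abort("`data` must be a data frame with a `value` column.")
  }
  check_samples(data$value)
  check_fs(fs)
  out <- tibble::as_tibble(data)
  if (!"time" %in% names(out)) {
    out$time <- (seq_len(nrow(out)) - 1) / fs
    out <- dplyr::relocate(out, "time")
  }
  new_ppg_signal(out, fs)
}

#' Sampling frequency of a signal
#'
#' @param data A data frame carrying an `fs` attribute (as produced by
#'   [ppg_signal()] and every verb in this package).
#' @return The sampling frequency in Hz.
#' @export
signal_fs <- function(data) {
  fs <- attr(data, "fs", exact = TRUE)
  if (is.null(fs)) {
    abort(paste0(
      "No sampling frequency found. Pass `fs` explicitly or construct ",
      "the input with `ppg_signal()`."
    ))
  }
  fs
}

check_fs <- function(fs) {
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  invisible(fs)
}

check_samples <- function(x) {
  if (!is.numeric(x) || length(x) < 1) {
    abort("Signal samples must be a non-empty numeric vector.")
  }
  if (!all(is.finite(x))) {
    abort("Signal samples must all be finite.")
  }
  invisible(x)
}

#' Reverse a signal in time
#'
#' Reverses the order of the samples: `output[n] = input[N - 1 - n]`.
#' Applying it twice returns the original input. For data frames the
#' `value` column (and a `theta` column, if present) is reversed while
#' the `time` axis is kept, so the result remains a valid signal.
#'
#' @param x A numeric vector, or a data frame with a `value` column.
#' @return An object of the same shape as `x`, time-reversed.
#' @examples
#' time_reverse(c(1, 2, 3))
#' @export
time_reverse <- function(x) {
  if (is.numeric(x)) return(rev(x))
  if (is.data.frame(x)) {
    out <- x
    for (col in intersect(c("value", "theta"), names(out))) {
      out[[col]] <- rev(out[[col]])
    }
    return(out)
  }
  abort("`x` must be a numeric vector or a data frame with a `value` column.")
}

#' Band-pass preprocessing for raw PPG records
#'
#' Applies a causal third-order Butterworth band-pass filter (default
#' 0.5--10 Hz) and flags an initial burn-in period during which the
#' adaptive frequency tracker has not yet converged. Flagged samples are
#' kept in the record but marked `excluded = TRUE` so downstream
#' analysis can drop them. The filter is run in a single causal pass so
#' the whole preprocessing chain stays real-time admissible.
#'
#' @param data A data frame with a `value` column.
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order Butterworth filter order.
#' @param burn_in Burn-in duration in seconds to flag at the start.
#' @param fs Sampling frequency in Hz.
#' @return A `ppg_signal` tibble with columns `time`, `value` (filtered)
#'   and `excluded`.
#' @export
preprocess_signal <- function(data, low = 0.5, high = 10, order = 3,
                              burn_in = 10, fs = signal_fs(data)) {
  x <- pull_values(data)
  check_fs(fs)
  if (!(low > 0 && low < high && high < fs / 2)) {
    abort("Band edges must satisfy 0 < low < high < fs/2.")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  filtered <- as.numeric(signal::filter(bf, x))
  n_burn <- min(length(x), round(burn_in * fs))
  out <- tibble::tibble(
    time = (seq_along(x) - 1) / fs,
    value = filtered,
    excluded = seq_along(x) <= n_burn
  )
  new_ppg_signal(out, fs)
}

#' Read and write signals as CSV
#'
#' `read_signal()` accepts either a two-column CSV (`time`, `value`),
#' from which the sampling frequency is inferred from the time axis, or
#' a single-column CSV of values, for which `fs` must be supplied.
#' `write_signal()` writes `time` and `value` at full precision so a
#' round trip reproduces the samples exactly.
#'
#' @param path File path.
#' @param fs Sampling frequency in Hz; overrides any inferred value and
#'   is required for single-column files.
#' @return `read_signal()` returns a `ppg_signal` tibble;
#'   `write_signal()` invisibly returns `path`.
#' @export
read_signal <- function(path, fs = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- utils::read.csv(path)
  if (ncol(df) == 1) {
    if (is.null(fs)) {
      abort("Single-column CSV has no time axis: supply `fs`.")
    }
    value <- df[[1]]
  } else {
    if (!all(c("time", "value") %in% names(df))) {
      names(df)[1:2] <- c("time", "value")
    }
    value <- df$value
    if (is.null(fs)) {
      dt <- diff(df$time)
      if (length(dt) < 1 || any(dt <= 0)) {
        abort(paste0("Malformed time axis in ", path,
                     ": times must be strictly increasing."))
      }
      fs <- 1 / stats::median(dt)
    }
  }
  if (!is.numeric(value) || anyNA(value)) {
    abort(paste0("Malformed value column in ", path))
  }
  ppg_signal(value, fs = fs)
}

#' @rdname read_signal
#' @param data A data frame with `time` and `value` columns.
#' @export
write_signal <- function(data, path) {
  stopifnot(is.data.frame(data), all(c("time", "value") %in% names(data)))
  df <- data.frame(
    time = format(data$time, digits = 17, scientific = FALSE, trim = TRUE),
    value = format(data$value, digits = 17, trim = TRUE)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Extract the sample vector from a data frame or numeric vector input.
pull_values <- function(data) {
  if (is.numeric(data)) {
    check_samples(data)
    return(as.numeric(data))
  }
  if (is.data.frame(data) && "value" %in% names(data)) {
    check_samples(data$value)
    return(as.numeric(data$value))
  }
  abort("Input must be a numeric vector or a data frame with a `value` column.")
}
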