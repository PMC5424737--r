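test_that("peak detection finds strict local maxima", {
  expect_identical(detect_peaks(c(0, 1, 0, 2, 0), min_distance = 0),
                   c(2L, 4L))
  expect_length(detect_peaks(1:20, min_distance = 0), 0)
  # a flat-topped maximum counts once, at the plateau
  expect_identical(detect_peaks(c(0, 1, 1, 0), min_distance = 0), 2L)
  expect_identical(detect_peaks(c(0, 1, 1, 1, 0), min_distance = 0), 3L)
  expect_length(detect_peaks(c(1, 1, 0, 0), min_distance = 0), 0)
  p <- detect_peaks(sinusoid(1.2, 10), fs = FS)
  expect_true(abs(length(p) - 12) <= 1)
})

test_that("the distance constraint keeps the taller of two close peaks", {
  x <- c(0, 3, 0, 5, 0)
  expect_identical(detect_peaks(x, min_distance = 0.05, fs = FS), 4L)
})

test_that("peak matching applies the +/-75 ms acceptance rule one-to-one", {
  m <- match_peaks(c(100, 200, 300), c(101, 205, 450), fs = 100)
  expect_equal(m$pairs$reference, c(100, 200))
  expect_equal(m$pairs$detected, c(101, 205))
  expect_equal(m$false_positives, 450L)
  expect_equal(m$false_negatives, 300L)

  ident <- match_peaks(c(10, 50, 90), c(10, 50, 90), fs = 100)
  expect_equal(nrow(ident$pairs), 3L)
  expect_length(ident$false_positives, 0)
  expect_length(ident$false_negatives, 0)

  none <- match_peaks(c(10, 50), integer(0), fs = 100)
  expect_equal(none$false_negatives, c(10L, 50L))
})

test_that("two detections near one reference pair off nearest-first", {
  m <- match_peaks(c(100), c(97, 102), fs = 100)
  expect_equal(m$pairs$detected, 102L)
  expect_equal(m$false_positives, 97L)
})

test_that("the worked matching example yields the hand-computed metrics", {
  m <- match_peaks(c(100, 200, 300), c(101, 205, 450), fs = 100)
  met <- peak_metrics(m)
  expect_equal(met$se, 200 / 3, tolerance = 1e-12)
  expect_equal(met$ppv, 200 / 3, tolerance = 1e-12)
  expect_equal(met$f1, 200 / 3, tolerance = 1e-12)
  expect_equal(met$mae_ms, 30)
})

test_that("perfect detection scores 100/100/100 with zero timing error", {
  met <- peak_metrics(match_peaks(c(10, 50, 90), c(10, 50, 90), fs = 100))
  expect_equal(c(met$se, met$ppv, met$f1), c(100, 100, 100))
  expect_equal(met$mae_ms, 0)
})

test_that("no detections trigger the undefined-metric policy", {
  expect_warning(
    met <- peak_metrics(match_peaks(c(10, 50), integer(0), fs = 100)),
    "PPV"
  )
  expect_equal(met$se, 0)
  expect_equal(met$f1, 0)
  expect_equal(met$ppv, 0)
  expect_true(is.na(met$mae_ms))
})

test_that("F1 equals the harmonic mean of Se and PPV whenever both are defined", {
  set.seed(71)
  for (k in 1:20) {
    ref <- sort(sample(1000, 20))
    det <- sort(unique(ref + sample(-10:10, 20, replace = TRUE)))
    met <- suppressWarnings(peak_metrics(match_peaks(ref, det, fs = 100)))
    if (met$n_tp > 0 && (met$se + met$ppv) > 0) {
      expect_equal(met$f1, 2 * met$se * met$ppv / (met$se + met$ppv),
                   tolerance = 1e-10)
    }
  }
})

test_that("shrinking the tolerance never increases the TP count", {
  set.seed(72)
  ref <- sort(sample(2000, 25))
  det <- sort(sample(2000, 25))
  tols <- c(150, 100, 75, 50, 25, 10)
  tps <- vapply(tols, function(tol) {
    nrow(match_peaks(ref, det, fs = 100, tolerance_ms = tol)$pairs)
  }, numeric(1))
  expect_true(all(diff(tps) <= 0))
})

test_that("tidy and glance summarise a peak match", {
  m <- match_peaks(c(100, 200, 300), c(101, 205, 450), fs = 100)
  td <- tidy(m)
  expect_equal(sort(unique(td$status)), c("fn", "fp", "tp"))
  expect_equal(nrow(td), 4)
  expect_equal(glance(m)$f1, 200 / 3, tolerance = 1e-12)
})

test_that("correlation behaves as Pearson's r with guard rails", {
  set.seed(73)
  a <- rnorm(500)
  expect_equal(signal_correlation(a, a), 1)
  expect_equal(signal_correlation(a, -a), -1)
  t <- seq_len(1000) - 1
  expect_lt(abs(signal_correlation(sin(2 * pi * 10 * t / 1000),
                                   cos(2 * pi * 10 * t / 1000))), 1e-10)
  expect_error(signal_correlation(a, numeric(500)), "variance")
  expect_error(signal_correlation(a, rnorm(10)), "length")
})

test_that("the periodogram localises tones and satisfies Parseval", {
  x <- sinusoid(1, 10)
  psd <- signal_psd(x, fs = FS)
  expect_equal(psd$frequency[which.max(psd$power)], 1, tolerance = 0.01)
  set.seed(74)
  y <- rnorm(1000)
  psd_y <- signal_psd(y, fs = FS)
  df <- psd_y$frequency[2] - psd_y$frequency[1]
  expect_equal(sum(psd_y$power) * df, mean((y - mean(y))^2),
               tolerance = 1e-6)
})
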