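test_that("the window scheme derives overlap and window length correctly", {
  ws <- window_scheme()
  expect_equal(ws$window, 500L)
  expect_equal(ws$hop, 300L)
  expect_equal(ws$overlap, 200L)
  expect_error(window_scheme(transient = 0), "positive")
})

test_that("window plans tile the interior without gaps or double emission", {
  ws <- window_scheme()
  p1 <- window_plan(500, ws)
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$window_start, 1L)
  expect_equal(p1$window_end, 500L)
  expect_equal(p1$keep_start, 101L)
  expect_equal(p1$keep_end, 400L)

  p2 <- window_plan(800, ws)
  expect_equal(p2$window_start, c(1L, 301L))
  expect_equal(p2$window_end, c(500L, 800L))
  expect_equal(p2$keep_start, c(101L, 401L))
  expect_equal(p2$keep_end, c(400L, 700L))

  # one sample short of the second window: same plan minus it
  expect_identical(window_plan(799, ws), p1)

  for (n in c(500, 801, 1234, 5000)) {
    p <- window_plan(n, ws)
    kept <- unlist(purrr::map2(p$keep_start, p$keep_end, seq))
    expect_false(any(duplicated(kept)))
    expect_identical(kept, seq(min(kept), max(kept)))
    expect_true(all(p$keep_start - p$window_start >= ws$transient))
    expect_true(all(p$window_end - p$keep_end >= ws$transient))
  }
  expect_error(window_plan(499, ws), "at least 500")
})

test_that("a single-window record yields the central segment of its batch ZLE", {
  ws <- window_scheme()
  set.seed(41)
  rec <- make_contaminated(snr_db = 10, seed = 41, duration = 5)
  u <- rec$mixed$value
  batch <- enhance_zle(u, f0 = 1.2, fs = FS)
  win <- enhance_zle_windowed(u, scheme = ws, f0 = 1.2, fs = FS)
  expect_equal(nrow(win), 300L)
  expect_identical(win$enhanced, batch$enhanced[101:400])
})

test_that("windowed ZLE approximates batch ZLE over the common interior", {
  rec <- make_contaminated(snr_db = 5, seed = 42)
  track <- estimate_heart_rate(rec$mixed)$theta
  batch <- enhance_zle(rec$mixed, theta = track)
  win <- enhance_zle_windowed(rec$mixed, theta = track)
  common <- round(win$time * FS) + 1
  expect_lt(rel_rms(win$enhanced, batch$enhanced[common]), 0.05)
})

test_that("longer transients move the windowed output toward the batch output", {
  rec <- make_contaminated(snr_db = 5, seed = 43)
  track <- estimate_heart_rate(rec$mixed)$theta
  batch <- enhance_zle(rec$mixed, theta = track)
  devs <- vapply(c(100, 200, 400), function(tr) {
    win <- enhance_zle_windowed(rec$mixed, scheme = window_scheme(tr, 300),
                                theta = track)
    common <- round(win$time * FS) + 1
    rel_rms(win$enhanced, batch$enhanced[common])
  }, numeric(1))
  expect_true(all(diff(devs) <= 1e-12))
})

test_that("chunked streaming reproduces the windowed batch computation", {
  rec <- make_contaminated(snr_db = 5, seed = 44, duration = 30)
  u <- rec$mixed$value
  ref <- enhance_zle_windowed(u, f0 = 1.2, fs = FS)
  s <- zle_stream(fs = FS, f0 = 1.2)
  set.seed(45)
  i <- 1
  emitted <- list()
  while (i <= length(u)) {
    chunk <- u[i:min(length(u), i + sample(50:400, 1) - 1)]
    emitted[[length(emitted) + 1]] <- s$push(chunk)
    i <- i + length(chunk)
  }
  out <- dplyr::bind_rows(emitted)
  expect_equal(nrow(out), nrow(ref))
  expect_identical(out$enhanced, ref$enhanced)
  expect_identical(s$result()$enhanced, ref$enhanced)
})

test_that("streaming with the adaptive tracker stays close to the batch windowed path", {
  rec <- make_contaminated(snr_db = 10, seed = 46, duration = 30)
  u <- rec$mixed$value
  ref <- enhance_zle_windowed(u, fs = FS)
  s <- zle_stream(fs = FS)
  out <- s$push(u)
  expect_equal(nrow(out), nrow(ref))
  # running vs global input normalisation: tracks differ only slightly
  expect_lt(rel_rms(out$enhanced, ref$enhanced), 0.05)
})
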