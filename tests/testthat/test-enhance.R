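test_that("enhancers conserve the input: enhanced + artifact = input", {
  set.seed(31)
  u <- rnorm(2000)
  track <- 2 * pi * runif(2000, 0.8, 2.0) / FS
  for (fun in list(enhance_acf, enhance_zle)) {
    res <- fun(u, theta = track, fs = FS)
    # y is defined as the exact sample-wise difference u - artifact
    expect_identical(res$enhanced, res$input - res$artifact)
    expect_lt(max(abs(res$enhanced + res$artifact - res$input)),
              1e-12 * max(abs(u)))
  }
})

test_that("ACF with an exact constant track passes the fundamental through", {
  u <- sinusoid(1.2, 60)
  res <- enhance_acf(u, bank = notch_bank(8, 0.02), f0 = 1.2, fs = FS)
  steady <- (10 * FS + 1):length(u)
  expect_lt(sqrt(mean((res$enhanced[steady] - u[steady])^2)),
            1e-3 * sqrt(mean(u^2)))
})

test_that("ACF attenuates a non-harmonic tone per the 1 - H response", {
  bank <- notch_bank(8, 0.02)
  theta <- 2 * pi * 1.2 / FS
  f2 <- 0.37 * 1.2
  u <- sinusoid(1.2, 120) + sinusoid(f2, 120)
  res <- enhance_acf(u, bank = bank, f0 = 1.2, fs = FS)
  # retained fundamental within 1%
  expect_equal(tone_amplitude(res$enhanced, 1.2, discard = 30), 1,
               tolerance = 0.01)
  # the enhanced path has transfer 1 - H; compare at the second tone
  h <- notch_frequency_response(theta, bank, omega = 0.37 * theta)
  expect_equal(tone_amplitude(res$enhanced, f2, discard = 30),
               Mod(1 - h$response), tolerance = 0.02)
})

test_that("batch ZLE equals the filter-reverse-filter-reverse LTI oracle", {
  bank <- notch_bank(8, 0.02)
  theta <- 2 * pi * 1.2 / FS
  set.seed(32)
  u <- rnorm(4000)
  res <- enhance_zle(u, bank = bank, f0 = 1.2, fs = FS)
  w_oracle <- rev(lti_cascade(rev(lti_cascade(u, theta, bank)),
                              theta, bank))
  expect_lt(rel_rms(res$artifact, w_oracle), 1e-12)
})

test_that("ZLE is zero-phase where the single-pass ACF is not", {
  bank <- notch_bank(8, 0.02)
  u <- sinusoid(0.6, 60) # half the fundamental: passband edge region
  z <- enhance_zle(u, bank = bank, f0 = 1.2, fs = FS)
  a <- enhance_acf(u, bank = bank, f0 = 1.2, fs = FS)
  mid <- (0.25 * length(u)):(0.75 * length(u))
  lag_of <- function(x) {
    cc <- stats::ccf(x[mid], u[mid], lag.max = 50, plot = FALSE)
    cc$lag[which.max(cc$acf)]
  }
  expect_identical(lag_of(z$artifact), 0)
  expect_gt(abs(lag_of(a$artifact)), 0)
})

test_that("empirical u->w transfer is the squared magnitude response with zero phase", {
  bank <- notch_bank(8, 0.02)
  theta <- 2 * pi * 1.2 / FS
  n <- 2^14
  u <- numeric(n)
  u[n / 2] <- 1
  w <- enhance_zle(u, bank = bank, f0 = 1.2, fs = FS)$artifact
  emp <- fft(w) / exp(-2i * pi * (0:(n - 1)) * (n / 2 - 1) / n)
  h2 <- notch_frequency_response(theta, bank,
                                 omega = 2 * pi * (0:(n - 1)) / n)$magnitude^2
  keep <- h2 > 1e-3 & (0:(n - 1)) <= n / 2
  expect_lt(max(abs(Mod(emp)[keep] - h2[keep]) / h2[keep]), 0.02)
  expect_lt(max(abs(Arg(emp)[keep])), 0.02)
})

test_that("time reversal reverses samples and is an involution", {
  expect_equal(time_reverse(c(1, 2, 3)), c(3, 2, 1))
  set.seed(33)
  x <- rnorm(50)
  expect_identical(time_reverse(time_reverse(x)), x)
  pal <- c(1, 5, 2, 5, 1)
  expect_identical(time_reverse(pal), pal)
  s <- ppg_signal(x, fs = FS)
  rs <- time_reverse(s)
  expect_identical(rs$value, rev(x))
  expect_identical(rs$time, s$time)
})
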