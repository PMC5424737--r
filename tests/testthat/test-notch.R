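test_that("contraction factors follow r_j = 1 - j*delta and reject unstable banks", {
  expect_equal(contraction_factors(8, 0.02),
               c(0.98, 0.96, 0.94, 0.92, 0.90, 0.88, 0.86, 0.84))
  expect_equal(contraction_factors(1, 0.04), 0.96)
  expect_true(all(diff(contraction_factors(8, 0.03)) < 0))
  expect_error(contraction_factors(8, 0.2), "Unstable")
  expect_error(contraction_factors(8, 0.125), "Unstable")
})

test_that("section coefficients match the direct-form-2 formulas", {
  cf <- section_coefficients(pi / 3, 1, 0.98)
  expect_equal(cf$a1, 0.99)
  expect_equal(cf$a2, -0.98)
  expect_equal(cf$b1, -1.0)
  expect_equal(cf$k, 0.99)

  cf <- section_coefficients(pi / 2, 1, 0.96)
  expect_equal(cf$a1, 0, tolerance = 1e-15)
  expect_equal(cf$a2, -0.96)
  expect_equal(cf$b1, 0, tolerance = 1e-15)
  expect_equal(cf$k, 0.98)

  cf <- section_coefficients(0.1, 8, 0.84)
  expect_equal(cf$a1, 1.84 * cos(0.8))
  expect_equal(cf$a2, -0.84)
  expect_equal(cf$b1, -2 * cos(0.8))
  expect_equal(cf$k, 0.92)

  expect_error(section_coefficients(0.5, 8, 0.84), "pi")
})

test_that("frequency response has exact harmonic zeros and unit edge gain", {
  theta <- 2 * pi * 1.2 / FS
  bank <- notch_bank(8, 0.02)
  at_notches <- notch_frequency_response(theta, bank,
                                         omega = (1:8) * theta)
  expect_true(all(at_notches$magnitude < 1e-10))
  at_edges <- notch_frequency_response(theta, bank, omega = c(0, pi))
  expect_equal(at_edges$magnitude, c(1, 1), tolerance = 1e-12)
})

test_that("time-variant notch with constant track equals the LTI cascade oracle", {
  bank <- notch_bank(8, 0.02)
  theta <- 2 * pi * 1.2 / FS
  set.seed(11)
  u <- rnorm(3000)
  v <- apply_notch(u, bank, f0 = 1.2, fs = FS)$residual
  expect_lt(rel_rms(v, lti_cascade(u, theta, bank)), 1e-12)
})

test_that("the notch suppresses a sinusoid at its fundamental", {
  bank <- notch_bank(8, 0.02)
  u <- sinusoid(1.2, 60)
  v <- apply_notch(u, bank, f0 = 1.2, fs = FS)$residual
  steady <- (10 * FS + 1):length(u)
  expect_lt(sqrt(mean(v[steady]^2)), 1e-3 * sqrt(mean(u^2)))
})

test_that("the notch is linear and maps zeros to zeros", {
  bank <- notch_bank(8, 0.03)
  set.seed(12)
  n <- 1000
  track <- 2 * pi * runif(n, 0.8, 2.0) / FS
  expect_equal(apply_notch(numeric(n) + 0, bank, theta = track,
                           fs = FS)$residual,
               numeric(n))
  u1 <- rnorm(n)
  u2 <- rnorm(n)
  lhs <- apply_notch(2 * u1 - 3 * u2, bank, theta = track, fs = FS)$residual
  rhs <- 2 * apply_notch(u1, bank, theta = track, fs = FS)$residual -
    3 * apply_notch(u2, bank, theta = track, fs = FS)$residual
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("the cascade stays bounded under a random-walk frequency track", {
  bank <- notch_bank(8, 0.03)
  set.seed(13)
  n <- 60 * FS
  walk <- 1.5 + cumsum(rnorm(n, sd = 0.02))
  walk <- zle:::reflect_walk(walk, c(0.5, 3))
  track <- 2 * pi * walk / FS
  u <- rnorm(n)
  v <- apply_notch(u, bank, theta = track, fs = FS)$residual
  expect_true(all(is.finite(v)))
  expect_lt(max(abs(v)), 100 * max(abs(u)))
})

test_that("invalid inputs are rejected, not silently filtered", {
  bank <- notch_bank(8, 0.03)
  expect_error(apply_notch(c(1, NA, 2), bank, f0 = 1.2, fs = FS), "finite")
  expect_error(apply_notch(rnorm(10), bank, f0 = 7, fs = FS),
               "admissible")
  too_high <- rep(2 * pi * 1.2 / FS, 10)
  too_high[5] <- pi / 4 # 8th harmonic would hit 2*pi
  expect_error(apply_notch(rnorm(10), bank, theta = too_high, fs = FS),
               "admissible")
})
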