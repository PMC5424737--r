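# Shared fixtures, built in code.

FS <- 100

sinusoid <- function(freq, duration, fs = FS, phase = 0, amp = 1) {
  amp * sin(2 * pi * freq * (seq_len(round(duration * fs)) - 1) / fs + phase)
}

# Independent LTI oracle: cascade of time-invariant second-order
# sections built once from the section coefficients and run through
# signal::filter (a code path disjoint from the package's recursion).
lti_cascade <- function(u, theta, bank) {
  x <- u
  for (j in seq_len(bank$P)) {
    cf <- section_coefficients(theta, j, bank$r[j])
    b <- cf$k * c(1, cf$b1, 1)
    a <- c(1, -cf$a1, -cf$a2)
    x <- as.numeric(signal::filter(b, a, x))
  }
  x
}

rel_rms <- function(x, ref) sqrt(mean((x - ref)^2)) / sqrt(mean(ref^2))

# Amplitude of the sinusoidal component at `freq` in the steady-state
# part of x, by least squares on a sine/cosine pair.
tone_amplitude <- function(x, freq, fs = FS, discard = 10) {
  idx <- (round(discard * fs) + 1):length(x)
  t <- (idx - 1) / fs
  cf <- stats::lm.fit(cbind(sin(2 * pi * freq * t),
                            cos(2 * pi * freq * t)), x[idx])$coefficients
  sqrt(sum(cf^2))
}

# A standard 60 s contaminated record used by several suites.
make_contaminated <- function(snr_db = 0, seed = 1, duration = 60) {
  sim <- simulate_ppg(ppg_model(duration = duration), seed = seed)
  noise <- colored_noise(duration, FS, seed = seed + 10000L)
  list(sim = sim, mixed = mix_at_snr(sim, noise, snr_db))
}
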