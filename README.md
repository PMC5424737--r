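# zle — zero-phase line enhancement for photoplethysmograms

The photoplethysmogram (PPG) is a single-channel optical pulse signal
used by wearables for heart rate, heart-rate variability, SpO2 and
blood-pressure estimation. Limb motion injects low-frequency artifact
whose spectrum (roughly 0.5–2 Hz) overlaps the feasible heart-rate band,
so plain band-pass filtering cannot separate the two. This package
implements single-input motion-artifact reduction built around a
**time-variant harmonic IIR notch filter** and its **zero-phase
forward-backward variant**, for signal-processing researchers and
developers of pulse-waveform pipelines who need an artifact reducer that
does not require an accelerometer or second optical channel.

## The method

An adaptive lattice notch filter tracks the instantaneous fundamental
frequency (heart rate) θ(n), in rad/sample. A cascade of P second-order
notch sections is then placed at the harmonics jθ(n), j = 1…P:

    H(z, θ) = ∏_{j=1}^{P} (1 + r_j)/2 ·
              (1 − 2 cos(jθ) z⁻¹ + z⁻²) /
              (1 − (1 + r_j) cos(jθ) z⁻¹ + r_j z⁻²),   r_j = 1 − jδ

The notch bank removes the quasi-periodic pulse, so its residual v is
the motion-artifact estimate and **y = u − v** is the enhanced signal
(the causal *adaptive comb filter*, ACF). Because a single causal IIR
pass distorts phase whenever θ is misestimated, the **zero-phase line
enhancer (ZLE)** runs the time-variant notch forward, time-reverses,
runs it again with the reversed frequency track, and reverses once
more: for constant θ the composite input→artifact map is |H|² with
exactly zero phase. A moving-window scheme (100-sample transients
discarded around a 300-sample kept segment, windows overlapping by 200)
makes the batch ZLE real-time capable with one-window latency.

Also included: wavelet de-noising and cycle-by-cycle Fourier series
analysis (CFSA) baselines, a seeded synthetic PPG + colored-noise
generator, peak-detection metrics (Se, PPV, F1, MAE under a ±75 ms
acceptance window), and a Monte Carlo harness comparing all four
methods across an SNR grid with one-tailed paired t-tests.

## Worked example

```r
library(zle)

sim   <- simulate_ppg(ppg_model(duration = 60), seed = 1)   # clean + truth
noise <- colored_noise(60, fs = 100, seed = 1001)           # 0.5-2 Hz artifact
mixed <- mix_at_snr(sim, noise, snr_db = 0)

res <- enhance_zle(mixed)   # tracks theta, then forward-backward notch
res
#> # A tibble: 6,000 × 5
#>   time  input  theta  artifact enhanced
#>   <dbl>  <dbl>  <dbl>     <dbl>    <dbl>
#> 1  0    -0.734 0.0942 -0.465      -0.269
#> 2  0.01 -0.548 0.0717 -0.164      -0.385
#> 3  0.02 -0.362 0.0314 -0.000209   -0.361
#> 4  0.03 -0.176 0.0314  0.0823     -0.258
#> # i 5,996 more rows

idx <- 1001:6000  # discard the 10 s tracker burn-in
signal_correlation(mixed$value[idx], sim$value[idx])  # 0.656 before
signal_correlation(res$enhanced[idx], sim$value[idx]) # 0.721 after

det <- detect_peaks(res$enhanced, fs = 100); det <- det[det > 1000]
ref <- true_peaks(sim);                      ref <- ref[ref > 1000]
peak_metrics(match_peaks(ref, det, fs = 100))
#> # A tibble: 1 × 7
#>    n_tp  n_fp  n_fn    se   ppv    f1 mae_ms
#>   <int> <int> <int> <dbl> <dbl> <dbl>  <dbl>
#> 1    46    36    11  80.7  56.1  66.2   19.3
```

At 0 dB input SNR the enhanced waveform correlates with the clean pulse
at 0.72 versus 0.66 for the raw mixture on this record, and 81% of the
true systolic peaks are recovered within ±75 ms with a 19 ms mean
timing error. The full Monte Carlo comparison
(`run_monte_carlo()`) shows the same picture on average — at 0 dB the
mean correlation is about 0.80 for ZLE against 0.69–0.71 for the ACF,
CFSA and wavelet baselines — with one-tailed paired t-tests on
correlation, MAE and F1 all far below p = 0.001.

A thin command-line interface is installed as `exec/zle`
(`zle simulate | enhance | evaluate | montecarlo`); see the file header
for usage.

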