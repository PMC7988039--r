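test_that("energy flux density follows direct arithmetic", {
  dt <- 1e-6
  expect_equal(energy_flux_density(rep(1e6, 1000), dt), 90, tolerance = 1e-9)
  x <- stats::rnorm(512)
  expect_equal(energy_flux_density(2 * x, dt) - energy_flux_density(x, dt),
               20 * log10(2), tolerance = 1e-9)
  t <- (0:999) * dt
  s <- 1e6 * sin(2 * pi * 60e3 * t)
  expect_equal(energy_flux_density(s, dt), 86.99, tolerance = 1e-3)
  expect_error(energy_flux_density(numeric(10) , dt), "all-zero")
})

test_that("the -10 dB duration handles canonical envelope shapes", {
  fs <- 4e6; dt <- 1 / fs
  # rectangular burst of 100 us: within a sample of 100 us
  n <- round(100e-6 * fs)
  burst <- c(rep(0, 50), sin(2 * pi * 3e5 * (0:(n - 1)) / fs), rep(0, 50))
  expect_equal(duration_m10dB(burst, dt), 100e-6, tolerance = 0.03)
  # two identical narrowband pulses 300 us apart: outermost crossings
  t <- (0:4095) * dt
  pulse <- exp(-2 * pi^2 * 20e3^2 * (t - 5e-5)^2) * sin(2 * pi * 3e5 * t)
  single <- duration_m10dB(pulse, dt)
  sep <- round(300e-6 * fs)
  two <- pulse + c(rep(0, sep), pulse[seq_len(length(pulse) - sep)])
  expect_equal(duration_m10dB(two, dt), 300e-6 + single,
               tolerance = 0.02)
  expect_error(duration_m10dB(numeric(8), dt), "all-zero")
})

test_that("spectral moments recover line spectra", {
  # bin-centered lines over an integer number of cycles (the FFT length
  # is the next power of two, so fs is chosen to keep the lines on
  # bins), so the rectangular window leaks nothing
  fs <- 1.024e6; dt <- 1 / fs; n <- 16384; t <- (0:(n - 1)) * dt
  tone <- sin(2 * pi * 60e3 * t)
  m <- spectral_moments(tone, dt, zero_pad = 1)
  expect_equal(m[["centroid"]], 60e3, tolerance = 1e-6)
  expect_lt(m[["rms_bandwidth"]], fs / n)  # within one bin
  duo <- sin(2 * pi * 40e3 * t) + sin(2 * pi * 80e3 * t)
  m2 <- spectral_moments(duo, dt, zero_pad = 1)
  expect_equal(m2[["centroid"]], 60e3, tolerance = 1e-6)
  expect_equal(m2[["rms_bandwidth"]], 20e3, tolerance = 1e-6)
})

test_that("time-domain and spectral energies agree (Parseval)", {
  set.seed(42)
  x <- stats::rnorm(2048) * 1e5
  dt <- 5e-7
  e_time <- 10 * log10(sum(x^2) * dt)
  X <- stats::fft(x)
  e_spec <- 10 * log10(sum(Mod(X)^2) / length(x) * dt)
  expect_lt(abs(e_time - e_spec), 0.1)
})

test_that("echo-to-click ratios follow amplitude scaling", {
  p <- generate_pulse(sample_rate = 2e6)$samples
  expect_equal(echo_click_ratio(p, p), 0)
  expect_equal(echo_click_ratio(p / 2, p), -20 * log10(2), tolerance = 1e-9)
  expect_error(echo_click_ratio(p, numeric(length(p))), "zero click")
})

test_that("highlight detection counts interface reflections", {
  fs <- 2e6; dt <- 1 / fs
  p <- generate_pulse(f0 = 60e3, sample_rate = fs)$samples
  expect_length(detect_highlights(p, dt), 1)
  x <- c(p, rep(0, 400))
  sep <- round(30e-6 * fs)
  two <- x + c(rep(0, sep), x[seq_len(length(x) - sep)])
  hl <- detect_highlights(two, dt)
  expect_length(hl, 2)
  expect_equal((hl[2] - hl[1]) * 1e6, 30, tolerance = 1 / 30)
  expect_length(detect_highlights(numeric(16), dt), 0)
})

test_that("the sliding energy window behaves as an energy detector", {
  dt <- 1e-6
  inside <- c(rep(0, 100), rep(1e6, 100), rep(0, 100))
  expect_equal(energy_in_window(inside, dt, window = 264e-6),
               energy_flux_density(inside, dt), tolerance = 1e-9)
  # constant trace twice the window length: half the energy
  const <- rep(1e6, 2 * 264)
  expect_equal(energy_in_window(const, dt, window = 264e-6),
               energy_flux_density(const, dt) - 10 * log10(2),
               tolerance = 1e-3)
  expect_error(energy_in_window(const, dt, window = 1e-7), "one sample")
})

test_that("metrics are invariant to uniform scaling except levels", {
  p <- generate_pulse(sample_rate = 2e6)
  x <- p$samples * 1e6
  dt <- 1 / p$sample_rate
  for (k in c(0.1, 3, 250)) {
    expect_equal(duration_m10dB(k * x, dt), duration_m10dB(x, dt))
    expect_equal(spectral_moments(k * x, dt), spectral_moments(x, dt),
                 tolerance = 1e-9)
    expect_equal(detect_highlights(k * x, dt), detect_highlights(x, dt))
    expect_equal(energy_flux_density(k * x, dt) - energy_flux_density(x, dt),
                 20 * log10(k), tolerance = 1e-9)
    expect_equal(peak_to_peak_level(k * x) - peak_to_peak_level(x),
                 20 * log10(k), tolerance = 1e-9)
  }
})
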