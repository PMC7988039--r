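#' Amplitude envelope of a pressure trace
#'
#' Magnitude of the analytic signal, computed by zeroing the negative
#' frequencies of the FFT.
#'
#' @param x Numeric time series.
#' @return Non-negative envelope of the same length.
#' @export
envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Energy flux density of a trace
#'
#' `10 * log10( sum(p^2) * dt )` with pressure in micropascals, i.e. the
#' time integral of squared pressure expressed in dB re 1 uPa^2 s.
#'
#' @param pressure Pressure samples in micropascals.
#' @param dt Sample interval in seconds.
#' @return Level in dB re 1 uPa^2 s.
#' @export
#' @examples
#' energy_flux_density(rep(1e6, 1000), 1e-6)  # 90 dB
energy_flux_density <- function(pressure, dt) {
  if (all(pressure == 0)) stop("energy flux density of an all-zero trace is undefined")
  10 * log10(sum(pressure^2) * dt)
}

#' Echo duration by the -10 dB envelope criterion
#'
#' Time between the outermost crossings of the amplitude envelope through
#' 10^(-10/20) of its maximum, with the crossing instants located by
#' linear interpolation. Outermost (rather than contiguous main-lobe)
#' crossings are used so that multi-highlight echoes report their full
#' extent.
#'
#' @param pressure Pressure samples.
#' @param dt Sample interval (s).
#' @return Duration in seconds.
#' @export
duration_m10dB <- function(pressure, dt) {
  if (all(pressure == 0)) stop("duration of an all-zero trace is undefined")
  env <- envelope(pressure)
  thr <- max(env) * 10^(-10 / 20)
  above <- which(env >= thr)
  i0 <- above[1]; i1 <- above[length(above)]
  t0 <- (i0 - 1) * dt
  if (i0 > 1) {
    t0 <- t0 - dt * (env[i0] - thr) / (env[i0] - env[i0 - 1])
  }
  t1 <- (i1 - 1) * dt
  if (i1 < length(env)) {
    t1 <- t1 + dt * (env[i1] - thr) / (env[i1] - env[i1 + 1])
  }
  t1 - t0
}

#' Spectral centroid and RMS bandwidth
#'
#' First spectral moment of the power spectrum over positive frequencies
#' and the square root of the second central moment:
#' centroid = integral(f |S|^2) / integral(|S|^2),
#' bandwidth = sqrt(integral((f - centroid)^2 |S|^2) / integral(|S|^2)).
#' The FFT is zero-padded for smooth moment integrals; an optional band
#' restriction excludes DC and grid-dispersion artifacts when analyzing
#' solver traces.
#'
#' @param pressure Pressure samples.
#' @param dt Sample interval (s).
#' @param band Length-2 numeric, frequency band (Hz) over which moments
#'   are taken; default the full positive axis.
#' @param zero_pad Zero-padding factor (>= 1); default 8.
#' @return Named numeric: `centroid` and `rms_bandwidth`, both Hz.
#' @export
#' @examples
#' p <- generate_pulse(f0 = 60e3, sample_rate = 2e6)
#' spectral_moments(p$samples, 1 / p$sample_rate)  # bandwidth ~37.7 kHz
spectral_moments <- function(pressure, dt, band = c(0, Inf), zero_pad = 8) {
  if (all(pressure == 0)) stop("spectral moments of an all-zero trace are undefined")
  n <- length(pressure)
  nfft <- 2^ceiling(log2(n * zero_pad))
  X <- stats::fft(c(pressure, rep(0, nfft - n)))
  f <- (seq_len(nfft) - 1) / (nfft * dt)
  keep <- f <= 1 / (2 * dt) & f >= band[1] & f <= band[2]
  f <- f[keep]
  P <- Mod(X[keep])^2
  fc <- sum(f * P) / sum(P)
  bw <- sqrt(sum((f - fc)^2 * P) / sum(P))
  c(centroid = fc, rms_bandwidth = bw)
}

#' Peak-to-peak level of a trace
#'
#' @param pressure Pressure samples in micropascals.
#' @return Level in dB re 1 uPa (peak-to-peak).
#' @export
peak_to_peak_level <- function(pressure) {
  20 * log10(max(pressure) - min(pressure))
}

#' Echo-to-click level ratio
#'
#' `20 * log10( pp(echo) / pp(click) )`, the peak-to-peak level difference
#' between the time-gated returning echo and the outgoing click at the
#' on-axis 0.5 m calibration point.
#'
#' @param echo,click Pressure sample vectors (same units).
#' @return Ratio in dB.
#' @export
echo_click_ratio <- function(echo, click) {
  ppc <- max(click) - min(click)
  if (ppc == 0) stop("zero click trace")
  20 * log10((max(echo) - min(echo)) / ppc)
}

#' Split a calibration-point trace into outgoing click and returning echo
#'
#' The gate is placed a round trip from the calibration point to the
#' target after the click peak, minus a guard interval, separating the
#' outgoing click window from the returning echo window.
#'
#' @param trace A trace from [get_trace()].
#' @param target_distance Source-to-target distance (m).
#' @param cal_offset Source-to-calibration-point distance (m).
#' @param c_water Sound speed (m/s).
#' @param guard Guard interval (s) subtracted from the nominal echo
#'   arrival.
#' @return List with `click` and `echo` pressure vectors, the `gate` time
#'   (s) and the click peak time.
#' @export
split_click_echo <- function(trace, target_distance = 1.1,
                             cal_offset = 0.5, c_water = 1527,
                             guard = 60e-6) {
  p <- trace$pressure
  t <- trace$time
  # click peak: restricted to times before any target return can exist
  t_min_echo <- (2 * (target_distance - cal_offset)) / c_water
  early <- t <= t[1] + t_min_echo * 0.8 + (t[2] - t[1])
  tpk <- t[early][which.max(abs(p[early]))]
  gate <- tpk + 2 * (target_distance - cal_offset) / c_water - guard
  list(click = p[t <= gate], echo = p[t > gate], gate = gate,
       click_peak_time = tpk)
}

#' Detect echo highlights
#'
#' Finds the local maxima of the amplitude envelope that qualify as echo
#' highlights. A peak counts if it satisfies both of:
#' \itemize{
#'   \item height within `max_below_peak` dB of the strongest peak -- the
#'     same -10 dB convention used for the duration criterion; weaker
#'     structure (e.g. second-order reverberation, two layer bounces
#'     down) is not a highlight;
#'   \item topographic prominence of at least `min_prominence` dB -- the
#'     peak must rise that far above the highest saddle connecting it to
#'     larger envelope values, which separates arrivals rising from deep
#'     valleys (distinct interface reflections) from first-order
#'     reverberation riding on the shoulder of its parent peak.
#' }
#' Peaks closer than `min_separation` are merged (the stronger wins).
#'
#' @param pressure Pressure samples.
#' @param dt Sample interval (s).
#' @param min_separation Minimum separation between highlights (s).
#' @param min_prominence Minimum topographic prominence (dB).
#' @param max_below_peak Height window below the strongest peak (dB).
#' @return Numeric vector of highlight times (s), sorted ascending; may be
#'   empty.
#' @export
detect_highlights <- function(pressure, dt, min_separation = 15e-6,
                              min_prominence = 10, max_below_peak = 10) {
  env <- envelope(pressure)
  n <- length(env)
  if (n < 3 || max(env) == 0) return(numeric(0))
  db <- 20 * log10(pmax(env, max(env) * 1e-8) / max(env))
  pk <- which(diff(sign(diff(db))) < 0) + 1
  pk <- pk[db[pk] >= -max_below_peak]
  if (length(pk) == 0) return(numeric(0))
  prom <- vapply(pk, function(i) {
    side <- function(idx) {
      higher <- which(db[idx] > db[i])
      path <- if (length(higher) == 0) idx else idx[seq_len(higher[1] - 1)]
      if (length(path) == 0) -Inf else min(db[path])
    }
    left <- if (i > 1) side(rev(seq_len(i - 1))) else -Inf
    right <- if (i < n) side(seq(i + 1, n)) else -Inf
    db[i] - max(left, right)
  }, numeric(1))
  pk <- pk[prom >= min_prominence]
  if (length(pk) == 0) return(numeric(0))
  ord <- pk[order(env[pk], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(i - kept) * dt >= min_separation)) kept <- c(kept, i)
  }
  sort((kept - 1) * dt)
}

#' Energy in the best-placed sliding window
#'
#' Maximum over placements of the energy flux density restricted to a
#' sliding window, emulating the ~264 us energy-detector integration
#' window of the dolphin's auditory system.
#'
#' @param pressure Pressure samples in micropascals.
#' @param dt Sample interval (s).
#' @param window Window length (s); default 264 us.
#' @return Level in dB re 1 uPa^2 s.
#' @export
energy_in_window <- function(pressure, dt, window = 264e-6) {
  w <- round(window / dt)
  if (w < 1) stop("window shorter than one sample")
  e <- pressure^2
  if (w >= length(e)) return(10 * log10(sum(e) * dt))
  cs <- cumsum(e)
  win <- cs[w:length(e)] - c(0, cs[seq_len(length(e) - w)])
  10 * log10(max(win) * dt)
}

#' Table-style echo metric bundle for one trace
#'
#' Computes the five-column characterization of a click or time-gated
#' echo: energy flux density, -10 dB duration, centroid frequency, RMS
#' bandwidth and peak-to-peak level.
#'
#' @param pressure Pressure samples in micropascals.
#' @param dt Sample interval (s).
#' @param band Frequency band (Hz) for the spectral moments; the default
#'   10-200 kHz excludes DC and grid-dispersion artifacts of solver
#'   traces.
#' @return A one-row data frame with columns `energy_flux_density_db`,
#'   `duration_us`, `centroid_khz`, `rms_bandwidth_khz`, `pp_level_db`.
#' @export
echo_metrics <- function(pressure, dt, band = c(10e3, 200e3)) {
  mom <- spectral_moments(pressure, dt, band = band)
  data.frame(
    energy_flux_density_db = energy_flux_density(pressure, dt),
    duration_us = duration_m10dB(pressure, dt) * 1e6,
    centroid_khz = mom[["centroid"]] / 1e3,
    rms_bandwidth_khz = mom[["rms_bandwidth"]] / 1e3,
    pp_level_db = peak_to_peak_level(pressure)
  )
}
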