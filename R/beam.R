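#' Beam pattern from field snapshots on a circle
#'
#' For each angle, takes the peak-to-peak pressure over time at the
#' corresponding point of a circle (bilinear interpolation off-grid),
#' normalizes to the circle maximum, and converts to SPL via
#' `SPL = A + 20 * log10(P)` with `P` the normalized peak-to-peak
#' pressure.
#'
#' @param snapshots List of pressure matrices (one per recorded instant),
#'   as stored in a `sim_result`.
#' @param dx Grid spacing (m).
#' @param origin Grid origin (m), the coordinates of cell `[1, 1]`.
#' @param center Circle center (x, z) in meters.
#' @param radius Circle radius (m).
#' @param angles Angles in degrees at which to sample. Angle 0 is the -x
#'   direction (back toward the source) unless `axis = "+x"`.
#' @param axis `"-x"` (echo patterns, facing the dolphin) or `"+x"`
#'   (transmit patterns).
#' @param A Normalization constant (dB); the pattern maximum equals `A`.
#' @return An object of class `beam_pattern`: list with `angles`, `spl`,
#'   `A`, `center`, `radius`.
#' @export
beam_pattern <- function(snapshots, dx, origin, center, radius,
                         angles = seq(-60, 60, by = 0.25),
                         axis = c("-x", "+x"), A = 0) {
  if (length(snapshots) == 0) stop("empty snapshot list")
  axis <- match.arg(axis)
  sgn <- if (axis == "-x") -1 else 1
  px <- center[1] + sgn * radius * cos(angles * pi / 180)
  pz <- center[2] + radius * sin(angles * pi / 180)
  nx <- nrow(snapshots[[1]]); nz <- ncol(snapshots[[1]])
  gi <- (px - origin[1]) / dx + 1
  gj <- (pz - origin[2]) / dx + 1
  if (any(gi < 1 | gi > nx | gj < 1 | gj > nz)) {
    stop("beam-pattern circle extends outside the snapshot grid")
  }
  i0 <- pmin(floor(gi), nx - 1); j0 <- pmin(floor(gj), nz - 1)
  fx <- gi - i0; fz <- gj - j0
  vals <- sapply(snapshots, function(s) {
    s[cbind(i0, j0)] * (1 - fx) * (1 - fz) +
      s[cbind(i0 + 1, j0)] * fx * (1 - fz) +
      s[cbind(i0, j0 + 1)] * (1 - fx) * fz +
      s[cbind(i0 + 1, j0 + 1)] * fx * fz
  })
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(angles))
  pp <- apply(vals, 1, function(v) max(v) - min(v))
  beam_pattern_from_pp(pp, angles, A = A, center = center, radius = radius)
}

#' Beam pattern from receiver-arc traces
#'
#' Equivalent to [beam_pattern()] but using the pressure traces recorded
#' directly at the arc receivers of a scene, which avoids storing full
#' field snapshots.
#'
#' Two amplitude readings are available. `"pp"` (default) is the
#' broadband peak-to-peak pressure of the transiting signal, the reading
#' used for echo beam patterns. `"tone"` extracts the spectral amplitude
#' at `f0` per angle; for very broadband clicks the peak-to-peak pattern
#' is measurably narrower than the single-frequency pattern the aperture
#' calibration is defined against, so the transmit-beam calibration
#' check reads the `f0` component.
#'
#' @param result A `sim_result` from a scene built with an arc.
#' @param A Normalization constant (dB).
#' @param time_window Optional length-2 numeric (s) restricting the
#'   analysis (e.g. to the echo transit window).
#' @param component `"pp"` (peak-to-peak) or `"tone"` (spectral
#'   amplitude at `f0`).
#' @param f0 Frequency (Hz) of the `"tone"` component; defaults to the
#'   scene's click peak frequency.
#' @return A `beam_pattern`.
#' @export
beam_pattern_from_arc <- function(result, A = 0, time_window = NULL,
                                  component = c("pp", "tone"),
                                  f0 = NULL) {
  component <- match.arg(component)
  arc <- result$scene$arc
  if (is.null(arc)) stop("scene has no receiver arc")
  idx <- match(arc$names, result$receivers$name)
  tr <- result$traces[, idx, drop = FALSE]
  if (!is.null(time_window)) {
    keep <- result$time >= time_window[1] & result$time <= time_window[2]
    tr <- tr[keep, , drop = FALSE]
  }
  if (component == "pp") {
    amp <- apply(tr, 2, function(v) max(v) - min(v))
  } else {
    if (is.null(f0)) f0 <- result$scene$f0
    n <- nrow(tr)
    w <- exp(-2i * pi * f0 * (seq_len(n) - 1) * result$dt)
    amp <- abs(as.vector(crossprod(tr, w))) / n
  }
  beam_pattern_from_pp(amp, arc$angles, A = A, center = arc$center,
                       radius = arc$radius)
}

beam_pattern_from_pp <- function(pp, angles, A = 0, center = NULL,
                                 radius = NULL) {
  if (max(pp) == 0) stop("all-zero field on the beam-pattern circle")
  spl <- A + 20 * log10(pp / max(pp))
  structure(list(angles = angles, spl = spl, A = A,
                 center = center, radius = radius),
            class = "beam_pattern")
}

#' @export
print.beam_pattern <- function(x, ...) {
  cat(sprintf("beam_pattern: %d angles in [%g, %g] deg, max at %g deg\n",
              length(x$angles), min(x$angles), max(x$angles),
              x$angles[which.max(x$spl)]))
  invisible(x)
}

#' 3-dB beamwidth of a beam pattern
#'
#' Angular distance between the -3 dB crossings bracketing the global
#' maximum, located by linear interpolation between angular samples. If
#' the pattern never falls 3 dB below its maximum the full sampled span
#' is returned with attribute `flat = TRUE`.
#'
#' @param pattern A `beam_pattern`.
#' @return Beamwidth in degrees.
#' @export
beamwidth_3dB <- function(pattern) {
  spl <- pattern$spl - max(pattern$spl)
  ang <- pattern$angles
  imax <- which.max(spl)[1]  # lowest-angle lobe on ties
  cross <- function(side) {
    idx <- if (side < 0) seq(imax, 1) else seq(imax, length(ang))
    below <- which(spl[idx] <= -3)
    if (length(below) == 0) return(NA_real_)
    k <- idx[below[1]]; kprev <- idx[below[1] - 1]
    ang[kprev] + (ang[k] - ang[kprev]) *
      (-3 - spl[kprev]) / (spl[k] - spl[kprev])
  }
  lo <- cross(-1); hi <- cross(+1)
  if (is.na(lo) || is.na(hi)) {
    out <- diff(range(ang))
    attr(out, "flat") <- TRUE
    return(out)
  }
  hi - lo
}

#' Count beam-pattern lobes
#'
#' Local maxima of the pattern within an angular window and above a
#' height floor relative to the pattern maximum. Used to contrast the
#' single dominant main lobe of the pipe echoes with the multi-lobe
#' interference pattern of the foam-ball array.
#'
#' @param pattern A `beam_pattern`.
#' @param within Length-2 angular window (degrees).
#' @param floor_db Height floor relative to the maximum (dB, negative).
#' @param min_separation Minimum lobe separation (degrees).
#' @return Angles (degrees) of the detected lobes.
#' @export
beam_lobes <- function(pattern, within = c(-45, 45), floor_db = -20,
                       min_separation = 2) {
  keep <- pattern$angles >= within[1] & pattern$angles <= within[2]
  ang <- pattern$angles[keep]
  spl <- pattern$spl[keep] - max(pattern$spl)
  pk <- which(diff(sign(diff(spl))) < 0) + 1
  if (spl[1] > spl[2]) pk <- c(1, pk)
  n <- length(spl)
  if (spl[n] > spl[n - 1]) pk <- c(pk, n)
  pk <- pk[spl[pk] >= floor_db]
  if (length(pk) == 0) return(numeric(0))
  ord <- pk[order(spl[pk], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(ang[i] - ang[kept]) >= min_separation)) kept <- c(kept, i)
  }
  sort(ang[kept])
}

#' In-plane directivity index of a beam pattern
#'
#' 2D definition: `DI = 10 * log10( 2 * pi / integral(D(theta)^2) )` with
#' `D` the amplitude pattern normalized to 1 at its maximum and the
#' integral taken in radians over the full circle. A pattern sampled over
#' a half-plane (span <= 185 degrees) is assumed front-back symmetric and
#' its integral doubled; energy outside the sampled span of a narrow beam
#' is negligible.
#'
#' @param pattern A `beam_pattern`.
#' @return Directivity index in dB (0 for an omnidirectional pattern).
#' @export
directivity_index <- function(pattern) {
  D <- 10^((pattern$spl - max(pattern$spl)) / 20)
  th <- pattern$angles * pi / 180
  integ <- pracma::trapz(th, D^2)
  span <- diff(range(pattern$angles))
  if (span <= 185) integ <- 2 * integ
  10 * log10(2 * pi / integ)
}
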