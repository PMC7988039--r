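#' Acoustic material constants used in the target-discrimination models
#'
#' Returns the table of fluid-equivalent acoustic properties for the media
#' appearing in the simulated scenes: the seawater background (salinity and
#' temperature as measured in the experimental pool), the PVC pipe material,
#' the foam-ball material, the soft closed-cell foam wrap, and air (for the
#' sealed pipe interiors). Only sound speed and density are carried; all
#' media are lossless.
#'
#' @return A data frame with columns `name`, `sound_speed` (m/s) and
#'   `density` (kg/m^3).
#' @export
#' @examples
#' material_table()
material_table <- function() {
  data.frame(
    name = c("seawater", "PVC", "foam-ball", "closed-cell-foam", "air"),
    sound_speed = c(1527, 2218, 500, 1700, 343),
    density = c(1022, 1350, 300, 330, 1.2),
    stringsAsFactors = FALSE
  )
}

#' Look up one material
#'
#' @param name Material name; one of `"seawater"`, `"PVC"`, `"foam-ball"`,
#'   `"closed-cell-foam"`, `"air"`.
#' @return A list with `name`, `sound_speed` (m/s), `density` (kg/m^3) and
#'   `impedance` (rayl).
#' @export
#' @examples
#' material("PVC")
material <- function(name) {
  tab <- material_table()
  i <- match(name, tab$name)
  if (is.na(i)) {
    stop("unknown material '", name, "'; available: ",
         paste(tab$name, collapse = ", "))
  }
  list(name = tab$name[i], sound_speed = tab$sound_speed[i],
       density = tab$density[i],
       impedance = tab$sound_speed[i] * tab$density[i])
}

#' Plane-wave pressure reflection coefficient at a fluid-fluid interface
#'
#' Normal-incidence reflection coefficient (Z2 - Z1) / (Z2 + Z1) with
#' Z = rho * c, used as the analytic oracle for interface reflections in the
#' wave solver and to reason about the target cases (e.g. the near-total,
#' phase-reversed reflection at a water/air interface).
#'
#' @param m1,m2 Materials: either names accepted by [material()] or lists
#'   with `sound_speed` and `density` fields.
#' @return Dimensionless signed amplitude reflection coefficient.
#' @export
#' @examples
#' reflection_coefficient("seawater", "PVC")   # +0.315
#' reflection_coefficient("seawater", "air")   # ~ -1
reflection_coefficient <- function(m1, m2) {
  as_mat <- function(m) if (is.character(m)) material(m) else m
  m1 <- as_mat(m1); m2 <- as_mat(m2)
  stopifnot(m1$sound_speed > 0, m1$density > 0,
            m2$sound_speed > 0, m2$density > 0)
  z1 <- m1$sound_speed * m1$density
  z2 <- m2$sound_speed * m2$density
  (z2 - z1) / (z2 + z1)
}

#' Acoustic wavelength
#'
#' @param sound_speed Sound speed in m/s (default: seawater).
#' @param frequency Frequency in Hz (default: the 60 kHz click peak
#'   frequency).
#' @return Wavelength in meters.
#' @export
#' @examples
#' wavelength()  # 0.02545 m at 60 kHz in seawater
wavelength <- function(sound_speed = material("seawater")$sound_speed,
                       frequency = 60e3) {
  stopifnot(sound_speed > 0, frequency > 0)
  sound_speed / frequency
}

#' Normal-incidence reflection from a layered stack
#'
#' Frequency-domain reflection coefficient of a stack of fluid layers
#' between two half-spaces, by the standard input-impedance recursion.
#' This is the analytic oracle for the target cross-sections: the
#' air-filled pipe front (water | 3 mm PVC | air), the water-filled pipe
#' (water | PVC | water | PVC | water), and the foam-wrapped pipe
#' (water | foam | PVC | air).
#'
#' @param f Frequencies in Hz (>= 0).
#' @param layers List of layers, each a list or vector with elements
#'   `c` (m/s), `rho` (kg/m^3), `d` (thickness, m), ordered from the
#'   incident side.
#' @param load Material name or list for the terminating half-space.
#' @param incident Material name or list for the incident half-space
#'   (default seawater).
#' @return Complex reflection coefficient, one per frequency.
#' @export
#' @examples
#' # 3 mm PVC wall in water at 60 kHz
#' Mod(stack_reflection(60e3, list(c(2218, 1350, 3e-3)), "seawater"))
stack_reflection <- function(f, layers, load, incident = "seawater") {
  as_mat <- function(m) if (is.character(m)) material(m) else m
  zl <- as_mat(load); z0 <- as_mat(incident)
  z_load <- zl$sound_speed * zl$density
  z_inc <- z0$sound_speed * z0$density
  vapply(f, function(ff) {
    Z <- complex(real = z_load)
    if (ff > 0) {
      for (L in rev(layers)) {
        L <- as.numeric(unlist(L))
        zc <- L[1] * L[2]
        k <- 2 * pi * ff / L[1]
        Z <- zc * (Z + 1i * zc * tan(k * L[3])) /
          (zc + 1i * Z * tan(k * L[3]))
      }
    }
    (Z - z_inc) / (Z + z_inc)
  }, complex(1))
}

#' Broadband peak-to-peak reflectivity of a layered stack
#'
#' Applies [stack_reflection()] across the spectrum of a source pulse and
#' returns the peak-to-peak amplitude of the reflected wavelet relative
#' to the incident one -- the quantity that, combined with image-source
#' spreading, predicts the simulated echo-to-click level ratios.
#'
#' @param layers,load,incident As in [stack_reflection()].
#' @param pulse A [generate_pulse()] object; default the standard click.
#' @return Peak-to-peak amplitude ratio (dimensionless).
#' @export
stack_pp_reflectivity <- function(layers, load, incident = "seawater",
                                  pulse = generate_pulse(sample_rate = 4e6)) {
  q <- pulse$samples
  n <- length(q)
  nfft <- 2^ceiling(log2(4 * n))
  Q <- stats::fft(c(q, rep(0, nfft - n)))
  dt <- 1 / pulse$sample_rate
  f <- (seq_len(nfft) - 1) / (nfft * dt)
  neg <- f > 1 / (2 * dt)
  fa <- f; fa[neg] <- 1 / dt - f[neg]
  R <- stack_reflection(fa, layers, load, incident)
  R[neg] <- Conj(R[neg])
  w <- Re(stats::fft(Q * R, inverse = TRUE) / nfft)
  (max(w) - min(w)) / (max(q) - min(q))
}
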