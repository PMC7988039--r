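#' Build a complete target-discrimination scene
#'
#' Assembles the simulated experiment for one material case: a seawater
#' domain with the target rasterized at 1.1 m from the source, the
#' calibrated finite-aperture surrogate source (standing in for the
#' phonic-lips/head system), a lower-jaw-proxy receiver 0.10 m below and
#' 0.05 m behind the source, an on-axis calibration receiver 0.5 m from
#' the source (where echo-to-click level ratios are defined), and
#' optionally a receiver arc on the 0.5 m circle centered on the target
#' for echo beam patterns.
#'
#' Two resolution presets are provided: `"desk"` (dx = 1.5 mm, reduced
#' 1.6 m x 1.0 m domain) for routine runs, and `"paper"` (dx = 1.0 mm,
#' larger domain) for closer quantitative work.
#'
#' @param case_kind `"AF"`, `"WF"`, `"FB"`, `"SF"`, or `"none"` for a
#'   uniform seawater scene with the same layout.
#' @param preset `"desk"` or `"paper"`.
#' @param dx,domain Override grid spacing (m) and domain extent
#'   `c(Lx, Lz)` (m).
#' @param target_distance Source-to-target-center distance (m).
#' @param aperture_beamwidth Far-field 3-dB beamwidth (degrees) the
#'   surrogate aperture is calibrated to; ignored if `point_source`.
#' @param point_source Use a single-cell omnidirectional source instead of
#'   the calibrated aperture.
#' @param arc One of `"target"` (echo beam-pattern arc centered on the
#'   target), `"none"`.
#' @param arc_radius,arc_half_span,arc_step Arc radius (m), half angular
#'   span and step (degrees). Angle 0 points from the arc center back
#'   toward the source.
#' @param f0 Click peak frequency (Hz).
#' @param amplitude Source pulse amplitude (Pa).
#' @param duration Simulated time (s); the default covers the round trip
#'   to the target plus the longest expected echo.
#' @param geometry Optional [target_geometry()] override (its center is
#'   repositioned to the scene layout).
#' @return An object of class `scene`.
#' @export
#' @examples
#' sc <- build_scene("AF")
#' sqrt(sum((sc$target$center - sc$source$position)^2))  # 1.1 m
build_scene <- function(case_kind = c("AF", "WF", "FB", "SF", "none"),
                        preset = c("desk", "paper"),
                        dx = NULL, domain = NULL,
                        target_distance = 1.1,
                        aperture_beamwidth = 11.1,
                        point_source = FALSE,
                        arc = c("target", "none"),
                        arc_radius = 0.5, arc_half_span = 60,
                        arc_step = 0.25,
                        f0 = 60e3, amplitude = 1,
                        duration = NULL, geometry = NULL) {
  case_kind <- match.arg(case_kind)
  preset <- match.arg(preset)
  arc <- match.arg(arc)
  if (is.null(dx)) dx <- if (preset == "desk") 1.5e-3 else 1.0e-3
  if (is.null(domain)) {
    domain <- if (preset == "desk") c(1.6, 1.0) else c(1.8, 1.1)
  }
  c_w <- material("seawater")$sound_speed
  nx <- round(domain[1] / dx) + 1
  nz <- round(domain[2] / dx) + 1
  m <- medium_map(nx, nz, dx)
  check_mesh_rule(m, f0)

  snap_idx <- function(p) c(round(p[1] / dx) + 1, round(p[2] / dx) + 1)
  snap_pos <- function(p) (snap_idx(p) - 1) * dx

  source_pos <- snap_pos(c(0.15, domain[2] / 2))
  target_center <- source_pos + c(target_distance, 0)
  target_center <- snap_pos(target_center)
  # keep the 1.1 m separation exact after snapping
  target_center[1] <- source_pos[1] + target_distance

  # source: vertical aperture of calibrated length (or a point)
  if (point_source) {
    ap_len <- 0
  } else {
    ap_len <- calibrate_aperture(aperture_beamwidth, f0, c_w)$length
  }
  sidx <- snap_idx(source_pos)
  n_half <- if (ap_len > 0) floor((ap_len / 2) / dx) else 0L
  jj <- (sidx[2] - n_half):(sidx[2] + n_half)
  elements <- data.frame(i = rep(sidx[1], length(jj)), j = jj,
                         w = rep(1 / length(jj), length(jj)))

  # receivers
  recs <- list(jaw = source_pos + c(-0.05, -0.10),
               cal = source_pos + c(0.5, 0))
  rec_df <- do.call(rbind, lapply(names(recs), function(nm) {
    ij <- snap_idx(recs[[nm]])
    data.frame(name = nm, x = (ij[1] - 1) * dx, z = (ij[2] - 1) * dx,
               i = ij[1], j = ij[2], stringsAsFactors = FALSE)
  }))
  arc_info <- NULL
  if (arc == "target") {
    angles <- seq(-arc_half_span, arc_half_span, by = arc_step)
    # angle 0 points from the target center back toward the source
    px <- target_center[1] - arc_radius * cos(angles * pi / 180)
    pz <- target_center[2] + arc_radius * sin(angles * pi / 180)
    adf <- do.call(rbind, lapply(seq_along(angles), function(k) {
      ij <- snap_idx(c(px[k], pz[k]))
      data.frame(name = sprintf("arc_%04d", k),
                 x = (ij[1] - 1) * dx, z = (ij[2] - 1) * dx,
                 i = ij[1], j = ij[2], stringsAsFactors = FALSE)
    }))
    rec_df <- rbind(rec_df, adf)
    arc_info <- list(center = target_center, radius = arc_radius,
                     angles = angles,
                     names = adf$name)
  }

  # target
  geom <- NULL
  if (case_kind != "none") {
    if (is.null(geometry)) {
      geom <- target_geometry(case_kind, center = target_center)
    } else {
      stopifnot(geometry$case_kind == case_kind)
      geom <- geometry
      geom$center <- target_center
      validate_geometry(geom)
    }
    X <- matrix(map_x(m), nx, nz)
    Z <- matrix(map_z(m), nx, nz, byrow = TRUE)
    names_mat <- rasterize_case(X, Z, geom)
    tab <- material_table()
    idx <- match(names_mat, tab$name)
    m$sound_speed <- matrix(tab$sound_speed[idx], nx, nz)
    m$density <- matrix(tab$density[idx], nx, nz)
    # the resolution precondition of the rasterizer
    feat <- min_feature(geom)
    limit <- if (case_kind %in% c("AF", "WF")) feat / 2 else feat
    if (dx > limit + 1e-12) {
      stop(sprintf("dx = %g m too coarse for the %s target (need <= %g m)",
                   dx, case_kind, limit))
    }
  }

  if (is.null(duration)) {
    duration <- 2 * target_distance / c_w + 5.5e-4
  }

  sc <- structure(list(medium = m, dx = dx, f0 = f0, amplitude = amplitude,
                       case_kind = case_kind, preset = preset,
                       domain = domain,
                       source = list(position = source_pos,
                                     length = ap_len,
                                     orientation = c(1, 0),
                                     elements = elements),
                       receivers = rec_df, arc = arc_info,
                       target = geom,
                       target_distance = target_distance,
                       duration = duration),
                  class = "scene")
  validate_scene(sc)
  sc
}

validate_scene <- function(sc, absorbing_cells = 40) {
  m <- sc$medium
  margin <- absorbing_cells * sc$dx
  lim_x <- c(margin, (m$nx - 1) * sc$dx - margin)
  lim_z <- c(margin, (m$nz - 1) * sc$dx - margin)
  inside <- function(x, z) {
    x >= lim_x[1] & x <= lim_x[2] & z >= lim_z[1] & z <= lim_z[2]
  }
  if (!all(inside(sc$receivers$x, sc$receivers$z))) {
    stop("receiver(s) fall inside the absorbing margin or outside the grid")
  }
  ez <- sc$source$elements
  if (any(ez$i < 1 | ez$i > m$nx | ez$j < 1 | ez$j > m$nz)) {
    stop("source aperture extends outside the grid")
  }
  if (!is.null(sc$target)) {
    d <- sqrt(sum((sc$target$center - sc$source$position)^2))
    stopifnot(abs(d - sc$target_distance) < 1e-9)
  }
  invisible(sc)
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("scene: case %s, %s preset, dx = %g mm, domain %.2f x %.2f m\n",
              x$case_kind, x$preset %||% "custom", x$dx * 1e3,
              x$domain[1] %||% NA, x$domain[2] %||% NA))
  cat(sprintf("  source at (%.3f, %.3f), aperture %.1f mm, %d receivers\n",
              x$source$position[1], x$source$position[2],
              x$source$length * 1e3, nrow(x$receivers)))
  invisible(x)
}

#' Build a free-field scene for measuring the transmitted beam
#'
#' A target-free seawater domain with the calibrated aperture source and a
#' receiver arc centered on the source, used to measure the far-field
#' 3-dB beamwidth of the emitted click. Angle 0 points along the beam
#' axis (+x).
#'
#' @param arc_radius Arc radius in meters; the default 1.0 m is at the
#'   far-field transition `2 L^2 / lambda` of the calibrated aperture.
#' @param arc_half_span,arc_step Half span and step of the arc (degrees).
#' @param dx Grid spacing (m).
#' @param aperture_beamwidth Calibration target (degrees).
#' @param point_source Use a point source instead (for omnidirectionality
#'   checks).
#' @param f0,amplitude Pulse parameters.
#' @return A `scene` with an `arc` whose angles are measured off the beam
#'   axis.
#' @export
build_beam_scene <- function(arc_radius = 1.0, arc_half_span = 30,
                             arc_step = 0.25, dx = 1.5e-3,
                             aperture_beamwidth = 11.1,
                             point_source = FALSE,
                             f0 = 60e3, amplitude = 1) {
  c_w <- material("seawater")$sound_speed
  margin <- 0.11
  src_x <- 0.15
  Lx <- src_x + arc_radius + margin
  Lz <- 2 * (arc_radius * sin(arc_half_span * pi / 180) + margin)
  nx <- round(Lx / dx) + 1
  nz <- round(Lz / dx) + 1
  m <- medium_map(nx, nz, dx)
  check_mesh_rule(m, f0)
  snap_idx <- function(p) c(round(p[1] / dx) + 1, round(p[2] / dx) + 1)
  source_pos <- (snap_idx(c(src_x, Lz / 2)) - 1) * dx
  if (point_source) {
    ap_len <- 0
  } else {
    ap_len <- calibrate_aperture(aperture_beamwidth, f0, c_w)$length
  }
  sidx <- snap_idx(source_pos)
  n_half <- if (ap_len > 0) floor((ap_len / 2) / dx) else 0L
  jj <- (sidx[2] - n_half):(sidx[2] + n_half)
  elements <- data.frame(i = rep(sidx[1], length(jj)), j = jj,
                         w = rep(1 / length(jj), length(jj)))
  angles <- seq(-arc_half_span, arc_half_span, by = arc_step)
  px <- source_pos[1] + arc_radius * cos(angles * pi / 180)
  pz <- source_pos[2] + arc_radius * sin(angles * pi / 180)
  rec_df <- do.call(rbind, lapply(seq_along(angles), function(k) {
    ij <- snap_idx(c(px[k], pz[k]))
    data.frame(name = sprintf("arc_%04d", k),
               x = (ij[1] - 1) * dx, z = (ij[2] - 1) * dx,
               i = ij[1], j = ij[2], stringsAsFactors = FALSE)
  }))
  duration <- arc_radius / c_w + 2.5e-4
  structure(list(medium = m, dx = dx, f0 = f0, amplitude = amplitude,
                 case_kind = "none", preset = "beam",
                 domain = c(Lx, Lz),
                 source = list(position = source_pos, length = ap_len,
                               orientation = c(1, 0), elements = elements),
                 receivers = rec_df,
                 arc = list(center = source_pos, radius = arc_radius,
                            angles = angles, names = rec_df$name),
                 target = NULL, target_distance = NA_real_,
                 duration = duration),
            class = "scene")
}
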