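#' Target geometry for the four material cases
#'
#' Builds the 2D cross-section geometry of one test object. All four cases
#' share the same 48 mm outer width and overall shape; they differ only in
#' material composition:
#' \describe{
#'   \item{AF}{air-filled PVC pipe: 48 mm outer width, 3 mm PVC wall,
#'     sealed air interior.}
#'   \item{WF}{water-filled PVC pipe: identical PVC shell, seawater
#'     interior.}
#'   \item{FB}{foam-ball array: a vertical column of 48 mm foam-ball disks
#'     (the mono-filament line is ignored).}
#'   \item{SF}{closed-cell-foam-wrapped pipe: a 16 mm outer-diameter PVC
#'     pipe (2 mm wall, air interior) centered in a 48 mm closed-cell foam
#'     wrap.}
#' }
#' The vertical pipe is modeled in cross-section through its axis as a
#' rectangular section of outer width 48 mm and length `section_length`,
#' with walls on all sides; the incident click crosses the front/back
#' walls.
#'
#' @param case_kind One of `"AF"`, `"WF"`, `"FB"`, `"SF"`.
#' @param center Length-2 numeric, target center (x, z) in meters.
#' @param section_length Vertical extent of the pipe section in meters.
#' @param ball_count,ball_spacing FB only: number of foam-ball disks and
#'   center-to-center spacing (m).
#' @return An object of class `target_geometry`.
#' @export
#' @examples
#' target_geometry("AF", center = c(1.25, 0.5))
target_geometry <- function(case_kind = c("AF", "WF", "FB", "SF"),
                            center = c(1.25, 0.5),
                            section_length = 0.300,
                            ball_count = 6L, ball_spacing = 0.050) {
  case_kind <- match.arg(case_kind)
  g <- list(case_kind = case_kind, center = center,
            section_length = section_length)
  if (case_kind %in% c("AF", "WF")) {
    g$pipe_outer_diameter <- 0.048
    g$pipe_wall_thickness <- 0.003
  } else if (case_kind == "SF") {
    g$pipe_outer_diameter <- 0.016
    g$pipe_wall_thickness <- 0.002
    g$foam_wrap_outer_diameter <- 0.048
  } else { # FB
    g$ball_diameter <- 0.048
    g$ball_count <- as.integer(ball_count)
    g$ball_spacing <- ball_spacing
  }
  validate_geometry(g)
  structure(g, class = "target_geometry")
}

validate_geometry <- function(g) {
  if (!is.null(g$pipe_outer_diameter)) {
    stopifnot(g$pipe_wall_thickness < g$pipe_outer_diameter / 2)
  }
  if (g$case_kind == "SF") {
    stopifnot(g$pipe_outer_diameter < g$foam_wrap_outer_diameter)
  }
  if (g$case_kind == "FB") {
    stopifnot(g$ball_count >= 1L, g$ball_spacing >= g$ball_diameter)
  }
  invisible(g)
}

# thinnest material feature that must survive rasterization (m)
min_feature <- function(g) {
  switch(g$case_kind,
         AF = , WF = g$pipe_wall_thickness,
         SF = g$pipe_wall_thickness,
         FB = g$ball_diameter / 2)
}

# Material-name raster for cell-center coordinate matrices X, Z.
# Cells outside every target region keep the background name.
rasterize_case <- function(X, Z, g, background = "seawater") {
  mat <- matrix(background, nrow(X), ncol(X))
  cx <- g$center[1]; cz <- g$center[2]
  # nanometer tie tolerance: cell centers that sit exactly on a region
  # boundary must resolve identically on both sides of a symmetric
  # target, which bare floating-point comparison does not guarantee
  eps <- 1e-9
  inrect <- function(hw, hl) {
    abs(X - cx) <= hw + eps & abs(Z - cz) <= hl + eps
  }
  if (g$case_kind %in% c("AF", "WF")) {
    hw <- g$pipe_outer_diameter / 2
    hl <- g$section_length / 2
    w <- g$pipe_wall_thickness
    mat[inrect(hw, hl)] <- "PVC"
    mat[inrect(hw - w, hl - w)] <- if (g$case_kind == "AF") "air" else "seawater"
  } else if (g$case_kind == "SF") {
    hw_foam <- g$foam_wrap_outer_diameter / 2
    hl_foam <- g$section_length / 2
    wrap <- (g$foam_wrap_outer_diameter - g$pipe_outer_diameter) / 2
    hw_pvc <- g$pipe_outer_diameter / 2
    hl_pvc <- hl_foam - wrap
    w <- g$pipe_wall_thickness
    mat[inrect(hw_foam, hl_foam)] <- "closed-cell-foam"
    mat[inrect(hw_pvc, hl_pvc)] <- "PVC"
    mat[inrect(hw_pvc - w, hl_pvc - w)] <- "air"
  } else { # FB: vertical column of disks
    r <- g$ball_diameter / 2
    zc <- cz + (seq_len(g$ball_count) - (g$ball_count + 1) / 2) * g$ball_spacing
    for (z0 in zc) {
      mat[(X - cx)^2 + (Z - z0)^2 <= r^2 + 1e-9] <- "foam-ball"
    }
  }
  mat
}

# vertical footprint of the target (m), for domain checks
target_extent_z <- function(g) {
  if (g$case_kind == "FB") {
    (g$ball_count - 1) * g$ball_spacing + g$ball_diameter
  } else {
    g$section_length
  }
}

#' Rasterize a target geometry onto a grid patch
#'
#' Builds a stand-alone `medium_map` patch covering the target with a small
#' seawater margin, assigning each cell the material whose region contains
#' the cell center. The patch grid is aligned to the global lattice
#' (multiples of `dx`), so it drops losslessly into a scene map built with
#' the same spacing.
#'
#' @param geom A [target_geometry()].
#' @param dx Grid spacing in meters. Must resolve the thinnest material
#'   feature of the case (for the 3 mm PVC pipe wall this requires
#'   `dx <= 1.5e-3`).
#' @param margin Seawater margin around the target (m).
#' @return A `medium_map` patch, with the material-name raster attached as
#'   attribute `"materials"`.
#' @export
#' @examples
#' p <- build_target_map(target_geometry("AF"), dx = 1e-3)
#' table(attr(p, "materials"))
build_target_map <- function(geom, dx, margin = 0.01) {
  stopifnot(inherits(geom, "target_geometry"), dx > 0)
  feat <- min_feature(geom)
  # two cells across the 3 mm main-pipe wall; the SF inner wall (2 mm) is
  # accepted down to one cell so the desk grid (1.5 mm) remains usable
  limit <- if (geom$case_kind %in% c("AF", "WF")) feat / 2 else feat
  if (dx > limit + 1e-12) {
    stop(sprintf("dx = %g m too coarse for the %s case (thinnest feature %g m; need dx <= %g m)",
                 dx, geom$case_kind, feat, limit))
  }
  hx <- if (geom$case_kind == "FB") geom$ball_diameter / 2 else
    if (geom$case_kind == "SF") geom$foam_wrap_outer_diameter / 2 else
      geom$pipe_outer_diameter / 2
  hz <- target_extent_z(geom) / 2
  i0 <- floor((geom$center[1] - hx - margin) / dx)
  i1 <- ceiling((geom$center[1] + hx + margin) / dx)
  j0 <- floor((geom$center[2] - hz - margin) / dx)
  j1 <- ceiling((geom$center[2] + hz + margin) / dx)
  m <- medium_map(i1 - i0 + 1, j1 - j0 + 1, dx, origin = c(i0, j0) * dx)
  X <- matrix(map_x(m), m$nx, m$nz)
  Z <- matrix(map_z(m), m$nx, m$nz, byrow = TRUE)
  names_mat <- rasterize_case(X, Z, geom)
  tab <- material_table()
  idx <- match(names_mat, tab$name)
  m$sound_speed <- matrix(tab$sound_speed[idx], m$nx, m$nz)
  m$density <- matrix(tab$density[idx], m$nx, m$nz)
  attr(m, "materials") <- names_mat
  m
}

#' Merge a target patch into a larger medium map
#'
#' @param m Parent `medium_map`.
#' @param patch Patch from [build_target_map()], built with the same `dx`
#'   on the aligned lattice.
#' @return The parent map with the patch cells overwritten.
#' @export
apply_patch <- function(m, patch) {
  stopifnot(abs(m$dx - patch$dx) < 1e-12)
  di <- (patch$origin[1] - m$origin[1]) / m$dx
  dj <- (patch$origin[2] - m$origin[2]) / m$dx
  if (max(abs(di - round(di)), abs(dj - round(dj))) > 1e-6) {
    stop("patch lattice is not aligned with the parent map")
  }
  di <- round(di); dj <- round(dj)
  if (di < 0 || dj < 0 || di + patch$nx > m$nx || dj + patch$nz > m$nz) {
    stop("patch exceeds the parent map bounds")
  }
  ii <- di + seq_len(patch$nx); jj <- dj + seq_len(patch$nz)
  m$sound_speed[ii, jj] <- patch$sound_speed
  m$density[ii, jj] <- patch$density
  m
}
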