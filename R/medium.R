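#' Create a uniform 2D medium map
#'
#' A `medium_map` is the gridded description of the simulated scene: two
#' matching matrices of sound speed (m/s) and density (kg/m^3) on a uniform
#' cell-centered Cartesian grid. Indexing is `[i, j]` with `i` along x
#' (toward the target) and `j` along z (vertical); the center of cell
#' `[1, 1]` sits at `origin`.
#'
#' @param nx,nz Grid dimensions (cells).
#' @param dx Isotropic grid spacing in meters.
#' @param origin Length-2 numeric, coordinates of the first cell center.
#' @param fill Background material name (default seawater).
#' @return An object of class `medium_map` with fields `nx`, `nz`, `dx`,
#'   `origin`, `sound_speed` and `density`.
#' @export
medium_map <- function(nx, nz, dx, origin = c(0, 0), fill = "seawater") {
  stopifnot(nx >= 1, nz >= 1, dx > 0, length(origin) == 2)
  m <- material(fill)
  structure(list(
    nx = as.integer(nx), nz = as.integer(nz), dx = dx, origin = origin,
    sound_speed = matrix(m$sound_speed, nx, nz),
    density = matrix(m$density, nx, nz)
  ), class = "medium_map")
}

#' @export
print.medium_map <- function(x, ...) {
  cat(sprintf("medium_map: %d x %d cells, dx = %g mm, extent %.3f x %.3f m\n",
              x$nx, x$nz, x$dx * 1e3,
              (x$nx - 1) * x$dx, (x$nz - 1) * x$dx))
  cat(sprintf("  sound speed: %.0f..%.0f m/s; density: %.3g..%.3g kg/m^3\n",
              min(x$sound_speed), max(x$sound_speed),
              min(x$density), max(x$density)))
  invisible(x)
}

#' Cell-center coordinates of a medium map
#'
#' @param m A `medium_map`.
#' @return Numeric vector of x (resp. z) cell-center coordinates in meters.
#' @export
map_x <- function(m) m$origin[1] + (seq_len(m$nx) - 1) * m$dx

#' @rdname map_x
#' @export
map_z <- function(m) m$origin[2] + (seq_len(m$nz) - 1) * m$dx

# validity used by the solver
check_medium <- function(m) {
  stopifnot(inherits(m, "medium_map"),
            all(dim(m$sound_speed) == c(m$nx, m$nz)),
            all(dim(m$density) == c(m$nx, m$nz)),
            all(m$sound_speed > 0), all(m$density > 0))
  invisible(m)
}

#' Check the mesh-resolution rule for a medium map
#'
#' The grid must resolve the peak-frequency wavelength in the background
#' water with at least ten cells (`dx <= lambda_p / 10`).
#'
#' @param m A `medium_map`.
#' @param f_peak Peak frequency of the excitation in Hz.
#' @return `TRUE` invisibly; errors if the rule is violated.
#' @export
check_mesh_rule <- function(m, f_peak = 60e3) {
  lam <- wavelength(material("seawater")$sound_speed, f_peak)
  if (m$dx > lam / 10 + 1e-12) {
    stop(sprintf("dx = %g m violates the ten-cells-per-wavelength rule (need <= %g m)",
                 m$dx, lam / 10))
  }
  invisible(TRUE)
}

#' Write / read a medium map as a self-describing plain-text container
#'
#' The format is a small header (`nx`, `nz`, `dx`, `origin`) followed by the
#' two grids in column order, suitable for small test grids and external
#' inspection.
#'
#' @param m A `medium_map`.
#' @param path Output file path.
#' @return `write_medium_map` returns `path` invisibly; `read_medium_map`
#'   returns the reconstructed `medium_map`.
#' @export
write_medium_map <- function(m, path) {
  check_medium(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# biosonarsim medium_map v1",
               sprintf("nx %d", m$nx), sprintf("nz %d", m$nz),
               sprintf("dx %.17g", m$dx),
               sprintf("origin %.17g %.17g", m$origin[1], m$origin[2]),
               "sound_speed"), con)
  write(format(m$sound_speed, digits = 17), con, ncolumns = 8)
  writeLines("density", con)
  write(format(m$density, digits = 17), con, ncolumns = 8)
  invisible(path)
}

#' @rdname write_medium_map
#' @export
read_medium_map <- function(path) {
  lines <- readLines(path)
  get1 <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)[1]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][-1])
  }
  nx <- as.integer(get1("nx")); nz <- as.integer(get1("nz"))
  dx <- get1("dx"); origin <- get1("origin")
  i_c <- which(lines == "sound_speed"); i_r <- which(lines == "density")
  vals_c <- as.numeric(unlist(strsplit(trimws(lines[(i_c + 1):(i_r - 1)]), "\\s+")))
  vals_r <- as.numeric(unlist(strsplit(trimws(lines[(i_r + 1):length(lines)]), "\\s+")))
  m <- medium_map(nx, nz, dx, origin)
  m$sound_speed <- matrix(vals_c[seq_len(nx * nz)], nx, nz)
  m$density <- matrix(vals_r[seq_len(nx * nz)], nx, nz)
  check_medium(m)
}
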