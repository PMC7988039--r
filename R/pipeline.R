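#' Default run configuration
#'
#' Flat key-value configuration for a full case run; can be stored in and
#' read back from a YAML file.
#'
#' @return A named list of configuration values.
#' @export
default_config <- function() {
  list(
    preset = "desk",
    dx = NA,                 # derived from preset unless set
    target_distance = 1.1,
    aperture_beamwidth = 11.1,
    f0 = 60e3,
    amplitude = 1,
    click_pp_level = 220,    # dB re 1 uPa pp at the 0.5 m on-axis point
    absorbing_cells = 40,
    courant_safety = 0.8,
    arc_radius = 0.5,
    arc_half_span = 60,
    arc_step = 0.25,
    guard = 60e-6,
    band_lo = 10e3,
    band_hi = 200e3,
    seed = 1
  )
}

#' Read / write a run configuration
#'
#' @param path YAML file path.
#' @param config Configuration list.
#' @return `read_config` returns the validated configuration list.
#' @export
read_config <- function(path) {
  cfg <- utils::modifyList(default_config(), yaml::read_yaml(path))
  validate_config(cfg)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

validate_config <- function(cfg) {
  stopifnot(cfg$target_distance > 0, cfg$f0 > 0,
            cfg$aperture_beamwidth > 0, cfg$aperture_beamwidth < 180,
            cfg$courant_safety > 0, cfg$courant_safety <= 0.85,
            cfg$arc_radius > 0, cfg$arc_step > 0)
  cfg
}

#' Run one material case end to end
#'
#' Builds the scene for the case, drives the calibrated aperture with the
#' source click, runs the wave solver, normalizes levels so the outgoing
#' click has the configured peak-to-peak level at the 0.5 m on-axis
#' point, and computes the echo characterization: the metric bundle of
#' the echo at the lower-jaw proxy receiver, the echo-to-click level
#' ratio at the calibration point, and the echo beam pattern on the
#' 0.5 m circle around the target with its 3-dB beamwidth.
#'
#' @param case_kind `"AF"`, `"WF"`, `"FB"` or `"SF"`.
#' @param config Configuration list (see [default_config()]).
#' @param output_dir Optional directory; when given, traces (CSV), the
#'   metrics record (JSON), the beam pattern (CSV) and a run manifest
#'   (JSON) are written there.
#' @param keep_result Keep the full `sim_result` in the returned object
#'   (memory-heavy for large grids).
#' @return An object of class `case_run`: list with `case_kind`,
#'   `metrics` (one-row data frame), `beam` (`beam_pattern`), `config`,
#'   `dt`, `manifest` (when `output_dir` is given), and optionally
#'   `result`.
#' @export
run_case <- function(case_kind, config = default_config(),
                     output_dir = NULL, keep_result = FALSE) {
  config <- validate_config(utils::modifyList(default_config(), config))
  if (config$amplitude == 0) {
    stop("all-zero trace: source amplitude is zero")
  }
  t_start <- Sys.time()
  dx <- if (is.na(config$dx)) NULL else config$dx
  scene <- build_scene(case_kind, preset = config$preset, dx = dx,
                       target_distance = config$target_distance,
                       aperture_beamwidth = config$aperture_beamwidth,
                       arc = "target", arc_radius = config$arc_radius,
                       arc_half_span = config$arc_half_span,
                       arc_step = config$arc_step,
                       f0 = config$f0, amplitude = config$amplitude)
  solver <- solver_config(courant_safety = config$courant_safety,
                          absorbing_cells = config$absorbing_cells)
  res <- run_simulation(scene, solver = solver)
  res <- normalize_click_level(res, level = config$click_pp_level)
  metrics <- case_metrics(res, config)
  beam <- echo_beam(res)
  out <- structure(list(case_kind = case_kind, metrics = metrics,
                        beam = beam, config = config, dt = res$dt,
                        dx = scene$dx,
                        wall_time_s = as.numeric(difftime(Sys.time(), t_start,
                                                          units = "secs"))),
                   class = "case_run")
  if (keep_result) out$result <- res
  if (!is.null(output_dir)) {
    out$manifest <- write_case_outputs(out, res, output_dir)
  }
  out
}

# scale all pressures so the outgoing click at the 0.5 m on-axis point has
# the requested peak-to-peak level (dB re 1 uPa); the simulation is linear
# so this is a pure unit calibration
normalize_click_level <- function(result, level = 220) {
  cal <- get_trace(result, "cal")
  sp <- split_click_echo(cal,
                         target_distance = result$scene$target_distance,
                         cal_offset = 0.5)
  pp <- max(sp$click) - min(sp$click)
  if (pp == 0) stop("all-zero trace at the calibration point")
  k <- 10^(level / 20) / pp
  result$traces <- result$traces * k
  result$snapshots <- lapply(result$snapshots, function(s) s * k)
  result$level_scale <- k
  result
}

# metric bundle for one finished case run
case_metrics <- function(res, config = default_config()) {
  band <- c(config$band_lo, config$band_hi)
  c_w <- material("seawater")$sound_speed
  d <- res$scene$target_distance

  cal <- get_trace(res, "cal")
  sp <- split_click_echo(cal, target_distance = d, cal_offset = 0.5,
                         c_water = c_w, guard = config$guard)
  ratio <- echo_click_ratio(sp$echo, sp$click)

  jaw <- get_trace(res, "jaw")
  jaw_target <- sqrt(sum((jaw$position -
                            c(res$scene$source$position[1] + d,
                              res$scene$source$position[2]))^2))
  t_echo <- (d + jaw_target) / c_w - 80e-6
  echo <- jaw$pressure[jaw$time >= t_echo]
  m <- echo_metrics(echo, res$dt, band = band)
  m$echo_click_ratio_db <- ratio
  m$energy_in_264us_window_db <- energy_in_window(echo, res$dt)
  hl <- detect_highlights(echo, res$dt)
  m$n_highlights <- length(hl)
  m$highlight_separation_us <- if (length(hl) >= 2) {
    (hl[2] - hl[1]) * 1e6
  } else NA_real_
  m$first_highlight_time_us <- if (length(hl) >= 1) {
    (t_echo + hl[1]) * 1e6
  } else NA_real_
  cbind(data.frame(case_kind = res$scene$case_kind,
                   stringsAsFactors = FALSE), m)
}

# echo beam pattern on the target-centered circle, gated to the transit
# of the returning echo through the arc
echo_beam <- function(res) {
  c_w <- material("seawater")$sound_speed
  d <- res$scene$target_distance
  r <- res$scene$arc$radius
  t0 <- (d - r) / c_w           # echo reaches the near arc point
  t1 <- (d + 2 * r) / c_w + 4e-4
  bp <- beam_pattern_from_arc(res, time_window = c(t0, t1))
  bp
}

write_case_outputs <- function(run, res, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(output_dir, run$case_kind)
  files <- character(0)
  # named (non-arc) receiver traces
  named <- setdiff(res$receivers$name, res$scene$arc$names)
  tr <- data.frame(time_s = res$time)
  for (nm in named) tr[[paste0(nm, "_upa")]] <- get_trace(res, nm)$pressure
  f <- paste0(base, "_traces.csv"); utils::write.csv(tr, f, row.names = FALSE)
  files <- c(files, f)
  f <- paste0(base, "_beam.csv")
  utils::write.csv(data.frame(angle_deg = run$beam$angles,
                              spl_db = run$beam$spl), f, row.names = FALSE)
  files <- c(files, f)
  f <- paste0(base, "_metrics.json")
  jsonlite::write_json(as.list(run$metrics), f, auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, f)
  manifest <- list(case_kind = run$case_kind, config = run$config,
                   dx = run$dx, dt = run$dt,
                   version = as.character(utils::packageVersion("biosonarsim")),
                   files = basename(files),
                   wall_time_s = run$wall_time_s)
  f <- paste0(base, "_manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA)
  stopifnot(all(file.exists(files)), all(file.size(files) > 0))
  manifest
}

#' Compare finished case runs
#'
#' Builds the four-case metric table, pairwise echo-level differences,
#' and pass/fail flags for the expected case ordering: the air-filled and
#' foam-wrapped pipes return comparably strong echoes, the foam-ball
#' array an intermediate one, and the water-filled pipe the weakest (at
#' least 10 dB below the air-filled case).
#'
#' @param runs List of `case_run` objects (>= 2) sharing grid and source
#'   settings.
#' @return List with `table` (metric rows), `level_differences` (pairwise
#'   echo-to-click ratio differences, dB) and `ordering` (named logical
#'   flags).
#' @export
compare_cases <- function(runs) {
  if (length(runs) < 2) stop("need at least two case runs to compare")
  dxs <- vapply(runs, function(r) r$dx, numeric(1))
  if (max(dxs) - min(dxs) > 1e-12) stop("incompatible grids across runs")
  tab <- do.call(rbind, lapply(runs, function(r) r$metrics))
  rownames(tab) <- NULL
  ratio <- stats::setNames(tab$echo_click_ratio_db, tab$case_kind)
  diffs <- outer(ratio, ratio, "-")
  ordering <- list()
  have <- function(...) all(c(...) %in% names(ratio))
  if (have("AF", "WF")) {
    ordering$wf_at_least_10db_below_af <- ratio["WF"] <= ratio["AF"] - 10
  }
  if (have("AF", "SF")) {
    ordering$af_sf_within_3db <- abs(ratio["AF"] - ratio["SF"]) <= 3
  }
  efd <- stats::setNames(tab$energy_flux_density_db, tab$case_kind)
  if (have("AF", "WF", "FB", "SF")) {
    ordering$efd_ordering_af_sf_fb_wf <-
      (abs(efd["AF"] - efd["SF"]) <= 6) &&
      (min(efd["AF"], efd["SF"]) > efd["FB"]) && (efd["FB"] > efd["WF"])
  }
  list(table = tab, level_differences = diffs,
       ordering = lapply(ordering, unname))
}
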