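test_that("the CFL bound evaluates as specified", {
  m <- medium_map(10, 10, 1.5e-3)
  m$sound_speed[5, 5] <- 2218
  expect_equal(max_stable_dt(m, 1.0), 1.5e-3 / (2218 * sqrt(2)),
               tolerance = 1e-12)
  expect_equal(max_stable_dt(m, 1.0), 4.782057e-7, tolerance = 1e-6)
  mw <- medium_map(10, 10, 1e-3)
  expect_equal(max_stable_dt(mw, 0.9), 0.9 * 1e-3 / (1527 * sqrt(2)),
               tolerance = 1e-12)
  expect_equal(max_stable_dt(mw, 0.9), 4.167623e-7, tolerance = 1e-6)
  # doubling dx doubles the bound
  m2 <- medium_map(10, 10, 3e-3)
  m2$sound_speed[5, 5] <- 2218
  expect_equal(max_stable_dt(m2, 1.0), 2 * max_stable_dt(m, 1.0))
})

test_that("solver configuration enforces its stability limits", {
  expect_error(solver_config(courant_safety = 0.9), "0.85")
  expect_error(solver_config(absorbing_cells = 10), ">= 20")
  expect_silent(solver_config(courant_safety = 0.8, absorbing_cells = 0))
})

test_that("a zero-amplitude pulse yields identically zero output", {
  m <- medium_map(101, 101, 1.5e-3)
  sc <- custom_scene(m, c(0.075, 0.075), list(p = c(0.11, 0.075)),
                     duration = 1e-4, amplitude = 0)
  res <- run_simulation(sc)
  expect_true(all(res$traces == 0))
})

test_that("runs at an over-CFL time step are refused", {
  m <- medium_map(101, 101, 1.5e-3)
  sc <- custom_scene(m, c(0.075, 0.075), list(p = c(0.11, 0.075)),
                     duration = 1e-4)
  expect_error(run_simulation(sc, dt = 1e-6), "CFL")
  expect_error(custom_scene(m, c(0.075, 0.075), list(p = c(0.5, 0.075)),
                            duration = 1e-4))
})

test_that("point-source amplitudes follow 2D cylindrical spreading", {
  ratio <- spreading_cached()
  expect_equal(ratio, sqrt(2), tolerance = 0.03)
})

test_that("half-space reflections match the Fresnel coefficients", {
  fr <- fresnel_cached()
  for (nm in names(fr)) {
    expect_equal(abs(fr[[nm]]$measured), abs(fr[[nm]]$analytic),
                 tolerance = 0.03, label = nm)
    expect_equal(sign(fr[[nm]]$measured), sign(fr[[nm]]$analytic),
                 label = paste(nm, "sign"))
  }
})

test_that("the absorbing boundary absorbs and thickness helps", {
  b <- boundary_cached()
  expect_lte(b$r40, -40)          # default layer quality
  expect_lte(b$r30, b$r0 - 30)    # a 30-cell layer is far from rigid
  expect_lte(b$r50, b$r40 + 0.5)  # thicker never (materially) worse
  expect_gt(b$r0, -3)             # rigid walls reflect essentially fully
})

test_that("rigid-wall energy drifts less than 1% after the source closes", {
  m <- medium_map(151, 151, 2e-3)
  sc <- custom_scene(m, c(0.15, 0.15), list(p = c(0.2, 0.15)),
                     duration = 1.6e-3)
  # raw (unshaped) drive: the injection closes with the pulse window
  res <- run_simulation(sc, solver = solver_config(absorbing_cells = 0,
                                                   energy_stride = 10),
                        shape_source = FALSE)
  e <- res$energy[res$energy_times > 1e-4]  # source window closed
  e <- e[seq_len(min(length(e), 200))]      # 2,000 steps
  expect_lt(max(abs(e - e[1])) / e[1], 0.01)
})

test_that("pressure traces are reciprocal under source-receiver swap", {
  dx <- 1.5e-3
  m <- medium_map(201, 201, dx)
  # an off-axis PVC block between the two points
  sel_i <- map_x(m) > 0.14 & map_x(m) < 0.17
  sel_j <- map_z(m) > 0.10 & map_z(m) < 0.20
  m$sound_speed[sel_i, sel_j] <- 2218
  m$density[sel_i, sel_j] <- 1350
  a <- c(0.08, 0.15); b <- c(0.22, 0.18)
  r1 <- run_simulation(custom_scene(m, a, list(p = b), duration = 2.5e-4))
  r2 <- run_simulation(custom_scene(m, b, list(p = a), duration = 2.5e-4))
  t1 <- get_trace(r1, "p")$pressure
  t2 <- get_trace(r2, "p")$pressure
  expect_lt(sqrt(mean((t1 - t2)^2)) / sqrt(mean(t1^2)), 0.01)
})

test_that("a mirror-symmetric scene produces a mirror-symmetric field", {
  dx <- 1.5e-3
  m <- medium_map(267, 201, dx)  # nz odd: z = 0.15 is an exact cell center
  g <- target_geometry("AF", center = c(0.25, 0.15),
                       section_length = 0.12)
  patch <- build_target_map(g, dx = dx)
  m <- apply_patch(m, patch)
  recs <- list(up = c(0.1, 0.15 + 0.045), dn = c(0.1, 0.15 - 0.045))
  sc <- custom_scene(m, c(0.05, 0.15), recs, duration = 4e-4)
  res <- run_simulation(sc)
  up <- get_trace(res, "up")$pressure
  dn <- get_trace(res, "dn")$pressure
  expect_lt(sqrt(mean((up - dn)^2)) / sqrt(mean(up^2)), 1e-3)
})

test_that("simulation output is deterministic", {
  m <- medium_map(101, 101, 1.5e-3)
  sc <- custom_scene(m, c(0.075, 0.075), list(p = c(0.11, 0.08)),
                     duration = 1.2e-4)
  r1 <- run_simulation(sc)
  r2 <- run_simulation(sc)
  expect_identical(r1$traces, r2$traces)
})
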