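test_that("the AF patch has three materials with air sealed inside PVC", {
  p <- build_target_map(target_geometry("AF"), dx = 1e-3)
  mats <- attr(p, "materials")
  expect_setequal(unique(as.vector(mats)), c("seawater", "PVC", "air"))
  # every air cell's 4-neighborhood is air or PVC: the air is sealed
  air <- which(mats == "air", arr.ind = TRUE)
  for (k in seq_len(nrow(air))) {
    i <- air[k, 1]; j <- air[k, 2]
    nb <- c(mats[i - 1, j], mats[i + 1, j], mats[i, j - 1], mats[i, j + 1])
    expect_true(all(nb %in% c("air", "PVC")))
  }
})

test_that("AF and WF share the PVC shell and differ only in the fill", {
  paf <- build_target_map(target_geometry("AF"), dx = 1e-3)
  pwf <- build_target_map(target_geometry("WF"), dx = 1e-3)
  maf <- attr(paf, "materials"); mwf <- attr(pwf, "materials")
  expect_identical(maf == "PVC", mwf == "PVC")
  expect_identical(maf == "seawater" | maf == "air",
                   mwf == "seawater")
  # scene-level: sound-speed grids differ only strictly inside the pipe
  saf <- build_scene("AF", arc = "none")
  swf <- build_scene("WF", arc = "none")
  diff_cells <- which(saf$medium$sound_speed != swf$medium$sound_speed,
                      arr.ind = TRUE)
  x <- map_x(saf$medium)[diff_cells[, 1]]
  z <- map_z(saf$medium)[diff_cells[, 2]]
  g <- saf$target
  hw <- g$pipe_outer_diameter / 2 - g$pipe_wall_thickness
  hl <- g$section_length / 2 - g$pipe_wall_thickness
  expect_true(all(abs(x - g$center[1]) <= hw + 1e-12))
  expect_true(all(abs(z - g$center[2]) <= hl + 1e-12))
})

test_that("the SF section is foam-wrapped PVC with an air core", {
  p <- build_target_map(target_geometry("SF"), dx = 0.5e-3)
  mats <- attr(p, "materials")
  expect_setequal(unique(as.vector(mats)),
                  c("seawater", "closed-cell-foam", "PVC", "air"))
  # along the horizontal midline: water, foam, PVC, air, PVC, foam, water
  mid <- mats[, ceiling(ncol(mats) / 2)]
  runs <- rle(mid)$values
  expect_identical(runs, c("seawater", "closed-cell-foam", "PVC", "air",
                           "PVC", "closed-cell-foam", "seawater"))
})

test_that("rasterized disk area converges to the analytic area", {
  g <- target_geometry("FB", ball_count = 1L)
  for (dx in c(1e-3, 0.5e-3)) {
    p <- build_target_map(g, dx = dx)
    n_foam <- sum(attr(p, "materials") == "foam-ball")
    area <- n_foam * dx^2
    analytic <- pi * (g$ball_diameter / 2)^2
    tol <- if (dx <= 0.5e-3) 0.02 else 0.05
    expect_lt(abs(area - analytic) / analytic, tol)
  }
})

test_that("the FB column contains the configured number of disks", {
  g <- target_geometry("FB")
  expect_equal(g$ball_count, 6L)
  p <- build_target_map(g, dx = 1e-3)
  mats <- attr(p, "materials")
  # vertical profile through the column center alternates water/foam 6 times
  mid <- mats[ceiling(nrow(mats) / 2), ]
  runs <- rle(mid == "foam-ball")
  expect_equal(sum(runs$values), 6)
})

test_that("rasterization rejects grids too coarse for the pipe wall", {
  expect_error(build_target_map(target_geometry("AF"), dx = 5e-3),
               "too coarse")
  expect_error(build_scene("AF", dx = 2.5e-3, preset = "desk"),
               "ten-cells-per-wavelength|too coarse")
  expect_silent(build_target_map(target_geometry("AF"), dx = 1.5e-3))
})

test_that("geometry invariants are enforced", {
  expect_error(target_geometry("FB", ball_spacing = 0.01))
  g <- target_geometry("AF")
  expect_lt(g$pipe_wall_thickness, g$pipe_outer_diameter / 2)
  gsf <- target_geometry("SF")
  expect_lt(gsf$pipe_outer_diameter, gsf$foam_wrap_outer_diameter)
})

test_that("patches drop into a parent map and misalignment errors", {
  m <- medium_map(400, 400, 1e-3)
  p <- build_target_map(target_geometry("AF", center = c(0.2, 0.2)),
                        dx = 1e-3)
  merged <- apply_patch(m, p)
  expect_equal(sum(merged$sound_speed == 2218),
               sum(p$sound_speed == 2218))
  p_bad <- p; p_bad$origin <- p$origin + 0.3e-3
  expect_error(apply_patch(m, p_bad), "not aligned")
  p_out <- build_target_map(target_geometry("AF", center = c(0.9, 0.2)),
                            dx = 1e-3)
  expect_error(apply_patch(m, p_out), "bounds")
})

test_that("scenes place the target 1.1 m from the source", {
  sc <- build_scene("AF", arc = "none")
  d <- sqrt(sum((sc$target$center - sc$source$position)^2))
  expect_equal(d, 1.1, tolerance = 1e-9)
  expect_true(all(c("jaw", "cal") %in% sc$receivers$name))
  cal <- sc$receivers[sc$receivers$name == "cal", ]
  expect_equal(cal$x - sc$source$position[1], 0.5, tolerance = 1.6e-3)
  # duration covers the round trip plus the longest expected echo
  expect_gte(sc$duration, 2 * 1.1 / 1527 + 5e-4)
  # empty scene: uniform seawater
  sc0 <- build_scene("none", arc = "none")
  expect_equal(unique(as.vector(sc0$medium$sound_speed)), 1527)
  expect_error(build_scene("XX"))
})

test_that("medium maps round-trip through the text container", {
  m <- medium_map(7, 5, 1.5e-3, origin = c(0.01, 0.02))
  m$sound_speed[3, 2] <- 2218
  m$density[3, 2] <- 1350
  f <- withr::local_tempfile(fileext = ".txt")
  write_medium_map(m, f)
  m2 <- read_medium_map(f)
  expect_equal(m2$sound_speed, m$sound_speed)
  expect_equal(m2$density, m$density)
  expect_equal(m2$dx, m$dx)
  expect_equal(m2$origin, m$origin)
})
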