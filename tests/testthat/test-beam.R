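# small free-field run with snapshots, shared by the snapshot-path tests
isotropic_snapshots <- function() {
  cached("iso_snap", {
    # a 20 kHz pulse (~50 cells per wavelength): the solver's residual
    # (k dx)^2 amplitude anisotropy is then well below the flatness
    # tolerance, so the test isolates the operation itself
    dx <- 1.5e-3
    m <- medium_map(241, 241, dx)
    sc <- custom_scene(m, c(0.18, 0.18), list(p = c(0.28, 0.18)),
                       duration = 2.6e-4, f0 = 20e3)
    run_simulation(sc, solver = solver_config(
      snapshot_stride = 2L, snapshot_window = c(5e-5, 2.5e-4)))
  })
}

test_that("an isotropic source gives a flat snapshot beam pattern", {
  res <- isotropic_snapshots()
  expect_gt(length(res$snapshots), 10)
  bp <- beam_pattern(res$snapshots, res$dx, res$origin,
                     center = c(0.18, 0.18), radius = 0.1,
                     angles = seq(-60, 60, by = 1), axis = "+x")
  expect_lt(max(bp$spl) - min(bp$spl), 0.2)
  expect_equal(max(bp$spl), bp$A)
  expect_error(beam_pattern(list(), res$dx, res$origin, c(0.18, 0.18), 0.1),
               "empty snapshot")
  expect_error(beam_pattern(res$snapshots, res$dx, res$origin,
                            c(0.18, 0.18), 5), "outside")
})

test_that("beamwidth of a flat pattern is flagged as degenerate", {
  flat <- biosonarsim:::beam_pattern_from_pp(rep(1, 121),
                                             seq(-60, 60, by = 1))
  bw <- beamwidth_3dB(flat)
  expect_equal(as.numeric(bw), 120)
  expect_true(attr(bw, "flat"))
})

test_that("beamwidth interpolates the analytic aperture pattern", {
  ang <- seq(-20, 20, by = 0.25)
  d <- analytic_line_directivity(0.116, 60e3, 1527, ang)
  bp <- biosonarsim:::beam_pattern_from_pp(d, ang)
  expect_equal(beamwidth_3dB(bp), 11.1, tolerance = 0.3 / 11.1)
})

test_that("two coherent sources reproduce the array-factor pattern", {
  # elements one wavelength apart: tone-component nulls at +/-30 degrees
  dx <- 1.5e-3
  lam <- wavelength()
  m <- medium_map(601, 601, dx)
  ctr <- c(0.31, 0.45)
  # element positions snap to the grid; the analytic oracle must use the
  # snapped spacing
  off <- round(lam / 2 / dx) * dx
  src <- rbind(ctr + c(0, off), ctr - c(0, off))
  d_el <- 2 * off
  ang <- seq(-45, 45, by = 1)
  recs <- lapply(ang, function(a) {
    ctr + 0.35 * c(cos(a * pi / 180), sin(a * pi / 180))
  })
  names(recs) <- sprintf("a%+03d", ang)
  sc <- custom_scene(m, src, recs, duration = 3.6e-4)
  res <- run_simulation(sc)
  n <- nrow(res$traces)
  w <- exp(-2i * pi * 60e3 * (seq_len(n) - 1) * res$dt)
  amp <- abs(as.vector(crossprod(res$traces, w)))
  af <- abs(cos(pi * d_el * sin(ang * pi / 180) / lam))
  # nulls and maxima line up with the analytic two-element factor
  expect_equal(amp / max(amp), af / max(af), tolerance = 0.08)
  null_pred <- asin(lam / (2 * d_el)) * 180 / pi
  null_meas <- ang[ang > 0][which.min(amp[ang > 0])]
  expect_lt(abs(null_meas - null_pred), 1)
})

test_that("the directivity index behaves as a beam-concentration measure", {
  ang <- seq(-180, 180, by = 0.5)
  omni <- biosonarsim:::beam_pattern_from_pp(rep(1, length(ang)), ang)
  expect_equal(directivity_index(omni), 0, tolerance = 1e-6)
  # narrower lobes concentrate more
  di <- sapply(c(30, 15, 8), function(s) {
    d <- exp(-(ang / s)^2)
    directivity_index(biosonarsim:::beam_pattern_from_pp(d, ang))
  })
  expect_true(all(diff(di) > 0))
  # half-wavelength in-phase pair: DI from the closed-form pattern matches
  # brute-force quadrature of |cos(pi/2 sin(theta))|^2
  d2 <- abs(cos(pi / 2 * sin(ang * pi / 180)))
  pat <- biosonarsim:::beam_pattern_from_pp(d2, ang)
  th <- ang * pi / 180
  di_oracle <- 10 * log10(2 * pi / pracma::trapz(th, (d2 / max(d2))^2))
  expect_equal(directivity_index(pat), di_oracle, tolerance = 0.1 / di_oracle)
})

test_that("lobe counting separates single- and multi-lobe patterns", {
  ang <- seq(-60, 60, by = 0.25)
  single <- exp(-(ang / 10)^2)
  expect_length(beam_lobes(biosonarsim:::beam_pattern_from_pp(single, ang)),
                1)
  multi <- abs(cos(pi * sin(ang * pi / 180) * 3)) + 0.05
  expect_gte(length(beam_lobes(biosonarsim:::beam_pattern_from_pp(multi, ang))),
             3)
})
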