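# Rasterization, DVH histograms and D/V endpoint evaluation.

test_that("axis-aligned box covers an exact voxel-center block", {
  ph <- make_phantom(phantom_spec(
    grid_shape = c(40, 40, 24), spacing = c(2, 2, 2),
    structures = list(structure_spec("box", "PTV", shape_box(40, 40, 28)))))
  m <- rasterize_structure(ph$rois$box, ph$grid)
  expect_equal(length(m$indices), 20 * 20 * 14)
  expect_equal(mask_volume_cc(m), 44.8)
})

test_that("sphere rasterization is within 3% at 2 mm and ring areas subtract", {
  ph <- make_phantom(phantom_spec(
    grid_shape = c(30, 30, 28), spacing = c(2, 2, 2),
    structures = list(structure_spec("sph", "PTV", shape_sphere(25)))))
  m <- rasterize_structure(ph$rois$sph, ph$grid)
  expect_lt(abs(mask_volume_cc(m) - 65.4498) / 65.4498, 0.03)

  ph2 <- make_phantom(phantom_spec(
    grid_shape = c(30, 30, 16), spacing = c(2, 2, 2),
    structures = list(
      structure_spec("ring", "ORGAN", shape_ring(20, 10, 20)),
      structure_spec("outer", "ORGAN", shape_cylinder(20, 20)),
      structure_spec("inner", "ORGAN", shape_cylinder(10, 20)))))
  n <- vapply(ph2$rois, function(r)
    length(rasterize_structure(r, ph2$grid)$indices), 0L)
  expect_equal(n[["ring"]], n[["outer"]] - n[["inner"]])
})

test_that("ROI outside the grid gives an empty mask with a warning", {
  ph <- make_phantom(phantom_spec(
    grid_shape = c(20, 20, 12), spacing = c(2, 2, 2),
    structures = list(structure_spec("PTV", "PTV", shape_sphere(8)))))
  far <- roi_contours("far", "ORGAN", list(list(z = 500, rings = list(
    list(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))))))
  expect_warning(m <- rasterize_structure(far, ph$grid), "empty mask")
  expect_length(m$indices, 0)
  expect_error(compute_dvh(m, ph$grid), "zero-volume")
})

test_that("uniform and two-level DVHs behave as step functions", {
  ph <- make_phantom(phantom_spec(
    grid_shape = c(40, 40, 24), spacing = c(2, 2, 2),
    dose_model = dose_uniform(60),
    structures = list(structure_spec("box", "PTV", shape_box(40, 40, 28)))))
  d <- compute_dvh(rasterize_structure(ph$rois$box, ph$grid), ph$grid,
                   rx_dose = 60)
  expect_equal(d$volume, 44.8)
  expect_equal(c(d$min_dose, d$mean_dose, d$max_dose), c(60, 60, 60))
  ec_dose_50 <- volume_at_dose(d, endpoint_spec("V", 50, "Gy"))
  expect_equal(ec_dose_50, 44.8)
  expect_equal(volume_at_dose(d, endpoint_spec("V", 70, "Gy")), 0)
  expect_equal(dose_at_volume(d, endpoint_spec("D", 95, "%")), 60,
               tolerance = d$bin_width)
  expect_equal(dose_at_volume(d, endpoint_spec("D", 2, "cc")), 60,
               tolerance = d$bin_width)

  two <- dvh_from_diff({ x <- numeric(6000); x[4000] <- 1; x[6000] <- 1; x },
                       bin_width = 0.01)
  expect_equal(two$mean_dose, 49.99, tolerance = 0.011)
  expect_equal(volume_at_dose(two, endpoint_spec("V", 45, "Gy")), 1)
})

test_that("cumulative DVH matches the voxel-counting oracle on a gradient", {
  ph <- make_phantom(phantom_spec(
    grid_shape = c(24, 24, 16), spacing = c(2.5, 2.5, 2.5),
    dose_model = dose_z_gradient(0.1),
    structures = list(structure_spec("PTV", "PTV", shape_sphere(14)))))
  m <- rasterize_structure(ph$rois$PTV, ph$grid)
  d <- compute_dvh(m, ph$grid)
  doses <- (ph$grid$values * ph$grid$dose_scaling)[m$indices]
  oracle <- oracle_cumulative(doses, m$voxel_mm3 / 1000, d$bin_width,
                              length(d$cumulative))
  expect_equal(d$cumulative, oracle, tolerance = 1e-12)
})

test_that("endpoint interpolation follows the closed form", {
  # cumulative: 10 cc up to 50 Gy, falling linearly to 0 at 60 Gy
  bw <- 0.01
  n <- 6000
  diffs <- numeric(n)
  drop_bins <- 5001:6000
  diffs[drop_bins] <- 10 / length(drop_bins)
  d <- dvh_from_diff(diffs, bin_width = bw, rx_dose = 70)
  expect_equal(dose_at_volume(d, endpoint_spec("D", 50, "%")), 55,
               tolerance = 2 * bw)
  expect_equal(dose_at_volume(d, endpoint_spec("D", 5, "cc")), 55,
               tolerance = 2 * bw)
  # relative output: D at 90% of rx
  d63 <- dvh_from_diff({ x <- numeric(6300); x[6300] <- 8; x },
                       bin_width = bw, rx_dose = 70)
  expect_equal(dose_at_volume(d63, endpoint_spec("D", 95, "%",
                                                 output_units = "rel")),
               90, tolerance = 0.1)
  # V_100% with rx 60 equals V_60Gy
  d60 <- dvh_from_diff({ x <- numeric(6000); x[6000] <- 8; x },
                       bin_width = bw, rx_dose = 60)
  expect_equal(volume_at_dose(d60, endpoint_spec("V", 100, "%")),
               volume_at_dose(d60, endpoint_spec("V", 60, "Gy")))
  expect_error(dose_at_volume(d60, endpoint_spec("D", 100, "cc")),
               "exceeds")
})

test_that("DVH monotonicity and D/V consistency hold across phantoms", {
  for (seed in c(1, 2, 3, 5, 8)) {
    ph <- oracle_phantom(seed)
    m <- rasterize_structure(ph$rois$PTV, ph$grid)
    d <- compute_dvh(m, ph$grid, rx_dose = 50)
    expect_true(all(diff(d$cumulative) <= 1e-12))
    expect_equal(d$cumulative[1], d$volume)
    expect_equal(sum(d$diff_counts), d$volume, tolerance = 1e-9)
    expect_lte(d$min_dose, d$mean_dose)
    expect_lte(d$mean_dose, d$max_dose)
    # dose_at_volume decreasing in volume; volume_at_dose decreasing in dose
    vols <- c(20, 50, 80, 95)
    ds <- vapply(vols, function(v)
      dose_at_volume(d, endpoint_spec("D", v, "%")), 0)
    expect_true(all(diff(ds) <= 1e-9))
    doses <- seq(0.5, d$max_dose, length.out = 8)
    vs <- vapply(doses, function(x)
      volume_at_dose(d, endpoint_spec("V", x, "Gy")), 0)
    expect_true(all(diff(vs) <= 1e-9))
    # consistency: V(D(v)) >= v within one bin's volume
    for (v in vols) {
      dv <- dose_at_volume(d, endpoint_spec("D", v, "%"))
      back <- volume_at_dose(d, endpoint_spec("V", dv, "Gy"))
      expect_gte(back, v / 100 * d$volume - max(d$diff_counts) - 1e-9)
    }
  }
})

test_that("sphere volume error decreases as the grid refines", {
  # generic (non-lattice) placement, as in patient data; lattice-aligned
  # placements make voxel-center counting error oscillate
  errs <- vapply(c(4, 2, 1), function(sp) {
    n <- ceiling(58 / sp)
    ph <- make_phantom(phantom_spec(
      grid_shape = c(n, n, n), spacing = rep(sp, 3),
      structures = list(structure_spec("sph", "PTV", shape_sphere(25),
                                       center = c(0.3, -0.6, 0.45)))))
    m <- rasterize_structure(ph$rois$sph, ph$grid)
    abs(mask_volume_cc(m) - 65.4498) / 65.4498
  }, 0)
  expect_lt(errs[2], 0.03)
  expect_true(all(diff(errs) < 0))
})

test_that("endpoint strings parse and label correctly", {
  sp <- parse_endpoint(c("D95%", "D_2cc", "V20Gy", "V50%:rel"))
  expect_equal(vapply(sp, `[[`, "", "kind"), c("D", "D", "V", "V"))
  expect_equal(vapply(sp, `[[`, 0, "value"), c(95, 2, 20, 50))
  expect_equal(sp[[4]]$output_units, "rel")
  expect_error(parse_endpoint("Q5"), "cannot parse")
})
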