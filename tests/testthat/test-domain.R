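test_that("domain construction gives isotropic voxels and rejects degenerate input", {
  d <- make_domain(7.5, 64)
  expect_equal(d$spacing, 7.5 / 64)
  expect_equal(make_domain(7.5, 75)$spacing, 0.1)
  # voxel volume conservation over the whole cube
  expect_equal(prod(d$dims) * voxel_volume(d), 7.5^3, tolerance = 1e-9)
  expect_error(make_domain(0, 64), "edge_length")
  expect_error(make_domain(7.5, 8), "resolution")
})

test_that("mask volumes follow the count-times-voxel rule", {
  d <- make_domain(7.5, 75)
  full <- irethreshold:::new_mask(d, array(TRUE, d$dims))
  expect_equal(mask_volume(full), 421.875)
  one <- array(FALSE, d$dims); one[40, 40, 40] <- TRUE
  expect_equal(mask_volume(irethreshold:::new_mask(d, one)), 0.001)
  none <- irethreshold:::new_mask(d, array(FALSE, d$dims))
  expect_warning(v <- mask_volume(none), "empty")
  expect_identical(v, 0)
})

test_that("rasterized ellipsoid volume matches the closed form and converges", {
  true_vol <- 4 * pi / 3 * 2 * 1.5 * 1
  d_fine <- make_domain(7.5, 150)  # 0.05 cm spacing
  v_fine <- mask_volume(ellipsoid_mask(d_fine, c(2, 1.5, 1)))
  expect_lt(abs(v_fine - true_vol) / true_vol, 0.02)
  # halving the spacing at least halves the error
  v_coarse <- mask_volume(ellipsoid_mask(make_domain(7.5, 75), c(2, 1.5, 1)))
  err <- function(v) abs(v - true_vol)
  expect_lt(err(v_fine), err(v_coarse) / 2 + 1e-12)
})

test_that("electrode grid geometry matches the square layout", {
  els <- place_electrode_grid(4, 2.0, 2.0)
  sp <- electrode_spacings(els)
  d <- sort(sp[upper.tri(sp)])
  expect_equal(d, c(2, 2, 2, 2, 2 * sqrt(2), 2 * sqrt(2)), tolerance = 1e-12)
  els2 <- place_electrode_grid(4, 1.4, 1.5)
  expect_equal(max(electrode_spacings(els2)), 1.4 * sqrt(2), tolerance = 1e-12)
  expect_equal(round(max(electrode_spacings(els2)), 3), 1.980)
  expect_error(place_electrode_grid(4, 5.0, 2.0), "limit")
  # containment check: a needle far longer than the cube cannot fit
  expect_error(place_electrode_grid(4, 2.0, 8.0), "outside")
})

test_that("electrode validation enforces unit axis and positive dimensions", {
  expect_error(electrode(c(0, 0, 0), axis = c(0, 0, 2), exposure_length = 1.5),
               "unit vector")
  expect_error(electrode(c(0, 0, 0), exposure_length = -1), "exposure_length")
  expect_error(electrode(c(0, 0, 0), exposure_length = 1.5, radius = 0),
               "radius")
})

test_that("clinical fixture table carries the ten printed records", {
  tab <- load_clinical_cohort()
  expect_equal(nrow(tab), 10)
  p2 <- tab[tab$patient_id == "P2", ]
  expect_equal(p2$max_voltage, 3000)
  expect_equal(p2$max_spacing, 2.0)
  expect_equal(p2$threshold_dynamic, 436)
  p8 <- tab[tab$patient_id == "P8", ]
  expect_equal(p8$threshold_dynamic, 614)
  expect_equal(p8$ablation_volume, 4.09)
  expect_equal(tab$psa_pre[1], 10.03)
  expect_equal(tab$ablation_volume[10], 4.63)
  # printed aggregates
  expect_equal(round(mean(tab$threshold_dynamic)), 506)
  expect_equal(range(tab$threshold_dynamic), c(412, 614))
})
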