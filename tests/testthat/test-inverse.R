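test_that("super-level volumes follow the step geometry", {
  d <- make_domain(7.5, 30)  # voxel volume 0.015625 cm^3
  e <- array(0, d$dims)
  block <- 1:4  # 64 voxels = 1 cm^3
  e[block, block, block] <- 100
  expect_equal(superlevel_volume(e, d, 0), 7.5^3)
  expect_equal(superlevel_volume(e, d, 50), 1)
  expect_equal(superlevel_volume(e, d, 150), 0)
  expect_equal(superlevel_volume(e, d, max(e) + 1), 0)
  expect_error(superlevel_volume(e, d, -5), "non-negative")
  # vectorized and non-increasing
  v <- superlevel_volume(e, d, c(0, 50, 100, 150))
  expect_true(all(diff(v) <= 0))
})

test_that("threshold inversion matches the closed-form 1/r^2 field", {
  d <- make_domain(7.5, 150)
  cc <- axis_centers(d)
  r <- sqrt(outer(outer(cc[[1]]^2, cc[[2]]^2, `+`), cc[[3]]^2, `+`))
  c0 <- 500 * 1.5^2  # point-like source scaled so E = 500 V/cm at r = 1.5 cm
  e <- c0 / pmax(r, 1e-6)^2
  for (e_t in c(450, 500, 550)) {
    r_star <- sqrt(c0 / e_t)  # super-level set is the ball of this radius
    th <- find_threshold(e, d, 4 / 3 * pi * r_star^3)
    expect_lte(abs(th$e_threshold - e_t), 1)
  }
  # self-consistency: a target produced at an integer contour is returned
  target <- superlevel_volume(e, d, 500)
  expect_equal(find_threshold(e, d, target)$e_threshold, 500L)
  # monotonicity: smaller targets need higher thresholds
  th_small <- find_threshold(e, d, 5)$e_threshold
  th_big <- find_threshold(e, d, 15)$e_threshold
  expect_gte(th_small, th_big)
})

test_that("volume ties resolve toward the lower (conservative) threshold", {
  d <- make_domain(7.5, 30)
  e <- array(0, d$dims)
  e[1:6, 1:6, 1:6] <- 100
  e[1:3, 1:3, 1:3] <- 200
  target <- superlevel_volume(e, d, 150)  # every contour in 101..200 ties
  expect_equal(find_threshold(e, d, target)$e_threshold, 101L)
})

test_that("threshold inversion rejects infeasible targets", {
  d <- make_domain(7.5, 30)
  e <- array(100, d$dims)
  expect_error(find_threshold(e, d, 7.5^3 * 2), "target_volume")
  expect_error(find_threshold(e, d, 0), "target_volume")
})

test_that("conductivity calibration recovers a planted sigma_max", {
  s <- square_setup()
  first <- c(s$plan$source[1], s$plan$sink[1])
  fwd <- solve_pair(s$domain, s$electrodes, first, s$plan$voltage[1],
                    tissue_model(sigma_max = 0.70))
  cal <- calibrate_sigma_max(s$domain, s$electrodes, s$plan,
                             fwd$source_current)
  expect_lt(abs(cal$sigma_max_hat - 0.70) / 0.70, 0.02)
  expect_true(cal$converged)
  expect_lt(abs(cal$achieved_current - cal$target_current) /
              cal$target_current, 0.005)
})

test_that("calibration degenerates to the baseline for a static-level current", {
  s <- square_setup()
  first <- c(s$plan$source[1], s$plan$sink[1])
  st <- solve_pair(s$domain, s$electrodes, first, s$plan$voltage[1],
                   tissue_model(mode = "static"))
  cal <- calibrate_sigma_max(s$domain, s$electrodes, s$plan,
                             st$source_current)
  expect_equal(cal$sigma_max_hat, 0.284, tolerance = 1e-6)
})

test_that("calibration refuses currents outside the achievable interval", {
  s <- square_setup()
  first <- c(s$plan$source[1], s$plan$sink[1])
  hi <- solve_pair(s$domain, s$electrodes, first, s$plan$voltage[1],
                   tissue_model(sigma_max = 2.0))
  expect_error(
    calibrate_sigma_max(s$domain, s$electrodes, s$plan,
                        10 * hi$source_current),
    "achievable interval")
  expect_error(
    calibrate_sigma_max(s$domain, s$electrodes, s$plan, 1e-3),
    "achievable interval")
})

test_that("bisection and the parametric sweep agree", {
  s <- square_setup(resolution = 24)
  first <- c(s$plan$source[1], s$plan$sink[1])
  fwd <- solve_pair(s$domain, s$electrodes, first, s$plan$voltage[1],
                    tissue_model(sigma_max = 0.82))
  bis <- calibrate_sigma_max(s$domain, s$electrodes, s$plan,
                             fwd$source_current)
  swp <- calibrate_sigma_max(s$domain, s$electrodes, s$plan,
                             fwd$source_current, method = "sweep",
                             sweep_step = 0.01, upper = 1.2)
  expect_lt(abs(bis$sigma_max_hat - swp$sigma_max_hat), 0.011)
})

test_that("full inference chain closes the loop on a synthetic patient", {
  coh <- generate_cohort(1, seed = 5, resolution = 32, current_noise = 0)
  p <- coh[[1]]
  inf <- infer_patient(p)
  expect_lt(abs(inf$sigma_max_hat - p$sigma_max_true) / p$sigma_max_true,
            0.02)
  expect_lte(abs(inf$threshold_dynamic - p$threshold_true), 5)
  # electroporation spreads the field, so the dynamic threshold sits higher
  expect_gt(inf$threshold_dynamic, inf$threshold_static)
})
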