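test_that("uniform-field (parallel-plate) solution is exact", {
  d <- coarse_domain(32)
  prob <- plate_problem(d)
  sol <- solve_field(d, prob$sigma, prob$dirichlet, prob$values)
  e_true <- prob$voltage / prob$gap_cm
  e <- irethreshold:::flux_magnitude(sol$phi, prob$sigma, d)
  tissue <- !prob$dirichlet
  expect_lt(max(abs(e[tissue] - e_true)) / e_true, 0.001)
  # I = sigma * V * A / d in SI
  i_true <- prob$sigma0 * prob$voltage * (d$edge_length / 100)^2 /
    (prob$gap_cm / 100)
  expect_equal(plate_current(d, prob, sol$phi), i_true, tolerance = 1e-6)
})

test_that("concentric-cylinder current matches the analytic solution", {
  d <- coarse_domain(64)
  prob <- cylinder_problem(d)
  sol <- solve_field(d, prob$sigma, prob$dirichlet, prob$values)
  i <- region_current_of(d, prob$sigma, sol$phi, prob$inner)
  expect_lt(abs(i - prob$current_true) / prob$current_true, 0.02)
  # potential profile phi(r) = V ln(b/r)/ln(b/a) at mid-height
  cc <- axis_centers(d)
  mid <- d$resolution / 2
  along_x <- sol$phi[, mid, mid]
  r <- sqrt(cc[[1]]^2 + cc[[2]][mid]^2)
  annulus <- r > 1.2 & r < 3.2
  phi_true <- prob$voltage * log(3.5 / r[annulus]) / log(3.5 / 1.0)
  expect_lt(max(abs(along_x[annulus] - phi_true)) / prob$voltage, 0.02)
})

test_that("static current scales linearly with conductivity and voltage", {
  d <- coarse_domain(24)
  prob <- plate_problem(d)
  sol1 <- solve_field(d, prob$sigma, prob$dirichlet, prob$values)
  i1 <- plate_current(d, prob, sol1$phi)
  sigma2 <- prob$sigma * 2
  sol2 <- solve_field(d, sigma2, prob$dirichlet, prob$values)
  prob2 <- prob; prob2$sigma <- sigma2
  expect_equal(plate_current(d, prob2, sol2$phi), 2 * i1, tolerance = 1e-8)
  sol3 <- solve_field(d, prob$sigma, prob$dirichlet, prob$values * 3)
  expect_equal(plate_current(d, prob, sol3$phi), 3 * i1, tolerance = 1e-8)
})

test_that("field magnitude recovers gradients at the expected order", {
  d <- make_domain(1, 20)
  x <- axis_centers(d)[[1]]
  ramp <- array(rep(100 * x, times = d$resolution^2), d$dims)
  expect_equal(field_magnitude(ramp, d), array(100, d$dims), tolerance = 1e-12)
  expect_equal(field_magnitude(array(5, d$dims), d), array(0, d$dims))
  # quadratic: central differences exact in the interior
  quad <- array(rep(x^2, times = d$resolution^2), d$dims)
  e <- field_magnitude(quad, d)
  interior <- 2:(d$resolution - 1)
  expect_equal(e[interior, 1, 1], abs(2 * x[interior]), tolerance = 1e-12)
  # cubic: interior truncation error shrinks as h^2
  err_at <- function(res) {
    dd <- make_domain(1, res)
    xx <- axis_centers(dd)[[1]]
    cub <- array(rep(xx^3, times = res^2), dd$dims)
    ee <- field_magnitude(cub, dd)
    idx <- 2:(res - 1)
    max(abs(ee[idx, 1, 1] - 3 * xx[idx]^2))
  }
  expect_gt(err_at(20) / err_at(40), 3.5)  # ~4 for O(h^2)
})

test_that("pair solutions conserve current and obey the maximum principle", {
  s <- square_setup()
  sol <- solve_pair(s$domain, s$electrodes, c(1, 4), 3000,
                    tissue_model(sigma_max = 0.7))
  expect_true(sol$converged)
  expect_lt(abs(sol$source_current - sol$sink_current) / sol$source_current,
            0.01)
  expect_gte(min(sol$phi), 0 - 1e-6 * 3000)
  expect_lte(max(sol$phi), 3000 * (1 + 1e-6))
  expect_true(all(sol$e_mag >= 0))
  expect_equal(pair_current(sol, "source"), sol$source_current)
  expect_equal(pair_current(sol, "sink"), sol$sink_current)
})

test_that("degenerate dynamic model reproduces the static solution exactly", {
  s <- square_setup()
  m_static <- tissue_model(mode = "static")
  m_degen <- tissue_model(sigma_max = 0.284)  # ceiling equals baseline
  a <- solve_pair(s$domain, s$electrodes, c(1, 2), 3000, m_static)
  b <- solve_pair(s$domain, s$electrodes, c(1, 2), 3000, m_degen)
  expect_identical(a$phi, b$phi)    # bitwise: same single linear solve
  expect_identical(b$iterations, 1L)
  expect_true(b$converged)
})

test_that("dynamic current is monotone in sigma_max and super-linear in voltage", {
  s <- square_setup()
  first <- c(s$plan$source[1], s$plan$sink[1])
  currents <- vapply(seq(0.3, 1.2, by = 0.1), function(sm) {
    solve_pair(s$domain, s$electrodes, first, 3000,
               tissue_model(sigma_max = sm))$source_current
  }, numeric(1))
  expect_true(all(diff(currents) > 0))
  m <- tissue_model(sigma_max = 0.8)
  volts <- c(500, 1500, 2500)
  iv <- vapply(volts, function(v) {
    solve_pair(s$domain, s$electrodes, first, v, m)$source_current
  }, numeric(1))
  # conductance I/V grows once the transition zone is entered
  expect_true(all(diff(iv / volts) > 0))
})

test_that("retained inactive electrodes barely perturb the solution beyond contrast 1e3", {
  s <- square_setup()
  i_of <- function(contrast) {
    solve_pair(s$domain, s$electrodes, c(1, 2), 3000,
               tissue_model(mode = "static"),
               control = solver_control(inactive_contrast = contrast)
               )$source_current
  }
  expect_lt(abs(i_of(1e4) - i_of(1e3)) / i_of(1e4), 0.01)
})

test_that("delivered current converges under grid refinement", {
  m <- tissue_model(mode = "static")
  i_at <- function(res) {
    d <- make_domain(7.5, res)
    els <- place_electrode_grid(4, 2.0, 2.0, domain = d)
    solve_pair(d, els, c(1, 2), 3000, m)$source_current
  }
  i24 <- i_at(24); i48 <- i_at(48); i96 <- i_at(96)
  expect_lt(abs(i96 - i48), abs(i48 - i24))
})

test_that("solver input validation catches unusable systems", {
  d <- coarse_domain(24)
  sig <- array(0.284, d$dims)
  expect_error(solve_field(d, sig, array(FALSE, d$dims), array(0, d$dims)),
               "singular")
  s <- square_setup(resolution = 24)
  expect_error(solve_pair(s$domain, s$electrodes, c(2, 2), 3000,
                          tissue_model(mode = "static")), "distinct")
  expect_error(solve_pair(s$domain, s$electrodes, c(1, 2), -5,
                          tissue_model(mode = "static")), "voltage")
})
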