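test_that("pair enumeration covers all unordered pairs", {
  expect_equal(nrow(enumerate_pairs(vector("list", 4))), 6)
  expect_equal(nrow(enumerate_pairs(vector("list", 2))), 1)
  expect_equal(nrow(enumerate_pairs(vector("list", 6))), 15)
  expect_error(enumerate_pairs(vector("list", 1)), "at least 2")
})

test_that("voltage-to-distance rule applies the hardware cap", {
  expect_equal(pair_voltage(2.0), 3000)
  expect_equal(pair_voltage(1.4), 2100)
  expect_equal(pair_voltage(2.2), 3000)
  expect_equal(round(pair_voltage(2.2) / 2.2), 1364)  # reduced effective ratio
  expect_equal(pair_voltage(1.0, ratio = 1000, cap = 3000), 1000)
  expect_error(pair_voltage(0), "positive")
})

test_that("activation order runs from highest voltage / largest spacing down", {
  els <- place_electrode_grid(4, 2.0, 2.0)
  plan <- treatment_plan(els)
  expect_equal(nrow(plan), 6)
  expect_true(all(diff(plan$voltage) <= 0))
  expect_true(all(plan$voltage <= 3000))
  # capped voltages tie at 3000; diagonals (2.828 cm) must fire first
  expect_equal(plan$spacing[1:2], rep(2 * sqrt(2), 2), tolerance = 1e-12)
  # among equal-spacing ties, ascending (source, sink) order
  sides <- plan[3:6, ]
  expect_equal(order(sides$source, sides$sink), 1:4)
  # stability: equal spacings everywhere preserve index order
  eq <- data.frame(source = c(1, 1, 2), sink = c(2, 3, 3),
                   spacing = 1.5, voltage = 2250)
  expect_equal(order_plan(eq)$sink, c(2, 3, 3))
  single <- order_plan(data.frame(source = 1, sink = 2, spacing = 2,
                                  voltage = 3000))
  expect_equal(nrow(single), 1)
})

test_that("plan aggregation takes voxelwise maxima over pairs", {
  s <- square_setup(resolution = 24)
  m <- tissue_model(mode = "static")
  res <- run_plan(s$domain, s$electrodes, s$plan, m)
  expect_equal(length(res$currents), 6)
  expect_true(all(res$converged))
  # E_max dominates each individual pair field and equals one of them voxelwise
  sol1 <- solve_pair(s$domain, s$electrodes,
                     c(s$plan$source[1], s$plan$sink[1]), s$plan$voltage[1], m)
  expect_true(all(res$e_max >= sol1$e_mag - 1e-12))
  one_pair <- s$plan[1, ]
  res1 <- run_plan(s$domain, s$electrodes, one_pair, m)
  expect_equal(res1$e_max, sol1$e_mag)
  # duplicating a pair leaves the maximum unchanged
  res2 <- run_plan(s$domain, s$electrodes, rbind(one_pair, one_pair), m)
  expect_equal(res2$e_max, res1$e_max)
})

test_that("field magnitude is invariant under polarity reversal", {
  s <- square_setup(resolution = 24)
  m <- tissue_model(mode = "static")
  a <- solve_pair(s$domain, s$electrodes, c(1, 2), 3000, m)
  b <- solve_pair(s$domain, s$electrodes, c(2, 1), 3000, m)
  expect_lt(max(abs(a$e_mag - b$e_mag)) / max(a$e_mag), 1e-7)
})
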