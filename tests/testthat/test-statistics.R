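test_that("pearson matches a brute-force sum-of-products computation", {
  brute <- function(x, y) {
    n <- length(x)
    sx <- sum(x); sy <- sum(y)
    num <- n * sum(x * y) - sx * sy
    den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
    r <- num / den
    t <- r * sqrt((n - 2) / (1 - r^2))
    list(r = r, p = 2 * pt(-abs(t), n - 2))
  }
  set.seed(71)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.3 * x
    got <- pearson(x, y)
    want <- brute(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
  x <- rnorm(10)
  expect_equal(pearson(x, x)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  expect_error(pearson(x, rep(1, 10)), "zero variance")
  expect_error(pearson(1:3, 1:4), "equal length")
})

test_that("clinical correlations reproduce the published values", {
  tab <- load_clinical_cohort()
  # agreement to the three printed decimals
  expect_lt(abs(pearson(tab$psa_pre, tab$threshold_dynamic)$r - (-0.624)), 5e-4)
  expect_lt(abs(pearson(tab$psa_pre, tab$delta_current)$r - 0.694), 5e-4)
  expect_lt(abs(pearson(tab$psa_pre, tab$ablation_volume)$r - 0.730), 5e-4)
  expect_lt(abs(pearson(tab$threshold_dynamic, tab$ablation_volume)$r - (-0.896)), 5e-4)
  expect_lt(abs(pearson(tab$psa_pre, tab$threshold_dynamic)$p - 0.054), 5e-4)
})

test_that("post-hoc power behaves like a power function", {
  # null effect: power collapses to the significance level
  expect_equal(posthoc_power(1e-12, 10), 0.05, tolerance = 1e-6)
  # monotone in |r| at fixed n, and in n at fixed r
  rs <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(sapply(rs, posthoc_power, n = 10)) > 0))
  ns <- c(5, 10, 20, 50)
  expect_true(all(diff(sapply(ns, function(n) posthoc_power(0.5, n))) > 0))
  # published power column (retrospective power at the observed t)
  printed <- c(50.9, 66.6, 75.4, 99.9)
  got <- 100 * sapply(c(-0.624, 0.694, 0.730, -0.896), posthoc_power, n = 10)
  expect_true(all(abs(got - printed) < 0.15))
  # the Fisher-z approximation is coarser on a sample of ten
  expect_lt(abs(100 * posthoc_power(0.694, 10, method = "fisher_z") - 66.6), 5)
  expect_error(posthoc_power(1, 10), "r")
  expect_error(posthoc_power(0.5, 3), "n")
})

test_that("the correlation table reports the four recoverable rows", {
  out <- cohort_correlations()
  expect_equal(nrow(out), 4)
  expect_equal(out$r, c(-0.624, 0.694, 0.730, -0.896), tolerance = 5e-4)
  expect_true(all(out$n == 10))
  expect_true(all(abs(out$r) <= 1))
  expect_true(all(out$p >= 0 & out$p <= 1))
  expect_true(all(out$power_pct > 0 & out$power_pct < 100))
  expect_match(attr(out, "omitted"), "Change in PSA")
})

test_that("Schwan transmembrane potential is linear in field and radius", {
  expect_equal(tmp_max(0, 10e-6), 0)
  expect_equal(tmp_max(66667, 10e-6), 1.0, tolerance = 1e-4)
  expect_equal(tmp_max(1000, 20e-6), 2 * tmp_max(1000, 10e-6))
  # field needed for a fixed critical TMP scales as 1/r: larger cells have
  # lower lethal thresholds
  e_crit <- function(r) 1 / (1.5 * r)
  expect_equal(e_crit(2e-5) / e_crit(1e-5), 0.5)
  expect_error(tmp_max(-1, 1e-5), "e_field")
})
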