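# Allometric power laws: evaluation, fitting, linear density conversions,
# size-class polyp lookup, growth increments.

test_that("power laws evaluate correctly and pass through the origin", {
  # frozen oracle values from log-space evaluation exp(log a + b log h)
  m_es <- power_law(0.2869, 1.9652)
  expect_equal(evaluate_power_law(m_es, 10), 26.4807659, tolerance = 1e-7)
  m_pc <- power_law(1.06, 1.69)
  expect_equal(evaluate_power_law(m_pc, 20), 167.5122, tolerance = 1e-6)
  # origin, including laws with b <= 0 where x^b would blow up
  expect_identical(evaluate_power_law(m_es, 0), 0)
  expect_identical(evaluate_power_law(power_law(2, -0.5), 0), 0)
  expect_error(evaluate_power_law(m_es, -1), "height")
  expect_error(power_law(-1, 2), "must be > 0")
})

test_that("power laws are strictly increasing in height for b > 0", {
  set.seed(42)
  for (i in 1:25) {
    m <- power_law(runif(1, 0.01, 5), runif(1, 0.1, 3))
    h <- sort(runif(10, 0, 100))
    expect_true(all(diff(evaluate_power_law(m, h)) > 0))
    # inversion round-trip
    y <- evaluate_power_law(m, h)
    expect_equal(invert_power_law(m, y), h, tolerance = 1e-10)
  }
})

test_that("fit_power_law recovers coefficients from noiseless pairs", {
  h <- c(5, 8, 12, 17, 25, 33, 40)
  y <- 0.2869 * h^1.9652
  fit <- fit_power_law(h, y)
  expect_equal(fit$a, 0.2869, tolerance = 1e-8)
  expect_equal(fit$b, 1.9652, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n_fit, 7)
  # refit reproduces training pairs
  expect_equal(evaluate_power_law(fit, h), y, tolerance = 1e-9)
})

test_that("fit_power_law under multiplicative noise stays near truth", {
  pairs <- generate_measurement_pairs(power_law(2, 1.5), n = 60,
                                      noise_sd = 0.1, seed = 7)
  fit <- fit_power_law(pairs$height_cm, pairs$response_value)
  expect_lt(abs(fit$b - 1.5), 0.1)
  expect_lt(fit$r_squared, 1)
  # 95% CI brackets the true exponent
  expect_true(fit$ci["b", 1] <= 1.5 && 1.5 <= fit$ci["b", 2])
})

test_that("fit_power_law rejects underdetermined or invalid input", {
  expect_error(fit_power_law(c(1, 2), c(1, 2)), ">= 3")
  expect_error(fit_power_law(c(1, 2, -3), c(1, 2, 3)), "> 0")
})

test_that("linear density conversions are linear with correct units", {
  afdm <- linear_density(18.35, 2.33, "mg_AFDM_per_cm")
  expect_equal(length_to_afdm(100, afdm), 1.835)
  expect_equal(length_to_afdm(0, afdm), 0)
  expect_equal(length_to_afdm(10, linear_density(2.94, units = "mg_AFDM_per_cm")),
               0.0294)
  pol <- linear_density(31.1, 1.1, "polyps_per_cm")
  expect_equal(length_to_polyps(10, pol), 311)
  expect_equal(length_to_polyps(2, pol), 62.2)
  expect_equal(length_to_polyps(0, pol), 0)
  # homogeneity of degree 1
  k <- 3.7
  expect_equal(length_to_afdm(k * 12, afdm), k * length_to_afdm(12, afdm))
  expect_equal(length_to_polyps(k * 12, pol), k * length_to_polyps(12, pol))
  # unit mismatch is an error
  expect_error(length_to_afdm(10, pol), "units")
  expect_error(length_to_polyps(10, afdm), "units")
})

test_that("size-class polyp lookup uses half-open classes and clamps ends", {
  tab <- polyp_size_table(edges = c(0, 10, 20, 30),
                          polyps = c(630, 5000, 26175))
  expect_equal(height_to_polyps_by_class(5, tab), 630)
  expect_equal(height_to_polyps_by_class(25, tab), 26175)
  # boundary belongs to the upper class
  expect_equal(height_to_polyps_by_class(10, tab), 5000)
  expect_warning(out <- height_to_polyps_by_class(45, tab), "clamped")
  expect_equal(out, 26175)
  expect_error(polyp_size_table(c(0, 10), c(5, 6)), "k\\+1 edges")
  expect_error(polyp_size_table(c(0, 10, 20), c(100, 50)), "non-decreasing")
})

test_that("growth converts height increments to length increments", {
  m <- power_law(0.2869, 1.9652)
  # frozen: a*(11^b) - a*(10^b) computed in log space
  expect_equal(growth_to_length_increment(m, 10, 1), 5.4548615,
               tolerance = 1e-6)
  expect_equal(growth_to_length_increment(m, 10, 0), 0)
  # linear law: increment equals the height increment exactly
  expect_equal(growth_to_length_increment(power_law(1, 1), 5, 2), 2)
  expect_error(growth_to_length_increment(m, 5, -1), ">= 0")
  # non-negative over random models
  set.seed(3)
  for (i in 1:10) {
    m2 <- power_law(runif(1, 0.1, 3), runif(1, 0.5, 2.5))
    expect_gte(growth_to_length_increment(m2, runif(1, 0, 50), runif(1, 0, 5)), 0)
  }
})
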