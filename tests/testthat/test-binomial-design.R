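test_that("binomial upper tail matches direct summation and full enumeration", {
  cases <- list(
    list(n = 25, p = 0.3, k = 7, expected = 0.65934508),
    list(n = 50, p = 0.3, k = 13, expected = 0.77713420),
    list(n = 75, p = 0.3, k = 19, expected = 0.84340642)
  )
  for (cs in cases) {
    expect_equal(binomial_tail_geq(cs$n, cs$p, cs$k), cs$expected, tolerance = 1e-7)
    expect_equal(binomial_tail_geq(cs$n, cs$p, cs$k), oracle_tail_sum(cs$n, cs$p, cs$k))
  }
  # exhaustive enumeration of outcomes, n <= 12
  for (n in c(4L, 8L, 12L)) {
    for (p in c(0.1, 0.3, 0.62)) {
      for (k in c(0L, 1L, n %/% 2L, n, n + 1L)) {
        expect_equal(
          binomial_tail_geq(n, p, k),
          oracle_tail_enum(n, p, k),
          tolerance = 1e-12
        )
      }
    }
  }
})

test_that("tail boundaries and domain errors behave", {
  expect_identical(binomial_tail_geq(25, 0.3, 0), 1)
  expect_identical(binomial_tail_geq(25, 0, 1), 0)
  expect_identical(binomial_tail_geq(25, 0.3, 26), 0)
  expect_error(binomial_tail_geq(25.5, 0.3, 2), "integer")
  expect_error(binomial_tail_geq(25, 1.3, 2), "0, 1")
  expect_error(binomial_tail_geq(25, 0.3, 27), "0..n")
})

test_that("threshold discretization gives the minimum passing count", {
  expect_identical(min_count_for_threshold(25, 0.25), 7L)
  expect_identical(min_count_for_threshold(50, 0.25), 13L)
  expect_identical(min_count_for_threshold(4, 0.25), 1L)
  expect_identical(min_count_for_threshold(75, 0.25), 19L)
  # exact-multiple grid points are immune to float representation error
  expect_identical(min_count_for_threshold(20, 0.55), 11L)
  # strict rule: pass only above the threshold
  expect_identical(min_count_for_threshold(4, 0.25, "strict_gt"), 2L)
  expect_identical(min_count_for_threshold(25, 0.25, "strict_gt"), 7L)
  expect_error(min_count_for_threshold(25, 0), "threshold")
  # the count rule is exactly the observed-fraction event
  for (n in c(7L, 25L, 50L)) {
    for (t in c(0.1, 0.25, 0.4)) {
      k <- min_count_for_threshold(n, t)
      x <- 0:n
      expect_identical(x / n >= t, x >= k)
    }
  }
})

test_that("effective n shrinks by germination and roguing only on request", {
  expect_identical(effective_n(screening_scenario(50)), 50L)
  expect_identical(effective_n(screening_scenario(50, adjust_n = TRUE)), 38L)
  expect_identical(effective_n(screening_scenario(25, adjust_n = TRUE)), 19L)
  expect_identical(
    effective_n(screening_scenario(1, germination_rate = 0.5, adjust_n = TRUE)),
    1L
  )
})

test_that("detection probability reproduces the summation oracle and is monotone in p", {
  sc25 <- screening_scenario(25)
  sc50 <- screening_scenario(50)
  expect_equal(detection_probability(sc25, 0.30), 0.659, tolerance = 1e-3)
  expect_equal(detection_probability(sc50, 0.30), oracle_tail_sum(50, 0.30, 13))
  expect_identical(detection_probability(sc25, 1.0), 1)
  p_grid <- seq(0, 1, by = 0.01)
  for (n in c(25L, 50L, 75L)) {
    for (t in seq(0.10, 0.70, by = 0.05)) {
      d <- detection_probability(screening_scenario(n, threshold = t), p_grid)
      expect_true(all(diff(d) >= 0))
    }
  }
})

test_that("false negative rate is the exact complement of detection", {
  for (n in c(25L, 50L, 75L)) {
    for (t in seq(0.10, 0.70, by = 0.05)) {
      sc <- screening_scenario(n, threshold = t)
      for (p in c(0, 0.1, 0.3, 0.77, 1)) {
        expect_identical(false_negative_rate(sc, p) + detection_probability(sc, p), 1)
      }
    }
  }
  expect_equal(false_negative_rate(screening_scenario(75)), 0.1565936, tolerance = 1e-6)
  expect_equal(false_negative_rate(screening_scenario(25)), 1 - 0.6593451, tolerance = 1e-6)
  expect_identical(false_negative_rate(screening_scenario(25), 1.0), 0)
})

test_that("false positive rate is small at the 25% rule and nonincreasing in threshold", {
  expect_identical(false_positive_rate(screening_scenario(25), 0), 0)
  fpr25 <- false_positive_rate(screening_scenario(25))
  fpr50 <- false_positive_rate(screening_scenario(50))
  expect_gt(fpr25, 0)
  expect_lt(fpr25, 0.05)
  expect_lt(fpr50, fpr25)
  for (n in c(25L, 50L, 75L)) {
    fprs <- vapply(
      seq(0.10, 0.70, by = 0.05),
      function(t) false_positive_rate(screening_scenario(n, threshold = t)),
      numeric(1)
    )
    expect_true(all(diff(fprs) <= 0))
  }
})

test_that("a growing sample separates fertility classes around the threshold", {
  sc <- function(p) detection_probability(screening_scenario(2000, threshold = 0.25), p)
  expect_lt(abs(sc(0.40) - 1), 0.01)
  expect_lt(abs(sc(0.10) - 0), 0.01)
})

test_that("true discovery rate composes class detection under the prior", {
  sc50 <- screening_scenario(50)
  point_prior <- function(pi_high) hmf_prior(pi_high = pi_high, low = 0.10, high = 0.30)
  expect_identical(true_discovery_rate(sc50, point_prior(1)), 1)
  expect_identical(true_discovery_rate(sc50, point_prior(0)), 0)
  d_h <- oracle_tail_sum(50, 0.30, 13)
  d_l <- oracle_tail_sum(50, 0.10, 13)
  expect_equal(
    true_discovery_rate(sc50, point_prior(0.1)),
    0.1 * d_h / (0.1 * d_h + 0.9 * d_l)
  )
  # reference-point evaluation agrees with point-mass quadrature
  expect_equal(
    true_discovery_rate(sc50, point_prior(0.2)),
    true_discovery_rate(sc50, point_prior(0.2), integration = "quadrature")
  )
  # undefined when nothing can pass
  zero <- hmf_prior(pi_high = 0, low = 0, high = 0.99)
  sc_hard <- screening_scenario(50, threshold = 0.9)
  expect_warning(
    out <- true_discovery_rate(sc_hard, zero, integration = "quadrature"),
    "undefined"
  )
  expect_true(is.na(out))
})

test_that("TDR increases with the high-class prior weight and quadrature tracks sampling", {
  sc <- screening_scenario(50)
  tdrs <- vapply(
    seq(0.05, 0.95, by = 0.1),
    function(w) true_discovery_rate(sc, hmf_prior(pi_high = w, low = 0.10, high = 0.30)),
    numeric(1)
  )
  expect_true(all(diff(tdrs) > 0))
  prior <- hmf_prior()
  quad <- true_discovery_rate(sc, prior, integration = "quadrature")
  mc <- true_discovery_rate(sc, prior, integration = "monte_carlo", n_draws = 50000, seed = 11)
  expect_true(quad >= 0 && quad <= 1)
  expect_equal(mc, quad, tolerance = 0.02)
})

test_that("scenario construction validates its inputs", {
  expect_error(screening_scenario(0), "positive integer")
  expect_error(screening_scenario(50, threshold = 1), "0, 1")
  expect_error(screening_scenario(50, germination_rate = 1.2), "0, 1")
  expect_error(screening_scenario(50, rounding_rule = "nearest"), "arg")
})
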