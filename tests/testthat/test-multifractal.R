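test_that("the partition function matches closed forms", {
  quarters <- measure_grid(matrix(0.25, 2, 2), mode = "probability")
  expect_equal(partition_function(quarters, 1, 1L), 1)
  expect_equal(partition_function(quarters, 0, 1L), 4)
  expect_equal(partition_function(quarters, 2, 1L), 0.25)
  # aggregation: one box holding everything
  expect_equal(partition_function(quarters, 7, 2L), 1)
  expect_error(partition_function(quarters, 0, 3L), "divisor")
})

test_that("zero-measure boxes are excluded at negative exponents", {
  g <- cascade_field("M4", n = 4)
  z <- partition_function(g, -2, 1L)
  expect_true(is.finite(z))
  # all 3^4 occupied cells carry equal measure 3^-4
  expect_equal(z, 81 * (1 / 81)^-2)
})

test_that("estimated spectra are non-increasing with diagnostics attached", {
  u <- uniform_square_points(5e4, seed = 10)
  sp <- generalized_dimensions(rasterize(u, 128L),
                               box_config(s_grid = seq(-4, 4, 0.5)))
  expect_true(all(diff(sp$D) < 0.02))
  expect_true(all(sp$r_squared > 0.98))
  expect_true(all(sp$n_scales >= 3))
})

test_that("legendre transform collapses monofractals to a point", {
  s <- seq(-6, 6, 0.25)
  mono <- tibble::tibble(s = s, D = 2, tau = (s - 1) * 2)
  class(mono) <- c("mf_spectrum", class(mono))
  leg <- legendre_spectrum(mono)
  expect_equal(leg$alpha, rep(2, length(s)))
  expect_equal(leg$f, rep(2, length(s)))
  # M4: the gasket point (log2 3, log2 3)
  leg4 <- legendre_spectrum(analytic_generalized_dimensions("M4"))
  expect_equal(range(leg4$alpha), rep(log2(3), 2), tolerance = 1e-10)
  expect_equal(range(leg4$f), rep(log2(3), 2), tolerance = 1e-10)
})

test_that("f(alpha(0)) equals D0 and the transform is self-consistent", {
  for (m in c("M1", "M3", "M5")) {
    leg <- legendre_spectrum(analytic_generalized_dimensions(m))
    at0 <- which(leg$s == 0)
    expect_equal(leg$f[at0], leg$D[at0], tolerance = 1e-6)
    # s * alpha - f reproduces tau
    expect_lt(max(abs(leg$s * leg$alpha - leg$f - leg$tau)), 1e-8)
    # concavity of f on the interior of the grid
    interior <- seq(3, nrow(leg) - 2)
    expect_true(all(diff(leg$alpha[interior]) <= 1e-10))
  }
})

test_that("heterogeneity width separates mono- from multifractals", {
  expect_equal(heterogeneity_width(
    analytic_generalized_dimensions("M7"))$width, 0, tolerance = 1e-10)
  expect_equal(heterogeneity_width(
    analytic_generalized_dimensions("M4"))$width, 0, tolerance = 1e-10)
  w5 <- heterogeneity_width(analytic_generalized_dimensions("M5"))
  expect_equal(w5$alpha_min_inf, log2(2.75))
  expect_equal(w5$alpha_max_inf, log2(11))
  expect_gt(w5$width, 1)
})

test_that("the scaling-relation solver matches closed forms", {
  expect_equal(dimension_from_scaling(3, 0.5), log2(3), tolerance = 1e-9)
  expect_equal(dimension_from_scaling(4, 0.5), 2, tolerance = 1e-9)
  # two scales: root of (1/2)^D + 4 (1/4)^D = 1; bisection oracle
  g <- function(D) 1 * 0.5^D + 4 * 0.25^D - 1
  lo <- 0; hi <- 10
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(dimension_from_scaling(c(1, 4), c(0.5, 0.25)), lo,
               tolerance = 1e-8)
  expect_equal(round(lo, 3), 1.357)
  expect_error(dimension_from_scaling(1, 0.9), NA)
})

test_that("degenerate regressions are rejected", {
  tiny <- measure_grid(matrix(1 / 16, 4, 4), mode = "probability")
  expect_error(generalized_dimensions(tiny), "fewer than 3")
})
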