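test_that("cascade fields are Kronecker powers of the generator block", {
  f1 <- cascade_field(c(1, 1, 0.5, 0.25), n = 1, normalize = FALSE)
  # y-up storage: row 1 is the bottom row (p3, p4)
  expect_equal(f1$values, rbind(c(0.5, 0.25), c(1, 1)))
  # raw sum identity: (sum p)^n
  for (n in c(2, 5)) {
    f <- cascade_field(c(1, 1, 0.5, 0.25), n = n, normalize = FALSE)
    expect_equal(sum(f$values), 2.75^n)
    expect_equal(dim(f$values), c(2^n, 2^n))
  }
})

test_that("M4 support is a Sierpinski gasket with 3^n occupied cells", {
  f <- cascade_field("M4", n = 5, normalize = FALSE)
  expect_equal(sum(f$values > 0), 243L)
  expect_equal(sum(f$values), 243)  # all nonzero products are 1
})

test_that("invalid cascade specs are rejected", {
  expect_error(cascade_field("M9", n = 2), "unknown cascade model")
  expect_error(cascade_field(c(0, 0, 0, 0), n = 2), "not all zero")
  expect_error(cascade_field("M1", n = 13), "exceeds the grid cap")
})

test_that("analytic spectra of M4 and M7 are flat at log2(3) and 2", {
  s4 <- analytic_generalized_dimensions("M4")
  expect_equal(unique(round(s4$D, 10)), round(log2(3), 10))
  s7 <- analytic_generalized_dimensions("M7")
  expect_equal(range(s7$D), c(2, 2))
  expect_equal(s7$tau, (s7$s - 1) * 2)
})

test_that("the s -> -Inf asymptote comes from the smallest nonzero cell", {
  s5 <- analytic_generalized_dimensions("M5")
  # closed form: -log2(min f_j) with f = (1, 1, 0.5, 0.25)/2.75
  expect_equal(attr(s5, "alpha_max_inf"), log2(11))
  expect_equal(attr(s5, "alpha_min_inf"), log2(2.75))
  # finite-s spectrum approaches the asymptote from below
  wide <- analytic_generalized_dimensions("M5",
                                          s_grid = c(-1000, -10, 10, 1000))
  expect_lt(abs(wide$D[1] - log2(11)), 0.005)
  expect_lt(abs(wide$D[4] - log2(2.75)), 0.005)
})

test_that("M5 and M6 share a dimension spectrum; all spectra decrease", {
  sg <- seq(-8, 8, 0.2)
  expect_equal(analytic_generalized_dimensions("M5", sg)$D,
               analytic_generalized_dimensions("M6", sg)$D)
  for (m in cascade_models()$model) {
    D <- analytic_generalized_dimensions(m, sg)$D
    expect_true(all(diff(D) < 1e-10), info = m)
  }
})

test_that("s = 1 uses the entropy limit, continuous with neighbors", {
  sp <- analytic_generalized_dimensions("M1", s_grid = c(0.999, 1, 1.001))
  expect_lt(diff(range(sp$D)), 1e-3)
  f <- c(1, 1, 1, 0.5) / 3.5
  expect_equal(sp$D[2], -sum(f * log2(f)))
})

test_that("box counting on cascade fields reproduces the closed form", {
  sg <- seq(-5, 5, 0.5)
  for (m in c("M1", "M4", "M5")) {
    est <- generalized_dimensions(cascade_field(m, n = 7),
                                  box_config(s_grid = sg))
    an <- analytic_generalized_dimensions(m, s_grid = sg)
    expect_lt(max(abs(est$D - an$D)), 0.05)
  }
})

test_that("box-counting error does not grow with iteration depth", {
  sg <- seq(-3, 3, 0.5)
  an <- analytic_generalized_dimensions("M5", s_grid = sg)
  err <- vapply(c(5L, 8L), function(n) {
    est <- generalized_dimensions(cascade_field("M5", n = n),
                                  box_config(s_grid = sg))
    max(abs(est$D - an$D))
  }, numeric(1))
  expect_lt(err[2], 0.05)
  expect_lte(err[2], err[1] + 1e-8)
})
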