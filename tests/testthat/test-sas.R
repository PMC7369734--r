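test_that("pair-distance histograms conserve all unordered pairs", {
  sq <- make_points(c(0, 1, 0, 1), c(0, 0, 1, 1))
  h <- pair_distance_histogram(sq, bin_width = 0.01)
  expect_equal(sum(h$g), 6)
  # 4 edges at distance 1, 2 diagonals at sqrt(2)
  expect_equal(sum(h$g[h$r > 0.99 & h$r < 1.01]), 4)
  expect_equal(sum(h$g[h$r > 1.40]), 2)

  two <- make_points(c(0.1, 0.4), c(0.2, 0.2))
  h2 <- pair_distance_histogram(two, bin_width = 0.02)
  expect_equal(sum(h2$g), 1)
  expect_lt(abs(h2$r[h2$g == 1] - 0.3), 0.02)  # bin containing 0.3

  u <- uniform_square_points(1000, seed = 3)
  expect_equal(sum(pair_distance_histogram(u)$g), 1000 * 999 / 2)
  expect_error(pair_distance_histogram(make_points(0, 0)), "at least 2")
})

test_that("Debye intensity honors its exact anchors", {
  pts <- uniform_square_points(40, seed = 5)
  h <- pair_distance_histogram(pts)
  cv <- debye_intensity(h, c(0, 1, 10))
  expect_equal(cv$I[1], 1600)   # I(0) = N^2
  expect_equal(cv$S[1], 1)
  # N = 2 at distance d: q = pi/d kills the cross term
  d <- 75.5 * 0.004           # a bin center, so binning is exact here
  two <- make_points(c(0, d), c(0, 0))
  h2 <- pair_distance_histogram(two, bin_width = 0.004)
  expect_equal(debye_intensity(h2, pi / d)$I, 2, tolerance = 1e-12)
  expect_error(debye_intensity(h2, numeric(0)), "empty")
})

test_that("binned Debye agrees with the exact pair double-sum", {
  pts <- uniform_square_points(150, seed = 7)
  h <- pair_distance_histogram(pts)  # default bin width l/1000
  q <- q_log_grid(1, 1 / 64)
  ours <- debye_intensity(h, q)$I
  oracle <- direct_debye(pts$x, pts$y, q)
  expect_lt(max(abs(ours - oracle) / abs(oracle)), 0.01)
})

test_that("regime detection inverts the plateau into the point count", {
  u <- uniform_square_points(1000, seed = 9)
  h <- pair_distance_histogram(u)
  cv <- debye_intensity(h, q_log_grid(1, 1 / 100))
  reg <- detect_regimes(cv, 1, 1 / 100)
  expect_equal(reg$q_guinier_fractal, 2 * pi)
  expect_equal(reg$k_estimate, 1000, tolerance = 0.1)
  expect_error(detect_regimes(cv, 1, 1 / 1e5), "span")
})

test_that("power-law fits recover exponents of known structures", {
  # synthetic exact power law
  q <- q_log_grid(1, 1 / 64)
  synth <- tibble::tibble(q = q, I = q^-2 * 100, S = q^-2)
  class(synth) <- c("sas_curve", class(synth))
  expect_equal(fit_power_law_exponent(synth, range(q))$D, 2,
               tolerance = 1e-10)

  # uniform square: Euclidean, D = 2
  u <- uniform_square_points(2e4, seed = 2)
  hu <- pair_distance_histogram(u)
  cu <- debye_intensity(hu, q_log_grid(1, 1 / 360))
  fu <- fit_power_law_exponent(cu, fractal_fit_range(1, 1 / 360, 2e4))
  expect_equal(fu$D, 2, tolerance = 0.1)

  # chaos-game gasket points: D = log2 3
  att <- chaos_game_attractor(square_ifs_maps(1:3), n_points = 2e4, seed = 5)
  ha <- pair_distance_histogram(att)
  ca <- debye_intensity(ha, q_log_grid(1, 1 / 256))
  fa <- fit_power_law_exponent(ca, fractal_fit_range(1, 1 / 256, 2e4))
  expect_equal(fa$D, log2(3), tolerance = 0.1)

  expect_error(fit_power_law_exponent(synth, c(1e-9, 2e-9)), "fewer than 5")
  td <- tidy(fu)
  expect_equal(nrow(td), 2L)
  expect_equal(glance(fu)$D, fu$D)
})

test_that("log-periodicity recovers the halving scale of binarized gaskets", {
  n_min <- integer(0)
  for (n in c(5L, 6L, 7L)) {
    pts <- binarize(equalize_histogram(cascade_field("M4", n = n)), 0.4)
    h <- pair_distance_histogram(pts, bin_width = 1e-3)
    cv <- debye_intensity(h, q_log_grid(1, 2^-n))
    fr <- c(2 * 2 * pi, pi * 2^n)
    D <- fit_power_law_exponent(cv, fr)$D
    lp <- log_periodicity_analysis(cv, D, q_range = fr)
    expect_gte(lp$beta, 0.45)
    expect_lte(lp$beta, 0.55)
    n_min <- c(n_min, lp$n_minima)
  }
  expect_true(all(diff(n_min) >= 0))
  expect_gt(n_min[3], n_min[1])
})

test_that("featureless power laws yield no accepted minima", {
  q <- q_log_grid(1, 1 / 64)
  synth <- tibble::tibble(q = q, I = q^-1.8, S = q^-1.8)
  class(synth) <- c("sas_curve", class(synth))
  lp <- log_periodicity_analysis(synth, 1.8)
  expect_equal(lp$n_minima, 0L)
  expect_true(is.na(lp$beta))
  expect_equal(glance(lp)$n_minima, 0L)
})

test_that("the pddf is a density with the square's signature shape", {
  u <- uniform_square_points(1e4, seed = 1)
  h <- pair_distance_histogram(u, bin_width = 1 / 200)
  p <- pddf(h)
  expect_equal(sum(p$p) * attr(p, "bin_width"), 1)
  expect_equal(attr(p, "mode_r"), 0.5, tolerance = 0.05)
  expect_equal(attr(p, "r_support"), sqrt(2), tolerance = 0.03)
})
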