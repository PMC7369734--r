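test_that("cgr_map follows the half-distance rule from the square center", {
  pts <- cgr_map("CGT")
  # frozen from direct iteration: center (1/4, 1/4), C=(0,1/2), G=(1/2,1/2),
  # T=(1/2,0)
  expect_equal(pts$x, c(0.125, 0.3125, 0.40625))
  expect_equal(pts$y, c(0.375, 0.4375, 0.21875))
})

test_that("cgr_map agrees with an independent loop on random sequences", {
  lay <- vertex_layout()
  vx <- setNames(lay$vx, lay$base)
  vy <- setNames(lay$vy, lay$base)
  for (seed in 1:3) {
    s <- generate_random_sequence(500, seed = seed)
    pts <- cgr_map(s)
    oracle <- cgr_loop(s$bases, vx, vy, 0.25, 0.25)
    expect_equal(pts$x, oracle[, 1], tolerance = 1e-12)
    expect_equal(pts$y, oracle[, 2], tolerance = 1e-12)
    expect_equal(nrow(pts), 500L)
  }
})

test_that("repeated bases converge to the base vertex", {
  pts <- cgr_map(strrep("A", 30))
  d <- sqrt(pts$x^2 + pts$y^2)  # A sits at the origin
  expect_true(all(diff(d) < 0)) # monotone approach
  expect_lt(tail(d, 1), 1e-8)
})

test_that("cgr_map is invertible from the point quadrants", {
  lay <- vertex_layout()
  s <- generate_random_sequence(2000, seed = 8)
  pts <- cgr_map(s)
  # each point lies in the quadrant of its base's vertex
  vert_idx <- apply(as.matrix(pts), 1, function(p) {
    which.min((lay$vx - p[1])^2 + (lay$vy - p[2])^2)
  })
  decoded <- paste(lay$base[vert_idx], collapse = "")
  expect_equal(decoded, s$bases)
  expect_equal(cgr_map(decoded)$x, pts$x)
})

test_that("cgr_map rejects bases missing from the layout", {
  expect_error(cgr_map("ACGN"), "without a vertex")
})

test_that("chaos game points stay inside the unit square", {
  att <- chaos_game_attractor(square_ifs_maps(), n_points = 5000, seed = 1)
  expect_equal(nrow(att), 5000L)
  expect_true(all(att$x >= 0 & att$x <= 1 & att$y >= 0 & att$y <= 1))
  expect_error(chaos_game_attractor(square_ifs_maps(),
                                    probabilities = c(1, 1, 1, 1),
                                    n_points = 10, seed = 1),
               "sum to 1")
})

test_that("full-square chaos game is monofractal with dimension 2", {
  att <- chaos_game_attractor(square_ifs_maps(), n_points = 1e5, seed = 4)
  g <- rasterize(att, 256L)
  sp <- generalized_dimensions(g, box_config(s_grid = c(-2, -1, 0, 1, 2)))
  expect_true(all(abs(sp$D - 2) < 0.1))
})

test_that("three-map chaos game recovers the gasket dimension", {
  # oracle: the scaling relation k * beta^D = 1 with k = 3, beta = 1/2
  d_expect <- dimension_from_scaling(3, 0.5)
  att <- chaos_game_attractor(square_ifs_maps(1:3), n_points = 1e5, seed = 4)
  g <- rasterize(att, 256L)
  d0 <- generalized_dimensions(g, box_config(s_grid = 0))$D
  expect_equal(d0, d_expect, tolerance = 0.05)
})

test_that("rasterize conserves counts and normalizes to a probability", {
  centre <- make_points(0.25, 0.25, edge = 0.5)
  g <- rasterize(centre, 2L)
  expect_equal(sum(g$values), 1)
  expect_equal(sum(g$values > 0), 1L)

  u <- uniform_square_points(1e5, seed = 6)
  g8 <- rasterize(u, 8L)
  expect_equal(sum(g8$values), 1e5)
  mu <- 1e5 / 64
  sdv <- sqrt(1e5 * (1 / 64) * (63 / 64))
  expect_true(all(abs(g8$values - mu) < 4 * sdv))
  p <- normalize_grid(g8)
  expect_equal(sum(p$values), 1)
  expect_error(rasterize(make_points(1.5, 0.2, edge = 1)), "outside")
})

test_that("grids and point sets survive text round trips", {
  g <- cascade_field("M5", n = 4)
  f <- withr::local_tempfile(fileext = ".txt")
  write_grid_text(g, f)
  back <- read_grid_text(f, cell_size = g$cell_size, mode = "probability")
  expect_equal(back$values, g$values)

  pts <- uniform_square_points(50, seed = 1)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_points_tsv(pts, tf)
  back_pts <- read_points_tsv(tf, edge = 1)
  expect_equal(back_pts$x, pts$x)
})
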