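#' Vertex layout of the ACGT square
#'
#' The default layout places the four bases at the corners of an
#' axis-aligned square of edge 1/2: A = (0, 0), T = (1/2, 0),
#' G = (1/2, 1/2), C = (0, 1/2). Other CGR conventions (e.g. a unit square
#' or a different corner order) are supported by overriding the arguments.
#'
#' @param edge Square edge length (default 1/2).
#' @param order Bases assigned counter-clockwise from the bottom-left
#'   corner; default `c("A", "T", "G", "C")`.
#' @return A tibble with columns `base`, `vx`, `vy` and an `edge` attribute.
#' @export
vertex_layout <- function(edge = 0.5, order = c("A", "T", "G", "C")) {
  stopifnot(edge > 0, setequal(order, c("A", "C", "G", "T")))
  corners <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE) * edge
  out <- tibble::tibble(base = order, vx = corners[, 1], vy = corners[, 2])
  attr(out, "edge") <- edge
  out
}

layout_edge <- function(layout) attr(layout, "edge") %||% max(layout$vx)

new_point_set <- function(x, y, edge, label) {
  out <- tibble::tibble(x = x, y = y)
  class(out) <- c("cgr_points", class(out))
  attr(out, "edge") <- edge
  attr(out, "label") <- label
  out
}

#' Chaos game representation of a DNA sequence
#'
#' Deterministic CGR: starting from the center of the ACGT square, the point
#' for base k is placed at the fraction `ratio` (default one half) of the way
#' from the previous point to the vertex of base k. The map is one-to-one
#' with the sequence: the output has exactly one point per base, in order.
#'
#' @param sequence A one-row sequence tibble (from [read_fasta()] or the
#'   generators) or a plain character string of bases.
#' @param layout A [vertex_layout()].
#' @param ratio Contraction ratio toward the vertex (default 0.5, the
#'   classical half-distance rule).
#' @return A `cgr_points` tibble with columns `x`, `y` (square-edge units)
#'   and attributes `edge` and `label`.
#' @export
#' @examples
#' cgr_map("CGT")
cgr_map <- function(sequence, layout = vertex_layout(), ratio = 0.5) {
  if (is.data.frame(sequence)) {
    stopifnot(nrow(sequence) == 1L)
    label <- sequence$id
    bases <- sequence$bases
  } else {
    label <- "sequence"
    bases <- sequence
  }
  stopifnot(nchar(bases) >= 1L)
  b <- strsplit(toupper(bases), "")[[1]]
  idx <- match(b, layout$base)
  if (anyNA(idx)) {
    stop("base(s) without a vertex in layout: ",
         paste(unique(b[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  edge <- layout_edge(layout)
  x0 <- mean(range(layout$vx))
  y0 <- mean(range(layout$vy))
  # x_k = (1 - ratio) x_{k-1} + ratio v_k: a linear recurrence, run through
  # the recursive filter rather than an R-level loop
  xs <- as.numeric(stats::filter(ratio * layout$vx[idx], 1 - ratio,
                                 method = "recursive", init = x0))
  ys <- as.numeric(stats::filter(ratio * layout$vy[idx], 1 - ratio,
                                 method = "recursive", init = y0))
  new_point_set(xs, ys, edge, label)
}

#' Affine contraction maps for the chaos game
#'
#' Builds the tibble of 2D affine maps `w(x, y) = (a x + b y + e,
#' c x + d y + f)`. The four standard maps that render a uniformly filled
#' unit square have `a = d = 1/2`, `b = c = 0` and translations
#' `(e, f)` in `{0, 1/2}^2`.
#'
#' @param a,b,c,d Matrix coefficients, recycled to a common length.
#' @param e,f Translation offsets in square-edge units.
#' @return A tibble with one row per map.
#' @export
affine_maps <- function(a = 0.5, b = 0, c = 0, d = 0.5,
                        e = c(0, 0, 0.5, 0.5), f = c(0, 0.5, 0, 0.5)) {
  out <- tibble::tibble(a = a, b = b, c = c, d = d, e = e, f = f)
  # contraction check on the operator scale of each map
  s <- pmax(abs(out$a) + abs(out$b), abs(out$c) + abs(out$d))
  if (any(s >= 1)) stop("all maps must be contractions", call. = FALSE)
  out
}

#' The four affine maps of the uniformly-filled unit square
#'
#' Each map halves toward one corner of the unit square; played with equal
#' probabilities the chaos game fills the square uniformly. Dropping one map
#' yields a Sierpinski gasket (box-counting dimension `log2(3)`).
#'
#' @param keep Indices of maps to keep (default all four).
#' @return An [affine_maps()] tibble.
#' @export
square_ifs_maps <- function(keep = 1:4) affine_maps()[keep, ]

#' Render an IFS attractor by the random iteration algorithm
#'
#' At each step a map is chosen at random with the given probabilities and
#' applied to the current point; after discarding `burn_in` initial points
#' the orbit approximates the attractor of the IFS.
#'
#' @param maps An [affine_maps()] tibble.
#' @param probabilities Per-map weights, positive, summing to 1. Default
#'   equal weights.
#' @param n_points Number of points to return.
#' @param seed Integer seed.
#' @param burn_in Initial points discarded (default 100).
#' @param x0,y0 Starting point (default the fixed point region center 0.5,
#'   0.5).
#' @return A `cgr_points` tibble of `n_points` points.
#' @export
chaos_game_attractor <- function(maps, probabilities = NULL, n_points,
                                 seed, burn_in = 100L,
                                 x0 = 0.5, y0 = 0.5) {
  n_maps <- nrow(maps)
  if (n_maps == 0L) stop("at least one map is required", call. = FALSE)
  if (is.null(probabilities)) probabilities <- rep(1 / n_maps, n_maps)
  stopifnot(length(probabilities) == n_maps)
  if (any(probabilities <= 0) || abs(sum(probabilities) - 1) > 1e-8) {
    stop("probabilities must be positive and sum to 1", call. = FALSE)
  }
  n_points <- as.integer(n_points)
  stopifnot(n_points >= 1L)
  total <- n_points + as.integer(burn_in)
  pick <- withr::with_seed(seed,
    sample.int(n_maps, total, replace = TRUE, prob = probabilities))
  pts <- chaos_game_orbit(
    as.numeric(maps$a), as.numeric(maps$b), as.numeric(maps$c),
    as.numeric(maps$d), as.numeric(maps$e), as.numeric(maps$f),
    pick, x0, y0)
  keep <- seq.int(as.integer(burn_in) + 1L, total)
  new_point_set(pts[keep, 1], pts[keep, 2], edge = 1, label = "attractor")
}

#' Rasterize a point set to a counts grid
#'
#' Partitions the square into `grid_size` x `grid_size` half-open cells
#' (points on the top/right boundary are assigned to the last cell) and
#' counts points per cell. Row 1 of the matrix is the bottom of the square
#' (y-up convention).
#'
#' @param points A `cgr_points` tibble (or any tibble with `x`, `y` and an
#'   `edge` attribute; `edge` defaults to the max coordinate extent).
#' @param grid_size Number of cells per side (>= 2); default 360, a
#'   convenient working resolution for CGR images.
#' @return A [measure_grid()] in counts mode.
#' @export
rasterize <- function(points, grid_size = 360L) {
  grid_size <- as.integer(grid_size)
  stopifnot(grid_size >= 2L)
  edge <- attr(points, "edge") %||% max(points$x, points$y)
  if (any(points$x < 0 | points$x > edge | points$y < 0 | points$y > edge)) {
    stop("points outside the [0, edge] square", call. = FALSE)
  }
  delta <- edge / grid_size
  ix <- pmin(grid_size - 1L, floor(points$x / delta)) + 1L
  iy <- pmin(grid_size - 1L, floor(points$y / delta)) + 1L
  counts <- tabulate((ix - 1L) * grid_size + iy, nbins = grid_size^2)
  m <- matrix(counts, nrow = grid_size, ncol = grid_size)
  measure_grid(m, cell_size = delta, mode = "counts")
}

#' Construct a measure grid
#'
#' A square nonnegative field: either raw point counts or a probability
#' measure (values summing to 1). Row 1 is the bottom of the square.
#'
#' @param values A square numeric matrix with nonnegative entries.
#' @param cell_size Physical cell size in square-edge units.
#' @param mode `"counts"` or `"probability"`.
#' @return A `measure_grid` object.
#' @export
measure_grid <- function(values, cell_size = 1 / nrow(values),
                         mode = c("counts", "probability")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            all(values >= 0))
  if (mode == "probability" && abs(sum(values) - 1) > 1e-8) {
    stop("probability-mode grid must sum to 1", call. = FALSE)
  }
  structure(list(values = values, cell_size = cell_size, mode = mode),
            class = "measure_grid")
}

#' @export
print.measure_grid <- function(x, ...) {
  cat(sprintf("<measure_grid %dx%d, mode=%s, cell=%g, sum=%g>\n",
              nrow(x$values), ncol(x$values), x$mode, x$cell_size,
              sum(x$values)))
  invisible(x)
}

#' @export
dim.measure_grid <- function(x) dim(x$values)

#' Normalize a measure grid to a probability measure
#'
#' @param grid A [measure_grid()].
#' @return The grid with values summing to 1, in probability mode.
#' @export
normalize_grid <- function(grid) {
  total <- sum(grid$values)
  if (total <= 0) stop("cannot normalize an all-zero grid", call. = FALSE)
  measure_grid(grid$values / total, grid$cell_size, "probability")
}

#' @describeIn measure_grid Long-form tibble view (`row`, `col`, `x`, `y`,
#'   `value`), with `x`, `y` the cell centers.
#' @param x A `measure_grid`.
#' @param ... Unused.
#' @export
as_tibble.measure_grid <- function(x, ...) {
  m <- nrow(x$values)
  tibble::tibble(
    row = rep(seq_len(m), times = m),
    col = rep(seq_len(m), each = m),
    x = (rep(seq_len(m), each = m) - 0.5) * x$cell_size,
    y = (rep(seq_len(m), times = m) - 0.5) * x$cell_size,
    value = as.vector(x$values)
  )
}

#' Write a measure grid as a plain-text matrix
#'
#' Rows are written top-down so the text file reads like the image.
#'
#' @param grid A [measure_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_text <- function(grid, path) {
  utils::write.table(grid$values[rev(seq_len(nrow(grid$values))), ],
                     path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a plain-text measure grid written by [write_grid_text()]
#'
#' @param path Input path.
#' @param cell_size Physical cell size; default `1/M` for an `M` x `M` file.
#' @param mode Grid mode.
#' @return A [measure_grid()].
#' @export
read_grid_text <- function(path, cell_size = NULL,
                           mode = c("counts", "probability")) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  measure_grid(m, cell_size %||% 1 / nrow(m), match.arg(mode))
}

#' Write a measure grid as a grayscale PNG
#'
#' Values are min-max rescaled and inverted (ink convention): dense cells
#' render dark on a white background, like a plotted CGR.
#'
#' @param grid A [measure_grid()].
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_grid_png <- function(grid, path) {
  v <- grid$values
  rng <- range(v)
  img <- if (diff(rng) > 0) 1 - (v - rng[1]) / diff(rng) else v * 0 + 1
  # PNG rows run top-down; our row 1 is the square bottom
  png::writePNG(t(img)[rev(seq_len(ncol(img))), , drop = FALSE], path)
  invisible(path)
}

#' Write a point set as two-column TSV
#'
#' @param points A `cgr_points` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_points_tsv <- function(points, path) {
  utils::write.table(points[, c("x", "y")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a two-column point-set TSV
#'
#' @param path Input path.
#' @param edge Square edge length the coordinates live in (default the
#'   smallest power-of-two-free bound: the max coordinate).
#' @return A `cgr_points` tibble.
#' @export
read_points_tsv <- function(path, edge = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  new_point_set(d$x, d$y, edge %||% max(d$x, d$y), basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
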