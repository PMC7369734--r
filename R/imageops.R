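#' Pixel-level histogram of a grayscale field
#'
#' Converts the measure to grayscale pixel levels and counts cells per
#' level bin. The grayscale follows the ink convention of CGR images
#' (structure drawn dark on a white background): values are min-max
#' rescaled to `[0, 1]` and inverted, so level 0 is the densest cell and
#' level 1 the emptiest. Cascade fields concentrate almost all cells at
#' high (near-white) levels, which is what makes direct thresholding
#' impracticable before equalization. A constant grid puts all mass in a
#' single bin.
#'
#' @param grid A [measure_grid()].
#' @param n_levels Number of level bins (default 256, the 8-bit image
#'   convention).
#' @return A tibble with columns `level` (bin center in `[0, 1]`) and
#'   `count`; counts sum to the number of cells.
#' @export
pixel_histogram <- function(grid, n_levels = 256L) {
  n_levels <- as.integer(n_levels)
  stopifnot(n_levels >= 2L)
  v <- ink_levels(grid$values)
  lev <- quantize_levels(v, n_levels)
  counts <- tabulate(lev + 1L, nbins = n_levels)
  tibble::tibble(
    level = (seq_len(n_levels) - 0.5) / n_levels,
    count = counts
  )
}

rescale01 <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) v * 0 else (v - rng[1]) / diff(rng)
}

# grayscale with dense cells dark: level 0 = max measure, 1 = min
ink_levels <- function(v) 1 - rescale01(v)

quantize_levels <- function(v01, n_levels) {
  pmin(n_levels - 1L, as.integer(floor(v01 * n_levels)))
}

#' Histogram equalization of a grayscale field
#'
#' Standard cumulative-distribution level remapping on `n_levels` quantized
#' levels: cell values are converted to grayscale (ink convention, dense =
#' dark; see [pixel_histogram()]), quantized, and each level is mapped to
#' its (shifted) cumulative frequency so the output spans the full range
#' from 0 (black) to 1 (white). The remapping is monotone, so the ordering
#' of cells by grayscale level is preserved and ties stay tied.
#'
#' @param grid A [measure_grid()].
#' @param n_levels Quantization depth (default 256).
#' @param convention `"measure"` (default) when the grid holds raw measure
#'   values, which are first converted to ink levels; `"grayscale"` when
#'   the grid already holds pixel levels in `[0, 1]` (e.g. the output of a
#'   previous equalization), which are only min-max rescaled.
#' @return A [measure_grid()] in counts mode with values in `[0, 1]`
#'   (grayscale levels, dark = dense).
#' @export
equalize_histogram <- function(grid, n_levels = 256L,
                               convention = c("measure", "grayscale")) {
  convention <- match.arg(convention)
  n_levels <- as.integer(n_levels)
  stopifnot(n_levels >= 2L)
  v01 <- if (convention == "measure") ink_levels(grid$values)
         else rescale01(grid$values)
  lev <- quantize_levels(v01, n_levels)
  counts <- tabulate(lev + 1L, nbins = n_levels)
  cdf <- cumsum(counts)
  cdf_min <- min(cdf[counts > 0])
  denom <- length(v01) - cdf_min
  mapped <- if (denom > 0) (cdf - cdf_min) / denom else rep(1, n_levels)
  out <- matrix(mapped[lev + 1L], nrow = nrow(grid$values))
  measure_grid(out, grid$cell_size, "counts")
}

#' Binarize an equalized field into an occupied-cell point set
#'
#' Thresholding of an equalized grayscale field: the centers of all cells
#' whose level is on the selected side of the threshold become points.
#' With the default direction (`"<="`) occupied cells are the dark ones —
#' under the ink convention the high-measure cells carrying the structure
#' — and the occupied-set size is non-decreasing in `t`. Direction `">="`
#' selects the bright (low-measure) cells instead, i.e. the complementary
#' structure.
#'
#' @param grid A [measure_grid()] with values in `[0, 1]` (see
#'   [equalize_histogram()]).
#' @param t Threshold in `[0, 1]`.
#' @param direction `"<="` (default) or `">="`.
#' @return A `cgr_points` tibble of occupied-cell centers, with the number
#'   of cells as attribute `k`.
#' @export
binarize <- function(grid, t, direction = c("<=", ">=")) {
  direction <- match.arg(direction)
  if (t < 0 || t > 1) stop("threshold must lie in [0, 1]", call. = FALSE)
  v <- grid$values
  if (any(v < 0 | v > 1)) {
    stop("grid values outside [0, 1]; equalize or rescale first",
         call. = FALSE)
  }
  occ <- if (direction == "<=") v <= t else v >= t
  m <- nrow(v)
  idx <- which(occ, arr.ind = TRUE)
  pts <- new_point_set(
    x = (idx[, "col"] - 0.5) * grid$cell_size,
    y = (idx[, "row"] - 0.5) * grid$cell_size,
    edge = m * grid$cell_size,
    label = sprintf("binarized t=%g", t)
  )
  attr(pts, "k") <- nrow(pts)
  pts
}
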