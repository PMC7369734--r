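#' Pair-distance histogram of a point set
#'
#' Bins all `N(N-1)/2` unordered pair distances of a planar point set. The
#' binning is streamed in compiled code, so memory stays proportional to
#' the number of bins regardless of `N`. Bin width defaults to `l/1000`
#' (with `l` the square edge), fine enough that the binned Debye sum
#' tracks the exact pair double-sum in the scattering regimes of interest.
#'
#' @param points A `cgr_points` tibble (columns `x`, `y`; attribute `edge`).
#' @param bin_width Histogram bin width in square-edge units.
#' @return A `pair_hist` tibble with columns `r` (bin centers) and `g`
#'   (counts), and attributes `n_points`, `bin_width`, `edge`.
#' @export
pair_distance_histogram <- function(points,
                                    bin_width = layout_edge_of(points) / 1000) {
  n <- nrow(points)
  if (n < 2L) stop("at least 2 points are required", call. = FALSE)
  stopifnot(bin_width > 0)
  edge <- layout_edge_of(points)
  r_max <- sqrt(2) * edge
  n_bins <- max(1L, as.integer(ceiling(r_max / bin_width)))
  g <- pair_distance_counts(as.numeric(points$x), as.numeric(points$y),
                            bin_width, n_bins)
  out <- tibble::tibble(r = (seq_len(n_bins) - 0.5) * bin_width, g = g)
  class(out) <- c("pair_hist", class(out))
  attr(out, "n_points") <- n
  attr(out, "bin_width") <- bin_width
  attr(out, "edge") <- edge
  out
}

layout_edge_of <- function(points) {
  attr(points, "edge") %||% max(points$x, points$y)
}

#' Logarithmic scattering-vector grid
#'
#' Log-spaced `q` values spanning all three structure-factor regimes:
#' from well inside the Guinier region (`0.2 * 2*pi/l`) to well past the
#' fractal/asymptotic crossover (`20 * 2*pi/l0`).
#'
#' @param l Overall structure size (square edge).
#' @param l0 Smallest feature size (pixel/cell size).
#' @param n Number of grid points (default 256).
#' @return A numeric vector of `q` values (units 1/l).
#' @export
q_log_grid <- function(l, l0, n = 256L) {
  stopifnot(l > 0, l0 > 0, l0 < l, n >= 2L)
  exp(seq(log(0.2 * 2 * pi / l), log(20 * 2 * pi / l0), length.out = n))
}

#' Debye scattering intensity from a pair-distance histogram
#'
#' Orientationally averaged intensity of `N` identical point scatterers,
#' `I(q) = N + 2 * sum_i g(r_i) sin(q r_i) / (q r_i)` over histogram bin
#' centers, with `sin(x)/x -> 1` as `x -> 0`. `I(0) = N^2` exactly, and
#' the normalized structure factor `S(q) = I(q)/I(0)` starts at 1. The 3D
#' orientational average `sin(qr)/(qr)` is used for the planar point sets,
#' corresponding to free rotation of the square in three dimensions.
#'
#' @param hist A [pair_distance_histogram()].
#' @param q_grid Scattering-vector magnitudes (>= 0); see [q_log_grid()].
#' @return A `sas_curve` tibble with columns `q`, `I`, `S` and attribute
#'   `n_points`.
#' @export
debye_intensity <- function(hist, q_grid) {
  if (length(q_grid) == 0L) stop("empty q grid", call. = FALSE)
  stopifnot(all(q_grid >= 0))
  n <- attr(hist, "n_points")
  keep <- hist$g > 0
  r <- hist$r[keep]
  g <- hist$g[keep]
  I <- vapply(q_grid, function(q) {
    x <- q * r
    sinc <- ifelse(x == 0, 1, sin(x) / x)
    n + 2 * sum(g * sinc)
  }, numeric(1))
  out <- tibble::tibble(q = q_grid, I = I, S = I / n^2)
  class(out) <- c("sas_curve", class(out))
  attr(out, "n_points") <- n
  out
}

#' Locate the three structure-factor regimes
#'
#' For a mass fractal of overall size `l` built from features of size
#' `l0`, `S(q)` is flat in the Guinier region `q l < 2*pi`, decays as a
#' power law `q^-D` in the fractal region `2*pi < q l < 2*pi l/l0`, and
#' levels off near `1/k` (with `k` the number of scatterers) in the
#' asymptotic region. This reports the two boundary estimates and the
#' measured high-`q` plateau, inverted into an estimate of `k`.
#'
#' @param curve A `sas_curve`.
#' @param l Overall size.
#' @param l0 Smallest feature size.
#' @param plateau_factor Plateau is measured as the median of `S` at
#'   `q >= plateau_factor * 2*pi/l0` (default 2).
#' @return A one-row tibble: `q_guinier_fractal`, `q_fractal_asymptotic`,
#'   `plateau`, `k_estimate`.
#' @export
detect_regimes <- function(curve, l, l0, plateau_factor = 2) {
  q1 <- 2 * pi / l
  q2 <- 2 * pi / l0
  if (min(curve$q) > q1 || max(curve$q) < q2) {
    stop("q grid does not span both regime boundaries", call. = FALSE)
  }
  hi <- curve$S[curve$q >= plateau_factor * q2]
  if (length(hi) < 3L) hi <- tail(curve$S, 3L)
  plateau <- median(hi)
  tibble::tibble(
    q_guinier_fractal = q1,
    q_fractal_asymptotic = q2,
    plateau = plateau,
    k_estimate = 1 / plateau
  )
}

#' Fit the power-law exponent of the fractal region
#'
#' Least-squares fit of `log S` against `log q` over a `q` interval; the
#' negated slope estimates the mass-fractal dimension `D`. Non-positive
#' `S` values in the range (possible for a finite point set, since the
#' Debye sum is not pointwise nonnegative) are excluded with a warning.
#'
#' @param curve A `sas_curve`.
#' @param q_range Length-2 numeric interval.
#' @return A `powerlaw_fit` object (see [tidy.powerlaw_fit()]).
#' @export
fit_power_law_exponent <- function(curve, q_range) {
  stopifnot(length(q_range) == 2L)
  sel <- curve$q >= min(q_range) & curve$q <= max(q_range)
  d <- curve[sel, ]
  if (any(d$S <= 0)) {
    warning("excluding ", sum(d$S <= 0),
            " non-positive S value(s) from the power-law fit")
    d <- d[d$S > 0, ]
  }
  if (nrow(d) < 5L) {
    stop("fewer than 5 usable q points in the fit range", call. = FALSE)
  }
  fit <- lm(log(S) ~ log(q), data = d)
  y <- log(d$S)
  r2 <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
  structure(
    list(D = -coef(fit)[[2]], intercept = coef(fit)[[1]],
         r_squared = r2, n_used = nrow(d), q_range = range(d$q), fit = fit),
    class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit D=%.4f (R^2=%.4f, %d points, q in [%.3g, %.3g])>\n",
              x$D, x$r_squared, x$n_used, x$q_range[1], x$q_range[2]))
  invisible(x)
}

#' Tidy a fractal-region power-law fit
#'
#' @param x A `powerlaw_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per regression term; `glance()`: a one-row
#'   summary with the fitted exponent `D`, `r_squared`, `n_used` and the
#'   fitted `q` range.
#' @export
tidy.powerlaw_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, 1],
                 std_error = cf[, 2])
}

#' @rdname tidy.powerlaw_fit
#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble::tibble(D = x$D, r_squared = x$r_squared, n_used = x$n_used,
                 q_min = x$q_range[1], q_max = x$q_range[2])
}

#' Log-periodicity of the compensated scattering curve
#'
#' Deterministic fractals imprint a log-periodic modulation on the fractal
#' region of `S(q)`: after compensating the power law, `q^D S(q)` shows
#' minima evenly spaced on the logarithmic `q` axis, with period equal to
#' the inverse scaling factor. This smooths `log(q^D S)` (Savitzky-Golay
#' on the log-`q` axis), detects local minima above a prominence floor,
#' and reports the scaling factor `beta` as the inverse geometric mean of
#' successive minima-position ratios, together with the number of accepted
#' minima (an estimate of the iteration depth). Absence of periodicity is
#' a valid result: zero or one minima give `beta = NA`.
#'
#' @param curve A `sas_curve`, ideally restricted to the fractal region.
#' @param D Power-law exponent used for compensation.
#' @param q_range Optional length-2 interval to restrict to (e.g. the
#'   fractal region); default the whole curve.
#' @param prominence Minimum prominence of a minimum, as a fraction of the
#'   range of the smoothed compensated curve (default 0.05), with an
#'   absolute floor of 0.01 decades so that numerically flat curves yield
#'   no minima.
#' @param smooth_window Odd Savitzky-Golay window length; by default sized
#'   to span about a quarter decade of `q` at the curve's grid density,
#'   which suppresses the fine sinc oscillations of individual pair
#'   distances while leaving the (factor-`1/beta`-spaced) structural
#'   minima intact.
#' @return A `logperiod` list: `beta`, `n_minima`, `minima` (tibble of
#'   positions), `prominence`, `compensated` (tibble of `q`, `y`,
#'   `y_smooth`).
#' @export
log_periodicity_analysis <- function(curve, D, q_range = NULL,
                                     prominence = 0.05,
                                     smooth_window = NULL) {
  d <- curve
  if (!is.null(q_range)) {
    d <- d[d$q >= min(q_range) & d$q <= max(q_range), ]
  }
  d <- d[d$S > 0, ]
  y <- log10(d$q^D * d$S)
  if (is.null(smooth_window)) {
    pts_per_decade <- (nrow(d) - 1) / diff(range(log10(d$q)))
    smooth_window <- max(5L, as.integer(round(0.25 * pts_per_decade)))
  }
  smooth_window <- as.integer(smooth_window)
  if (smooth_window %% 2L == 0L) smooth_window <- smooth_window + 1L
  ys <- if (nrow(d) > smooth_window + 2L) {
    signal::sgolayfilt(y, p = 3, n = smooth_window)
  } else {
    y
  }
  mins <- find_prominent_minima(ys, prominence)
  minima <- tibble::tibble(q = d$q[mins$idx], y = ys[mins$idx],
                           prominence = mins$prom)
  beta <- if (nrow(minima) >= 2L) {
    1 / exp(mean(diff(log(minima$q))))
  } else {
    NA_real_
  }
  structure(
    list(beta = beta, n_minima = nrow(minima), minima = minima,
         prominence = prominence,
         compensated = tibble::tibble(q = d$q, y = y, y_smooth = ys)),
    class = "logperiod")
}

# Local minima of y with prominence above max(frac * range(y), 0.01).
# Prominence is measured against the local brackets: the highest value
# between this minimum and the adjacent candidate minima (or the range
# ends), so a shallow wiggle between two deep minima scores low even if
# the curve has tall peaks elsewhere.
find_prominent_minima <- function(y, frac) {
  n <- length(y)
  if (n < 3L) return(list(idx = integer(0), prom = numeric(0)))
  cand <- which(vapply(2:(n - 1), function(i) {
    y[i] <= y[i - 1] && y[i] <= y[i + 1] &&
      (y[i] < y[i - 1] || y[i] < y[i + 1])
  }, logical(1))) + 1L
  if (length(cand) == 0L) return(list(idx = integer(0), prom = numeric(0)))
  floor_prom <- max(frac * diff(range(y)), 0.01)
  bounds <- c(1L, cand, n)
  prom <- vapply(seq_along(cand), function(j) {
    i <- cand[j]
    left_peak <- max(y[bounds[j]:i])
    right_peak <- max(y[i:bounds[j + 2L]])
    min(left_peak, right_peak) - y[i]
  }, numeric(1))
  keep <- prom >= floor_prom
  list(idx = cand[keep], prom = prom[keep])
}

#' @export
print.logperiod <- function(x, ...) {
  cat(sprintf("<logperiod beta=%s, %d minima (prominence >= %g of range)>\n",
              ifelse(is.na(x$beta), "NA", sprintf("%.4f", x$beta)),
              x$n_minima, x$prominence))
  invisible(x)
}

#' @describeIn log_periodicity_analysis One-row tibble with `beta` and
#'   `n_minima`.
#' @param x A `logperiod` object.
#' @param ... Unused.
#' @export
glance.logperiod <- function(x, ...) {
  tibble::tibble(beta = x$beta, n_minima = x$n_minima)
}

#' Pair-distance distribution function
#'
#' Normalizes a pair-distance histogram to a probability density:
#' `p(r_i) = g(r_i) / (sum(g) * bin_width)`, so `sum p(r) dr = 1`. For
#' points in a square of edge `l`, the density peaks near `r/l = 0.5` and
#' its support ends at the diagonal `r/l = sqrt(2)`.
#'
#' @param hist A [pair_distance_histogram()].
#' @return A `pddf_tbl` tibble with columns `r` and `p`, and attributes
#'   `mode_r` (bin center of the maximum) and `r_support` (largest bin
#'   center with a nonzero count).
#' @export
pddf <- function(hist) {
  bw <- attr(hist, "bin_width")
  p <- hist$g / (sum(hist$g) * bw)
  out <- tibble::tibble(r = hist$r, p = p)
  class(out) <- c("pddf_tbl", class(out))
  attr(out, "bin_width") <- bw
  attr(out, "edge") <- attr(hist, "edge")
  attr(out, "mode_r") <- out$r[which.max(out$p)]
  attr(out, "r_support") <- max(out$r[hist$g > 0])
  out
}

#' Plot a scattering curve
#'
#' @param object A `sas_curve`.
#' @param compensate Optional exponent `D`; if given, plots `q^D S(q)`
#'   instead of `S(q)`.
#' @param ... Unused.
#' @return A ggplot object (log-log axes).
#' @export
autoplot.sas_curve <- function(object, compensate = NULL, ...) {
  d <- object[object$S > 0, ]
  if (is.null(compensate)) {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$q, y = .data$S)) +
      ggplot2::geom_line() +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::labs(x = "q", y = "S(q)")
  } else {
    d$y <- d$q^compensate * d$S
    ggplot2::ggplot(d, ggplot2::aes(x = .data$q, y = .data$y)) +
      ggplot2::geom_line() +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::labs(x = "q", y = sprintf("q^%.2g S(q)", compensate))
  }
}

#' Plot a pair-distance distribution function
#'
#' @param object A `pddf_tbl`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pddf_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r", y = "p(r)")
}

#' Plot a measure grid as a raster image
#'
#' @param grid A [measure_grid()].
#' @param trans Value transformation for display (default `"sqrt"`).
#' @return A ggplot object.
#' @export
plot_grid_raster <- function(grid, trans = "sqrt") {
  d <- as_tibble(grid)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_continuous(trans = trans) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y")
}

#' Plot a CGR point set
#'
#' @param points A `cgr_points` tibble.
#' @param size Point size (default 0.1).
#' @return A ggplot object.
#' @export
plot_points <- function(points, size = 0.1) {
  ggplot2::ggplot(points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = size) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y", title = attr(points, "label"))
}
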