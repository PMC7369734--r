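#' Box-counting configuration
#'
#' Controls the scales and exponents of the box-counting estimator. Box
#' sizes are dyadic aggregations of the measure grid (side `M, M/2, ...`
#' cells, stopping at `min_box` cells or when halving leaves the integers),
#' so box measures are exact block sums with no partial boxes. By default
#' the largest scale (one box, a degenerate regression point) and the two
#' smallest scales (discretization bias) are excluded from the fit, but
#' only while at least three scales remain.
#'
#' @param s_grid Exponent grid (default -10 to 10 in steps of 0.25).
#' @param min_box Smallest box side in cells (default 4).
#' @param drop_largest,drop_smallest Scales trimmed from the fit range
#'   (defaults 1 and 2).
#' @param min_count For counts-mode grids, boxes with fewer points are
#'   excluded (default 1, i.e. only empty boxes are excluded); guards
#'   negative exponents against sparsely-hit boundary boxes.
#' @return A list of class `box_config`.
#' @export
box_config <- function(s_grid = seq(-10, 10, 0.25), min_box = 4L,
                       drop_largest = 1L, drop_smallest = 2L,
                       min_count = 1L) {
  structure(list(s_grid = s_grid, min_box = as.integer(min_box),
                 drop_largest = as.integer(drop_largest),
                 drop_smallest = as.integer(drop_smallest),
                 min_count = as.integer(min_count)),
            class = "box_config")
}

dyadic_box_sizes <- function(M, min_box) {
  b <- M
  out <- integer(0)
  while (b >= min_box) {
    out <- c(out, b)
    if (b %% 2L != 0L) break
    b <- b %/% 2L
  }
  out
}

# exact block sums of an M x M matrix over b x b blocks (b divides M)
aggregate_blocks <- function(v, b) {
  k <- nrow(v) %/% b
  if (b == 1L) return(v)
  v2 <- rowsum(v, rep(seq_len(k), each = b))
  t(rowsum(t(v2), rep(seq_len(k), each = b)))
}

#' Partition function of a measure at one scale
#'
#' `Z(s, l) = sum_i p_i^s` over the boxes of side `l` with positive
#' aggregated measure `p_i`. `Z(1, l) = 1` for any probability measure and
#' `Z(0, l)` is the number of occupied boxes.
#'
#' @param measure A [measure_grid()]; normalized internally if in counts
#'   mode.
#' @param s Exponent.
#' @param box_cells Box side in grid cells (must divide the grid size).
#' @param min_count Minimum point count per box for counts-mode input.
#' @return The scalar Z value.
#' @export
partition_function <- function(measure, s, box_cells, min_count = 1L) {
  M <- nrow(measure$values)
  box_cells <- as.integer(box_cells)
  if (box_cells < 1L || M %% box_cells != 0L) {
    stop("box size must be a positive divisor of the grid size",
         call. = FALSE)
  }
  agg <- aggregate_blocks(measure$values, box_cells)
  keep <- if (measure$mode == "counts") agg >= min_count else agg > 0
  p <- agg[keep] / sum(measure$values)
  sum(p^s)
}

#' Box-counting estimate of the generalized-dimension spectrum
#'
#' For each exponent `s != 1`, `D_s` is the slope of `ln Z(s, l)` against
#' `ln l` over the fit range, divided by `(s - 1)`; `D_1` uses the entropy
#' sum `sum_i p_i ln p_i` against `ln l` (never interpolation across
#' `s = 1`). Per-exponent regression diagnostics (`r_squared`, number of
#' scales) are attached as columns.
#'
#' @param measure A [measure_grid()] (counts or probability mode).
#' @param config A [box_config()].
#' @return An `mf_spectrum` tibble with columns `s`, `D`, `tau`,
#'   `r_squared`, `n_scales`, and attributes `kind = "estimated"`,
#'   `fit_sizes` (box sides used, in cells).
#' @export
#' @examples
#' g <- cascade_field("M4", n = 6)
#' sp <- generalized_dimensions(g, box_config(s_grid = c(0, 2)))
#' sp$D  # both close to log2(3)
generalized_dimensions <- function(measure, config = box_config()) {
  M <- nrow(measure$values)
  sizes <- dyadic_box_sizes(M, config$min_box)
  fit_sizes <- trim_scales(sizes, config$drop_largest, config$drop_smallest)
  if (length(fit_sizes) < 3L) {
    stop("fewer than 3 box sizes in the fit range (grid too small)",
         call. = FALSE)
  }
  total <- sum(measure$values)
  log_l <- log(fit_sizes / M)
  # aggregated positive box measures at each fit scale
  p_at <- lapply(fit_sizes, function(b) {
    agg <- aggregate_blocks(measure$values, b)
    keep <- if (measure$mode == "counts") agg >= config$min_count else agg > 0
    agg[keep] / total
  })
  res <- purrr::map_dfr(config$s_grid, function(s) {
    y <- if (abs(s - 1) < 1e-12) {
      vapply(p_at, function(p) sum(p * log(p)), numeric(1))
    } else {
      vapply(p_at, function(p) log(sum(p^s)), numeric(1))
    }
    fit <- lm(y ~ log_l)
    slope <- coef(fit)[[2]]
    ssr <- sum(residuals(fit)^2)
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - ssr / sst else 1
    D <- if (abs(s - 1) < 1e-12) slope else slope / (s - 1)
    tibble::tibble(s = s, D = D, tau = (s - 1) * D,
                   r_squared = r2, n_scales = length(fit_sizes))
  })
  class(res) <- c("mf_spectrum", class(res))
  attr(res, "kind") <- "estimated"
  attr(res, "fit_sizes") <- fit_sizes
  res
}

trim_scales <- function(sizes, drop_largest, drop_smallest) {
  # relax the trims (smallest-side first) rather than dropping below 3 scales
  while (length(sizes) - drop_largest - drop_smallest < 3L &&
         (drop_largest > 0L || drop_smallest > 0L)) {
    if (drop_smallest > 0L) drop_smallest <- drop_smallest - 1L
    else drop_largest <- drop_largest - 1L
  }
  n <- length(sizes)
  sizes[seq.int(1L + drop_largest, n - drop_smallest)]
}

#' Legendre singularity spectrum from a dimension spectrum
#'
#' Fills `alpha(s) = d tau / d s` by central finite differences (one-sided
#' at the endpoints) and `f(alpha) = s * alpha - tau`. At `s = 0`,
#' `f(alpha)` equals the box-counting dimension `D_0`.
#'
#' @param spectrum An `mf_spectrum` tibble with `s` and `tau` columns.
#' @return The spectrum with `alpha` and `f` columns filled.
#' @export
legendre_spectrum <- function(spectrum) {
  s <- spectrum$s
  tau <- spectrum$tau
  n <- length(s)
  if (n < 3L) stop("s grid needs at least 3 points", call. = FALSE)
  alpha <- numeric(n)
  alpha[1] <- (tau[2] - tau[1]) / (s[2] - s[1])
  alpha[n] <- (tau[n] - tau[n - 1]) / (s[n] - s[n - 1])
  alpha[2:(n - 1)] <- (tau[3:n] - tau[1:(n - 2)]) / (s[3:n] - s[1:(n - 2)])
  spectrum$alpha <- alpha
  spectrum$f <- s * alpha - tau
  spectrum
}

#' Heterogeneity width of a multifractal spectrum
#'
#' Reports the extrema of the singularity strength `alpha` over the
#' evaluated exponent grid; a width of zero indicates a homogeneous
#' (mono)fractal. For analytic cascade spectra the exact `s -> +-Inf`
#' asymptotes (`-log2` of the largest / smallest nonzero cell fraction)
#' are reported alongside, since grid extrema always carry a
#' finite-`s` bias.
#'
#' @param spectrum An `mf_spectrum`; `alpha` is filled via
#'   [legendre_spectrum()] if absent.
#' @return A one-row tibble with `alpha_min`, `alpha_max`, `width`, and
#'   (when available) `alpha_min_inf`, `alpha_max_inf`.
#' @export
heterogeneity_width <- function(spectrum) {
  if (!"alpha" %in% names(spectrum)) spectrum <- legendre_spectrum(spectrum)
  out <- tibble::tibble(
    alpha_min = min(spectrum$alpha),
    alpha_max = max(spectrum$alpha),
    width = max(spectrum$alpha) - min(spectrum$alpha)
  )
  if (!is.null(attr(spectrum, "alpha_min_inf"))) {
    out$alpha_min_inf <- attr(spectrum, "alpha_min_inf")
    out$alpha_max_inf <- attr(spectrum, "alpha_max_inf")
  }
  out
}

#' Fractal dimension from a scaling relation
#'
#' Solves `sum_i k_i * beta_i^D = 1` for `D`: a fractal made of `k_i`
#' copies of itself scaled by `beta_i` at each iteration has this unique
#' dimension. With a single scaling factor the closed form is
#' `D = -log(k) / log(beta)`.
#'
#' @param k_list Copy counts (each >= 1).
#' @param beta_list Scaling factors in (0, 1), same length.
#' @return The dimension `D`, found by bracketed root search to 1e-10.
#' @export
#' @examples
#' dimension_from_scaling(3, 0.5)  # log2(3)
dimension_from_scaling <- function(k_list, beta_list) {
  stopifnot(length(k_list) == length(beta_list),
            all(k_list >= 1), all(beta_list > 0), all(beta_list < 1))
  g <- function(D) sum(k_list * beta_list^D) - 1
  if (g(0) < 0 || g(10) > 0) {
    stop("no root of the scaling relation in [0, 10]", call. = FALSE)
  }
  uniroot(g, c(0, 10), tol = 1e-10)$root
}

#' @export
print.mf_spectrum <- function(x, ...) {
  cat(sprintf("<mf_spectrum (%s), %d exponents in [%g, %g]>\n",
              attr(x, "kind") %||% "unknown", nrow(x), min(x$s), max(x$s)))
  NextMethod()
}

#' @describeIn generalized_dimensions One-row summary of a spectrum:
#'   `D0`, `D1`, `D2` (interpolated on the s grid) and the alpha width.
#' @param x An `mf_spectrum`.
#' @param ... Unused.
#' @export
glance.mf_spectrum <- function(x, ...) {
  at <- function(s0) stats::approx(x$s, x$D, xout = s0)$y
  w <- heterogeneity_width(x)
  tibble::tibble(D0 = at(0), D1 = at(1), D2 = at(2),
                 alpha_min = w$alpha_min, alpha_max = w$alpha_max,
                 width = w$width, kind = attr(x, "kind") %||% NA_character_)
}

#' Plot a multifractal spectrum
#'
#' @param object An `mf_spectrum`.
#' @param which `"dimensions"` for `D_s` vs `s`, `"falpha"` for the
#'   singularity spectrum `f(alpha)`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mf_spectrum <- function(object, which = c("dimensions", "falpha"),
                                 ...) {
  which <- match.arg(which)
  if (which == "dimensions") {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$s, y = .data$D)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "s", y = expression(D[s]))
  } else {
    obj <- if (!"alpha" %in% names(object)) legendre_spectrum(object)
           else object
    ggplot2::ggplot(obj, ggplot2::aes(x = .data$alpha, y = .data$f)) +
      ggplot2::geom_path() +
      ggplot2::labs(x = expression(alpha), y = expression(f(alpha)))
  }
}
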