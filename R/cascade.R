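#' Benchmark cascade models M1-M7
#'
#' Cell probabilities of the seven benchmark multiplicative-cascade models.
#' `(p1, p2)` form the top row and `(p3, p4)` the bottom row of the 2x2
#' generator block. M4 is a single-scale Sierpinski gasket support, M7 the
#' uniform square; M5 and M6 share the same probability multiset and hence
#' the same dimension spectrum.
#'
#' @return A tibble with columns `model`, `p1`, `p2`, `p3`, `p4`.
#' @export
cascade_models <- function() {
  tibble::tribble(
    ~model, ~p1, ~p2, ~p3, ~p4,
    "M1", 1, 1, 1, 0.5,
    "M2", 1, 1, 0.5, 0.5,
    "M3", 1, 0.75, 0.75, 0.75,
    "M4", 1, 1, 1, 0,
    "M5", 1, 1, 0.5, 0.25,
    "M6", 0.5, 1, 1, 0.25,
    "M7", 1, 1, 1, 1
  )
}

resolve_cascade_probs <- function(spec) {
  if (is.character(spec) && length(spec) == 1L) {
    row <- cascade_models()[cascade_models()$model == spec, ]
    if (nrow(row) == 0L) {
      stop("unknown cascade model: ", spec,
           " (use one of M1-M7 or a numeric vector of length 4)",
           call. = FALSE)
    }
    p <- c(row$p1, row$p2, row$p3, row$p4)
  } else {
    p <- as.numeric(spec)
  }
  if (length(p) != 4L || any(p < 0) || any(p > 1) || all(p == 0)) {
    stop("cascade probabilities must be 4 values in [0, 1], not all zero",
         call. = FALSE)
  }
  p
}

#' Multiplicative deterministic cascade field
#'
#' Builds the n-fold Kronecker power of the 2x2 probability block: the unit
#' square is split into four equal subsquares carrying probabilities
#' `p1..p4` (p1, p2 top row; p3, p4 bottom row), and each subsquare is
#' recursively split the same way, multiplying probabilities. The raw field
#' sums to `(p1+p2+p3+p4)^n`.
#'
#' @param spec A model name (`"M1"`..`"M7"`) or numeric `c(p1, p2, p3, p4)`.
#' @param n Iteration count (>= 1); the grid is `2^n` x `2^n`.
#' @param normalize If `TRUE` (default) return a probability grid (sums to
#'   1); otherwise the raw Kronecker power.
#' @param max_n Memory guard on the grid size (default 12, i.e. 4096^2).
#' @return A [measure_grid()] with cell size `2^-n`.
#' @export
#' @examples
#' cascade_field("M4", n = 3)
cascade_field <- function(spec, n, normalize = TRUE, max_n = 12L) {
  p <- resolve_cascade_probs(spec)
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (n > max_n) {
    stop("n = ", n, " exceeds the grid cap 2^", max_n, " x 2^", max_n,
         call. = FALSE)
  }
  # block in y-up matrix convention: row 1 = bottom of the square
  block <- rbind(c(p[3], p[4]), c(p[1], p[2]))
  field <- Reduce(kronecker, rep(list(block), n))
  if (normalize) {
    measure_grid(field / sum(field), cell_size = 2^-n, mode = "probability")
  } else {
    measure_grid(field, cell_size = 2^-n, mode = "counts")
  }
}

#' Closed-form generalized-dimension spectrum of a cascade
#'
#' For a multiplicative cascade with cell probabilities `p1..p4` the
#' generalized dimensions have the analytic form
#' `D_s = log2(sum_j f_j^s) / (1 - s)` with `f_j = p_j / sum(p)` taken over
#' the nonzero cells; at `s = 1` the entropy limit
#' `D_1 = -sum_j f_j log2 f_j` applies. The mass exponent
#' `tau(s) = (s - 1) D_s` is attached, and the analytic asymptotes
#' `alpha_min = -log2(max f_j)` (s -> +Inf) and
#' `alpha_max = -log2(min nonzero f_j)` (s -> -Inf) are stored as
#' attributes.
#'
#' @param spec A model name or numeric `c(p1, p2, p3, p4)`.
#' @param s_grid Exponent grid (default -10 to 10 in steps of 0.25).
#' @return An `mf_spectrum` tibble with columns `s`, `D`, `tau` and
#'   attributes `kind = "analytic"`, `alpha_min_inf`, `alpha_max_inf`.
#' @export
#' @examples
#' analytic_generalized_dimensions("M4")  # flat at log2(3)
analytic_generalized_dimensions <- function(spec,
                                            s_grid = seq(-10, 10, 0.25)) {
  p <- resolve_cascade_probs(spec)
  f <- p[p > 0] / sum(p)
  lf <- log(f)
  D <- vapply(s_grid, function(s) {
    if (abs(s - 1) < 1e-12) {
      -sum(f * log2(f))
    } else {
      # log-sum-exp keeps the expression finite for large |s|
      m <- max(s * lf)
      ((m + log(sum(exp(s * lf - m)))) / log(2)) / (1 - s)
    }
  }, numeric(1))
  out <- tibble::tibble(s = s_grid, D = D, tau = (s_grid - 1) * D)
  class(out) <- c("mf_spectrum", class(out))
  attr(out, "kind") <- "analytic"
  attr(out, "alpha_min_inf") <- -log2(max(f))
  attr(out, "alpha_max_inf") <- -log2(min(f))
  out
}
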