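#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis with its default, so a
#' run records exactly which values were applied. Exactly one input source
#' must be given: a FASTA path, a forbidden-pair model name (TR12/TR13/
#' TR33), a cascade model name (M1..M7), `"uniform"` (random points in the
#' square) or `"sierpinski"` (chaos game with three of the four square
#' maps).
#'
#' @param fasta Path to a FASTA file, or `NULL`.
#' @param model Benchmark model name, or `NULL`.
#' @param seed Integer seed for every stochastic stage.
#' @param n_points Points for sequence-free point processes (default 1e5).
#' @param sequence_length Length of generated TR sequences (default 8e4).
#' @param cascade_n Cascade iteration count (default 6).
#' @param grid_size Raster resolution for point sets (default 360).
#' @param threshold Binarization threshold for cascade fields (default
#'   0.4).
#' @param binarize_direction `"<="` (default: keep the dark, high-measure
#'   cells) or `">="` (the complementary structure).
#' @param box Box-counting configuration ([box_config()]).
#' @param bin_width_frac Pair-histogram bin width as a fraction of the
#'   edge (default 1/1000).
#' @param q_points Size of the log-spaced q grid (default 256).
#' @param prominence Log-periodicity prominence floor (default 0.05).
#' @param out_dir Output directory for artifacts, or `NULL` to skip
#'   writing.
#' @return A `run_config` list.
#' @export
run_config <- function(fasta = NULL, model = NULL, seed = 1L,
                       n_points = 1e5, sequence_length = 8e4,
                       cascade_n = 6L, grid_size = 360L, threshold = 0.4,
                       binarize_direction = "<=", box = box_config(),
                       bin_width_frac = 1e-3, q_points = 256L,
                       prominence = 0.05, out_dir = NULL) {
  if (is.null(fasta) == is.null(model)) {
    stop("give exactly one of `fasta` or `model`", call. = FALSE)
  }
  if (!is.null(model) &&
      !model %in% c(cascade_models()$model, names(TR_MODELS),
                    "uniform", "sierpinski")) {
    stop("unknown model: ", model, call. = FALSE)
  }
  structure(
    list(fasta = fasta, model = model, seed = as.integer(seed),
         n_points = n_points, sequence_length = sequence_length,
         cascade_n = as.integer(cascade_n), grid_size = as.integer(grid_size),
         threshold = threshold, binarize_direction = binarize_direction,
         box = box, bin_width_frac = bin_width_frac,
         q_points = as.integer(q_points), prominence = prominence,
         out_dir = out_dir),
    class = "run_config")
}

#' Default fractal-region fit interval
#'
#' The power-law (fractal) regime of the structure factor runs from the
#' Guinier knee `q = 2*pi/l` down to whichever cutoff comes first: the
#' smallest-feature knee `2*pi/l0`, or the finite-N plateau crossover near
#' `q = 2*pi*sqrt(N)/l` where `S(q)` meets its `1/N` floor (taking the
#' embedding dimension 2 for the crossover estimate). A factor-2 margin is
#' kept off the Guinier knee and a factor 2 (feature knee) or 4 (plateau
#' crossover, a softer shoulder) off the upper cutoff.
#'
#' @param l Overall size.
#' @param l0 Smallest feature size.
#' @param n_points Number of scatterers.
#' @return Length-2 numeric `q` interval.
#' @export
fractal_fit_range <- function(l, l0, n_points) {
  c(2 * 2 * pi / l,
    min(0.5 * 2 * pi / l0, 0.25 * 2 * pi * sqrt(n_points) / l))
}

#' Uniform random points in the square
#'
#' @param n_points Number of points.
#' @param seed Integer seed.
#' @param edge Square edge length (default 1).
#' @return A `cgr_points` tibble.
#' @export
uniform_square_points <- function(n_points, seed, edge = 1) {
  xy <- withr::with_seed(seed, matrix(runif(2 * n_points), ncol = 2)) * edge
  new_point_set(xy[, 1], xy[, 2], edge, "uniform")
}

resolve_input_points <- function(config) {
  c0 <- config
  if (!is.null(c0$fasta)) {
    seqs <- read_fasta(c0$fasta)
    return(list(points = cgr_map(seqs[1, ]), source = seqs$id[1],
                kind = "sequence"))
  }
  m <- c0$model
  if (m %in% names(TR_MODELS)) {
    s <- tr_model_sequence(m, length = c0$sequence_length, seed = c0$seed)
    list(points = cgr_map(s), source = m, kind = "sequence")
  } else if (m %in% cascade_models()$model) {
    field <- cascade_field(m, n = c0$cascade_n)
    eq <- equalize_histogram(field)
    pts <- binarize(eq, c0$threshold, direction = c0$binarize_direction)
    list(points = pts, source = m, kind = "cascade", field = field)
  } else if (m == "uniform") {
    list(points = uniform_square_points(c0$n_points, c0$seed),
         source = "uniform", kind = "points")
  } else {
    att <- chaos_game_attractor(square_ifs_maps(1:3), n_points = c0$n_points,
                                seed = c0$seed)
    list(points = att, source = "sierpinski", kind = "points")
  }
}

#' Run the full CGR / multifractal / scattering pipeline
#'
#' Resolves the configured input to a point set (and, for cascade models,
#' the underlying probability field), then computes: the raster measure
#' grid, the box-counting generalized-dimension spectrum with its Legendre
#' `f(alpha)` transform and heterogeneity width, the Debye structure
#' factor with regime boundaries, the fractal-region power-law exponent,
#' the log-periodicity of the compensated curve, and the pair-distance
#' distribution function. Deterministic given the seed. If `out_dir` is
#' set, every table is written (TSV / text grid / PNG / JSON summary).
#'
#' @param config A [run_config()].
#' @return A list of class `cgrsas_run`: `points`, `grid`, `spectrum`,
#'   `width`, `curve`, `regimes`, `power_fit`, `logper`, `pddf`, `summary`
#'   (one-row tibble), `config`.
#' @export
#' @examples
#' run <- run_pipeline(run_config(model = "M4", cascade_n = 5))
#' run$summary
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  src <- resolve_input_points(config)
  pts <- src$points
  edge <- attr(pts, "edge")

  # measure grid: the exact probability field for cascades, a raster of
  # the point set otherwise
  grid <- if (src$kind == "cascade") {
    src$field
  } else {
    rasterize(pts, config$grid_size)
  }
  spectrum <- legendre_spectrum(generalized_dimensions(grid, config$box))
  width <- heterogeneity_width(spectrum)
  D0 <- stats::approx(spectrum$s, spectrum$D, xout = 0)$y

  l0 <- grid$cell_size
  hist <- pair_distance_histogram(pts, bin_width = config$bin_width_frac * edge)
  curve <- debye_intensity(hist, q_log_grid(edge, l0, config$q_points))
  regimes <- detect_regimes(curve, edge, l0)
  fractal_range <- fractal_fit_range(edge, l0, nrow(pts))
  power_fit <- fit_power_law_exponent(curve, fractal_range)
  # the minima ladder stays readable through the plateau crossover, so the
  # periodicity search spans the whole fractal region
  logper <- log_periodicity_analysis(
    curve, power_fit$D,
    q_range = c(2 * 2 * pi / edge, 0.5 * 2 * pi / l0),
    prominence = config$prominence)
  p_r <- pddf(hist)

  summary <- tibble::tibble(
    source = src$source,
    seed = config$seed,
    n_points = nrow(pts),
    D0 = D0,
    D_sas = power_fit$D,
    beta = logper$beta,
    n_minima = logper$n_minima,
    alpha_min = width$alpha_min,
    alpha_max = width$alpha_max,
    k_estimate = regimes$k_estimate,
    pddf_mode = attr(p_r, "mode_r") / edge,
    pddf_support = attr(p_r, "r_support") / edge
  )
  run <- structure(
    list(points = pts, grid = grid, spectrum = spectrum, width = width,
         curve = curve, regimes = regimes, power_fit = power_fit,
         logper = logper, pddf = p_r, summary = summary, config = config),
    class = "cgrsas_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @export
print.cgrsas_run <- function(x, ...) {
  cat("<cgrsas_run>\n")
  print(x$summary)
  invisible(x)
}

#' @describeIn run_pipeline One-row tibble of the run's headline numbers.
#' @param x A `cgrsas_run`.
#' @param ... Unused.
#' @export
glance.cgrsas_run <- function(x, ...) x$summary

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(name) file.path(out_dir, name)
  write_points_tsv(run$points, fp("points.tsv"))
  write_grid_text(run$grid, fp("grid.txt"))
  write_grid_png(run$grid, fp("grid.png"))
  utils::write.table(run$spectrum, fp("spectrum.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(run$curve, fp("curve.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(run$pddf, fp("pddf.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(as.list(run$summary), fp("summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}

#' Write the benchmark fixture suite
#'
#' Materializes every offline benchmark input: the seven cascade fields
#' (M1..M7) as text grids, the three forbidden-pair sequences (TR12, TR13,
#' TR33, benchmark length 8e4) as FASTA, and the uniform-square and
#' Sierpinski point sets as TSV. Regeneration with the same seed is
#' byte-identical.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param cascade_n Cascade iterations for the text grids (default 5).
#' @param n_points Size of the point-set fixtures (default 1e4).
#' @param tr_length Length of the TR sequences (default 8e4).
#' @return Tibble listing the files written.
#' @export
fixture_suite <- function(dir, seed = 1L, cascade_n = 5L, n_points = 1e4,
                          tr_length = 8e4) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (m in cascade_models()$model) {
    f <- file.path(dir, paste0("cascade_", m, ".txt"))
    write_grid_text(cascade_field(m, n = cascade_n), f)
    files <- c(files, f)
  }
  for (m in names(TR_MODELS)) {
    f <- file.path(dir, paste0(m, ".fasta"))
    write_fasta(tr_model_sequence(m, length = tr_length, seed = seed), f)
    files <- c(files, f)
  }
  f <- file.path(dir, "uniform.tsv")
  write_points_tsv(uniform_square_points(n_points, seed), f)
  files <- c(files, f)
  f <- file.path(dir, "sierpinski.tsv")
  write_points_tsv(
    chaos_game_attractor(square_ifs_maps(1:3), n_points = n_points,
                         seed = seed), f)
  files <- c(files, f)
  tibble::tibble(file = files, bytes = file.size(files))
}
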