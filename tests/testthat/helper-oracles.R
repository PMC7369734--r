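# Independent oracles used across tests; these recompute quantities by
# brute force or closed form, never through the package's own path.

# Debye intensity by the exact pair double-sum (no histogram binning)
direct_debye <- function(x, y, q) {
  dmat <- as.matrix(dist(cbind(x, y)))
  d <- dmat[upper.tri(dmat)]
  n <- length(x)
  vapply(q, function(qq) {
    if (qq == 0) return(n^2)
    xx <- qq * d
    n + 2 * sum(sin(xx) / xx)
  }, numeric(1))
}

# point set wrapper for hand-built coordinates
make_points <- function(x, y, edge = 1) {
  pts <- tibble::tibble(x = x, y = y)
  class(pts) <- c("cgr_points", class(pts))
  attr(pts, "edge") <- edge
  attr(pts, "label") <- "test"
  pts
}

# half-distance CGR iteration written independently (plain loop)
cgr_loop <- function(bases, vx, vy, x0, y0) {
  out <- matrix(NA_real_, nchar(bases), 2)
  x <- x0; y <- y0
  b <- strsplit(bases, "")[[1]]
  for (k in seq_along(b)) {
    x <- (x + vx[b[k]]) / 2
    y <- (y + vy[b[k]]) / 2
    out[k, ] <- c(x, y)
  }
  out
}

# count occurrences of a dinucleotide (overlapping) in a base string
count_pairs <- function(bases, pair) {
  b <- strsplit(bases, "")[[1]]
  sum(paste0(b[-length(b)], b[-1]) == pair)
}
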