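---
title: "Characterizing CGR point sets: multifractal spectra and simulated small-angle scattering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing CGR point sets: multifractal spectra and simulated small-angle scattering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgrsas)
```

## The problem

The chaos game representation (CGR) turns a DNA sequence into a planar
point set: each base pulls the current point halfway toward its corner of
the ACGT square. Because the map is one-to-one with the sequence,
statistical structure in the sequence — forbidden dinucleotides,
long-range correlations, compositional bias — becomes geometric structure
in the point set, typically fractal. This package quantifies that
structure with two complementary formalisms:

* **multifractal box counting**, which measures how the occupation
  measure scales with box size and summarizes it in the generalized
  dimensions \(D_s\) and the singularity spectrum \(f(\alpha)\); and
* **simulated small-angle scattering (SAS)**, which treats the points as
  scatterers and reads structural parameters — fractal dimension, overall
  size, number of units, scaling factor, iteration depth — off the Debye
  structure factor \(S(q)\).

The two views are complementary: distinct measures can share a dimension
spectrum (the cascade models M5 and M6 below are an exact example), while
their scattering curves still differ; conversely the scattering exponent
recovers the box-counting dimension of the support.

Two synthetic benchmark families make every analysis testable without any
sequence download, and they are first-class, seeded generators in the
package, not fixtures.

## Chaos game and CGR

An iterated function system of four contractions
\(w_i(\mathbf x) = \tfrac12 \mathbf x + \mathbf e_i\), one per corner of
the unit square, rendered by the random iteration algorithm with equal
weights, fills the square uniformly; keeping three of the four maps draws
a Sierpiński gasket with dimension \(\log_2 3 \approx 1.585\)
(`chaos_game_attractor()`, `square_ifs_maps()`). The deterministic CGR of
a sequence (`cgr_map()`) starts at the square center and plots base $k$
at the midpoint between the previous point and the vertex of base $k$.
The default vertex layout is a square of edge \(1/2\) with A at the
origin, T, G, C counter-clockwise; both the layout and the contraction
ratio are configurable, since other CGR conventions exist. All points are
kept (no burn-in) for sequence CGR; the random-iteration attractor
discards a 100-point burn-in by default.

`rasterize()` bins a point set on an \(M \times M\) grid of half-open
cells (top/right boundary assigned to the last cell; row 1 is the bottom
of the square). The default \(M = 360\) is a convenient working
resolution for genome-scale CGRs.

## Benchmark generators

**Multiplicative deterministic cascades** (`cascade_field()`): the unit
square is split into four cells with probabilities \(p_1,\dots,p_4\)
((\(p_1,p_2\)) top row, (\(p_3,p_4\)) bottom — the placement only changes
the picture, never the spectrum), and the construction is iterated by
Kronecker powers of the \(2\times2\) block. The seven models M1–M7
(`cascade_models()`) span stripes, single-scale gaskets (M4 = (1,1,1,0)),
strongly multifractal measures (M5 = (1,1,0.5,0.25), M6 its reshuffle)
and the uniform square (M7). Their generalized dimensions have the closed
form
\[
D_s = \frac{1}{1-s}\,\log_2 \sum_j f_j^{\,s}, \qquad
f_j = p_j \Big/ \sum_i p_i,
\]
with the entropy limit \(D_1 = -\sum_j f_j \log_2 f_j\)
(`analytic_generalized_dimensions()`). Cells with \(f_j = 0\) are dropped
from the sum: \(0^s\) diverges for \(s<0\), and with the zero cells
removed the M4 spectrum is the finite constant \(\log_2 3\), as it must
be. The \(s \to \pm\infty\) asymptotes are \(-\log_2 \max_j f_j\) and
\(-\log_2 \min_{j: f_j>0} f_j\); for M5 these are
\(\log_2 2.75 \approx 1.459\) and \(\log_2 11 \approx 3.459\). We report
the analytic asymptotes and the finite-grid extrema separately, because
extrema taken on any finite \(s\) grid are biased toward the center by an
amount of order \(1/|s_{\max}|\). Extreme exponents are evaluated with a
log-sum-exp so the expression stays finite for \(|s|\) in the hundreds.

**Forbidden-dinucleotide sequences**
(`generate_forbidden_pair_sequence()`, `tr_model_sequence()`): random
sequences that never contain one ordered dinucleotide — TR12 forbids
"AT", TR13 "AG", TR33 "GG" — produce CGRs whose empty regions follow a
power-law size distribution. The generator is a first-order Markov chain,
uniform over the allowed successors of the previous base; this is the
minimal-assumption reading of "random sequence that never contains",
and with an empty forbidden set it reduces exactly to the i.i.d. uniform
sequence. Dead-end sets (a base with all four successors forbidden) are
rejected at construction. Seeds are explicit arguments everywhere; no
generator touches the global RNG state.

```{r}
analytic_generalized_dimensions("M4", s_grid = c(-5, 0, 5))$D
glance(legendre_spectrum(analytic_generalized_dimensions("M5")))
```

## Box-counting estimation

`generalized_dimensions()` aggregates the measure grid over dyadic blocks
(box sides \(M, M/2, \dots, 4\) cells), so box measures are exact block
sums with no partial boxes, and regresses \(\ln Z_s(l)\) on \(\ln l\),
with \(Z_s(l) = \sum_i p_i^s\) over occupied boxes. \(D_1\) uses the
entropy-sum regression \(\sum_i p_i \ln p_i\) versus \(\ln l\) rather
than interpolation across \(s = 1\). Defaults that matter:

* *s grid*: \(-10\) to \(10\) in steps of \(0.25\);
* *fit range*: the largest scale (a single box — a degenerate point) and
  the two smallest scales (discretization bias) are dropped, but trims
  are relaxed, smallest-side first, whenever fewer than three scales
  would remain (this is what a \(2^5\) grid gets);
* *occupancy guard*: boxes with zero measure are excluded for every
  \(s\); for counts grids a minimum of one point per box additionally
  guards \(s < 0\) against sparsely-hit boundary boxes, the standard
  box-counting pathology.

On cascade fields the block sums reproduce the construction exactly, so
the estimate agrees with the closed form to machine precision; on point
rasters it is a genuine estimate with per-\(s\) \(R^2\) diagnostics
attached. `legendre_spectrum()` fills \(\alpha = d\tau/ds\) by central
differences and \(f = s\alpha - \tau\); `heterogeneity_width()` reports
\(\alpha_{\min}, \alpha_{\max}\); `dimension_from_scaling()` solves the
scaling relation \(\sum_i k_i \beta_i^D = 1\) by bisection to
\(10^{-10}\).

## Grayscale preprocessing and the ink convention

Cascade measures span many decades, so their grayscale images concentrate
nearly all cells in a narrow range of levels and direct thresholding is
useless. The package therefore follows the image pipeline: pixel
histogram, histogram equalization, threshold binarization
(`pixel_histogram()`, `equalize_histogram()`, `binarize()`).

One convention decides everything here: grids are rendered as *ink*,
level \(= 1 -\) min-max-rescaled measure, so dense cells are dark —
exactly how a CGR is plotted (black points on white). Under this
convention cascade pixel levels pile up near white before equalization,
the default occupied rule "level \(\le t\)" picks the dark, high-measure
cells, the occupied count \(k\) grows with \(t\), and the occupied set at
moderate thresholds is the measure's support — the object whose dimension
the scattering exponent should recover. The opposite direction (`">="`)
is available for studying the complementary structure. Equalization uses
256 quantization levels by default (the 8-bit convention; the fitted
scattering exponent is verified to be stable across 128/256/512 levels),
is monotone (ties stay tied), and is idempotent up to quantization once
the input is already grayscale (`convention = "grayscale"`).

## Simulated small-angle scattering

With \(N\) identical point scatterers, the orientationally averaged
Debye intensity is
\[
I(q) = N + 2 \sum_{i<j} \frac{\sin(q r_{ij})}{q r_{ij}},
\]
computed through a pair-distance histogram \(g(r)\) so the cost is one
\(O(N^2)\) compiled pass with \(O(\text{bins})\) memory
(`pair_distance_histogram()`, `debye_intensity()`). The default bin width
\(l/1000\) keeps the binned sum within 1% of the exact double sum (a
tested oracle equivalence on small sets). The 3D average
\(\sin(qr)/qr\) is used although the points are planar, corresponding to
free rotation of the square in three dimensions. \(I(0) = N^2\) exactly;
the structure factor is \(S(q) = I(q)/I(0)\).

\(S(q)\) shows three regimes (`detect_regimes()`): a Guinier plateau for
\(ql \lesssim 2\pi\), a power law \(S \propto q^{-D}\) in the fractal
region, and a high-\(q\) plateau near \(1/k\) whose inverse estimates the
number of scatterers. The default \(q\) grid is 256 log-spaced points
from \(0.2\cdot 2\pi/l\) to \(20\cdot 2\pi/l_0\), covering all three
regimes with margin.

`fit_power_law_exponent()` is an ordinary least-squares fit of
\(\log S\) on \(\log q\). The pipeline's default fit interval
(`fractal_fit_range()`) keeps a factor-2 margin above the Guinier knee
and stays below both the smallest-feature knee \(2\pi/l_0\) (factor 2)
and the finite-\(N\) plateau crossover \(2\pi\sqrt{N}/l\) (factor 4) —
for point sets with few points relative to the raster, the plateau, not
the pixel size, ends the fractal regime, and ignoring that biases the
slope low. At desk-scale cascade resolutions (\(2^6\)–\(2^7\)) the
fitted slope of a binarized multifractal cascade tracks the correlation
dimension \(D_2\) of the thresholded set (about 1.76–1.83 for M5 at
threshold 0.4) rather than its box dimension \(D_0 \approx 1.95\); the
two converge at image-scale resolution. The tests assert exactly what
the package computes at these sizes.

**Log-periodicity** (`log_periodicity_analysis()`): deterministic
fractals superimpose log-periodic oscillations on the fractal-region
power law; the compensated curve \(q^D S(q)\) has minima spaced by the
inverse scaling factor on the log-\(q\) axis, and their count estimates
the iteration depth. The curve is smoothed with a Savitzky–Golay filter
whose window spans about a quarter decade of \(q\) at the grid's density
— wide enough to suppress the fine sinc oscillations of individual pair
distances, narrow enough to leave factor-2 periodicity intact. Minima
must clear a prominence floor, measured against the *local* flanking
maxima (between adjacent candidate minima), of 5% of the curve range
with an absolute floor of 0.01 decades; a featureless power law
therefore yields zero minima, which is a valid result, not an error.
\(\beta\) is the inverse geometric mean of successive minima-position
ratios rather than any single pair, since the periodicity is only
approximate. These defaults were calibrated once against the known
construction — binarized gasket cascades and chaos-game gaskets halve at
each iteration, so \(\beta = 1/2\) — and recover \(\beta \in
[0.45, 0.55]\) at cascade iterations 5–7. Minima counts near the
fractal/asymptotic crossover can be censored by the prominence rule
(at \(n = 6\) the fourth gasket minimum sits on the crossover shoulder),
so the count is best read as a lower bound on the iteration depth;
diagnostics expose the accepted minima and their prominences.

The pair-distance distribution function (`pddf()`) is the normalized
histogram \(p(r) = g(r)/(\sum g \cdot \Delta r)\). For uniform points in
a square of edge \(l\) its mode sits near \(r/l \approx 0.48\) (the
closed-form density \(2r(\pi - 4r + r^2)\) peaks there; at histogram
resolution this is the "\(\approx 0.5\)" signature of the square) and
its support ends at the diagonal \(r/l = \sqrt 2\).

## The pipeline

`run_pipeline(run_config(...))` chains every stage — input resolution,
rasterization, box counting, Legendre transform, Debye curve, regime
detection, power-law fit, log-periodicity, pddf — deterministically given
one seed, logs every applied default in its config object, writes all
tables when an output directory is set, and returns a one-row summary
(`D0`, `D_sas`, `beta`, `n_minima`, `alpha` extrema, `k_estimate`, pddf
mode/support). Each stage is an exported function, and recomputing any
stage by hand reproduces the bundled result exactly (a tested
composability property). `fixture_suite()` materializes all benchmarks
(M1–M7 fields, TR12/13/33 FASTA at the benchmark length \(8\times10^4\),
uniform and gasket point sets) byte-reproducibly.

```{r}
run <- run_pipeline(run_config(model = "M4", cascade_n = 5L))
run$summary
```

## What the generators do and do not emulate

The cascades and TR sequences reproduce the *mechanisms* the analyses
target — exact self-similarity with known \(D_s\), and constraint-induced
fractality with known forbidden pairs — under sizes chosen to run on a
desk: cascade iterations 5–8 (\(32^2\)–\(256^2\) grids), sequences of
\(8\times10^4\) bases, point sets of \(10^4\)–\(10^5\). They do not
emulate real genomes' mixture of constraints, compositional
heterogeneity along the sequence, or finite read quality; a test passing
on them validates the estimators' correctness and calibration, not any
biological claim about a particular organism. Real sequences enter
through `read_fasta()`, which upper-cases and strips non-ACGT symbols
(ambiguity codes would need vertices the chaos game does not have),
reporting the number removed.

## Known limitations

* The box-counting fit range on a 360-cell raster stops at the first odd
  halving (360, 180, 90, 45); power-of-two grid sizes use the full dyadic
  ladder.
* The scattering exponent of thresholded multifractal measures at
  reduced iteration depth is a \(D_2\)-like quantity, systematically
  below \(D_0\) (see above); comparisons against box-counting dimensions
  should use matching resolutions.
* \(\beta\) extraction assumes a single dominant scaling factor;
  multi-scale cascades superimpose several periods that the geometric
  mean does not separate.
* The Debye sum is not pointwise nonnegative at finite \(N\);
  non-positive \(S\) values are excluded from log-log fits with a
  warning.
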