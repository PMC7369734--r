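Package: cgrsas
Title: Chaos Game Representation, Multifractal Spectra and Simulated
    Small-Angle Scattering of DNA Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts DNA sequences into chaos-game-representation (CGR)
    point sets and characterizes them by two complementary formalisms:
    multifractal box-counting analysis (generalized dimensions, Legendre
    f(alpha) spectra) and simulated small-angle scattering (Debye
    intensity, structure-factor regimes, log-periodicity, pair-distance
    distribution functions). Includes generators for the two benchmark
    families used to validate the analyses without external data:
    multiplicative deterministic cascade measures built from Kronecker
    powers of a 2x2 probability block, and random sequences with
    forbidden dinucleotides.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
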