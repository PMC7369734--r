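#' Read DNA sequences from a FASTA file
#'
#' Parses a (possibly multi-record, wrapped or unwrapped) FASTA file into a
#' tibble of cleaned DNA sequences. Characters are upper-cased and every
#' symbol outside the `{A, C, G, T}` alphabet (ambiguity codes, gaps, `N`)
#' is removed, since the chaos-game map is defined only on the four bases.
#' The number of removed symbols per record is reported in the `n_removed`
#' column and via a message.
#'
#' @param path Path to a FASTA file.
#' @param quiet If `TRUE`, suppress the message about removed symbols.
#'
#' @return A tibble with one row per record and columns `id` (record label),
#'   `bases` (cleaned sequence string), `length` and `n_removed`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgtn"), fa)
#' read_fasta(fa)
read_fasta <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file contains no records: ", path, call. = FALSE)
  }
  raw <- toupper(as.character(set))
  clean <- gsub("[^ACGT]", "", raw)
  n_removed <- nchar(raw) - nchar(clean)
  if (any(nchar(clean) == 0L)) {
    bad <- names(set)[nchar(clean) == 0L]
    stop("record(s) with zero valid A/C/G/T bases: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!quiet && sum(n_removed) > 0L) {
    message("read_fasta: removed ", sum(n_removed),
            " non-ACGT symbol(s) across ", sum(n_removed > 0L), " record(s)")
  }
  tibble::tibble(
    id = names(set),
    bases = unname(clean),
    length = unname(nchar(clean)),
    n_removed = unname(n_removed)
  )
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs A tibble with columns `id` and `bases`, as returned by
#'   [read_fasta()] or the sequence generators.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("id", "bases") %in% names(seqs)))
  set <- Biostrings::DNAStringSet(seqs$bases)
  names(set) <- seqs$id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

DNA_BASES <- c("A", "C", "G", "T")

new_sequence_tbl <- function(id, bases) {
  tibble::tibble(id = id, bases = bases,
                 length = nchar(bases), n_removed = 0L)
}

#' Generate a random DNA sequence
#'
#' Draws bases i.i.d. uniformly over `{A, C, G, T}`.
#'
#' @param length Number of bases (>= 1).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @param id Record label.
#' @return A one-row sequence tibble (columns `id`, `bases`, `length`,
#'   `n_removed`).
#' @export
#' @examples
#' generate_random_sequence(12, seed = 1)
generate_random_sequence <- function(length, seed, id = "random") {
  stopifnot(is.numeric(length), length >= 1)
  length <- as.integer(length)
  bases <- withr::with_seed(seed,
    sample(DNA_BASES, length, replace = TRUE))
  new_sequence_tbl(id, paste(bases, collapse = ""))
}

#' Build a forbidden-dinucleotide set
#'
#' The TR benchmark models forbid one ordered dinucleotide each:
#' TR12 forbids "AT", TR13 forbids "AG", TR33 forbids "GG".
#'
#' @param pairs Character vector of ordered dinucleotides, e.g. `c("AT")`.
#' @return A two-column tibble (`from`, `to`) validated against dead ends:
#'   no base may have all four successors forbidden.
#' @export
forbidden_pairs <- function(pairs) {
  pairs <- toupper(pairs)
  if (length(pairs) && any(nchar(pairs) != 2L | grepl("[^ACGT]", pairs))) {
    stop("forbidden pairs must be dinucleotides over A/C/G/T", call. = FALSE)
  }
  out <- tibble::tibble(
    from = substr(pairs, 1L, 1L),
    to = substr(pairs, 2L, 2L)
  )
  out <- dplyr::distinct(out)
  blocked <- dplyr::count(out, .data$from)
  if (any(blocked$n >= 4L)) {
    stop("dead end: base(s) ", paste(blocked$from[blocked$n >= 4L],
         collapse = ", "), " have all four successors forbidden",
         call. = FALSE)
  }
  out
}

#' Generate a random sequence that avoids forbidden dinucleotides
#'
#' First-order Markov construction: the first base is uniform over the four
#' bases, and each subsequent base is uniform over the successors of the
#' previous base that are not forbidden. The output therefore never contains
#' any forbidden dinucleotide as a substring. The TR benchmark models are
#' available by name through [tr_model_sequence()].
#'
#' @param length Number of bases (>= 1).
#' @param forbidden A tibble from [forbidden_pairs()] (possibly empty).
#' @param seed Integer seed.
#' @param id Record label.
#' @return A one-row sequence tibble.
#' @export
#' @examples
#' s <- generate_forbidden_pair_sequence(1e3, forbidden_pairs("AT"), seed = 7)
#' grepl("AT", s$bases)  # FALSE by construction
generate_forbidden_pair_sequence <- function(length, forbidden, seed,
                                             id = "forbidden-pair") {
  stopifnot(is.numeric(length), length >= 1)
  length <- as.integer(length)
  forbidden <- forbidden[c("from", "to")]
  # allowed successor sets per base, validated non-empty
  allowed <- lapply(DNA_BASES, function(b) {
    setdiff(DNA_BASES, forbidden$to[forbidden$from == b])
  })
  names(allowed) <- DNA_BASES
  if (any(lengths(allowed) == 0L)) {
    stop("dead-end forbidden set", call. = FALSE)
  }
  bases <- withr::with_seed(seed, {
    out <- character(length)
    out[1L] <- sample(DNA_BASES, 1L)
    for (k in seq_len(length - 1L)) {
      succ <- allowed[[out[k]]]
      out[k + 1L] <- succ[sample.int(length(succ), 1L)]
    }
    out
  })
  new_sequence_tbl(id, paste(bases, collapse = ""))
}

TR_MODELS <- list(TR12 = "AT", TR13 = "AG", TR33 = "GG")

#' Generate one of the TR forbidden-pair benchmark sequences
#'
#' @param model One of `"TR12"` (no "AT"), `"TR13"` (no "AG"),
#'   `"TR33"` (no "GG").
#' @param length Number of bases; the benchmark length is `8e4`.
#' @param seed Integer seed.
#' @return A one-row sequence tibble.
#' @export
tr_model_sequence <- function(model = c("TR12", "TR13", "TR33"),
                              length = 8e4, seed = 1L) {
  model <- match.arg(model)
  generate_forbidden_pair_sequence(
    length, forbidden_pairs(TR_MODELS[[model]]), seed = seed, id = model)
}
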