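#' Construct an RNA sequence-structure record
#'
#' The unit of the whole pipeline: one RNA sequence together with its family
#' label and reference secondary structure, stored as a set of base pairs.
#' Pairs use 1-based coordinates with `i < j` and may cross (pseudoknots occur
#' in reference data even though minimum-free-energy folding cannot predict
#' them).
#'
#' @param id Character identifier, unique within a corpus.
#' @param sequence Character string over A, C, G, U; T is converted to U and
#'   IUPAC ambiguity letters are accepted.
#' @param pairs Two-column integer matrix (or empty) of paired positions.
#'   Rows may be given in either order; they are normalised to `i < j` and
#'   sorted by `i`.
#' @param family Character family label (e.g. `"tRNA"`), or `NA` if unknown.
#'
#' @return An object of class `rna_record`: a list with elements `id`,
#'   `family`, `sequence`, `pairs` (integer matrix with columns `i`, `j`).
#' @export
rna_record <- function(id, sequence, pairs = NULL, family = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- chartr("t", "u", sequence)
  sequence <- chartr("T", "U", toupper(sequence))
  n <- nchar(sequence)
  if (n > 0L && grepl("[^ACGUNRYSWKMBDHV]", sequence))
    stop("sequence contains characters outside the IUPAC RNA alphabet")
  if (is.null(pairs) || NROW(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  } else {
    pairs <- matrix(as.integer(as.matrix(pairs)), ncol = 2L)
    if (any(is.na(pairs))) stop("pair indices must be integers")
    swap <- pairs[, 1L] > pairs[, 2L]
    pairs[swap, ] <- pairs[swap, c(2L, 1L)]
    if (any(pairs[, 1L] == pairs[, 2L])) stop("a base cannot pair with itself")
    if (any(pairs < 1L) || any(pairs > n))
      stop("pair index outside [1, sequence length]")
    idx <- as.vector(pairs)
    if (anyDuplicated(idx))
      stop("a base appears in more than one pair")
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  }
  colnames(pairs) <- c("i", "j")
  structure(
    list(id = id, family = family, sequence = sequence, pairs = pairs),
    class = "rna_record"
  )
}

#' @export
print.rna_record <- function(x, ...) {
  cat(sprintf("<rna_record> %s  [%s]  %d nt, %d pairs\n",
              x$id, ifelse(is.na(x$family), "?", x$family),
              nchar(x$sequence), nrow(x$pairs)))
  invisible(x)
}

#' Sequence length of a record
#' @param record An [rna_record()].
#' @return Integer nucleotide count.
#' @export
seq_length <- function(record) nchar(record$sequence)

# Canonical sorted key form of a pair matrix, for set comparisons in tests
# and scoring.
pair_key <- function(pairs, n) {
  if (NROW(pairs) == 0L) return(integer(0))
  sort(pairs[, 1L] * (n + 1L) + pairs[, 2L])
}

#' Do two pair sets match exactly?
#' @param a,b Two-column pair matrices.
#' @return Logical.
#' @export
pairs_identical <- function(a, b) {
  n <- max(1L, a, b)
  identical(pair_key(a, n), pair_key(b, n))
}
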