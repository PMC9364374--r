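#' Read a connectivity-table (CT) file
#'
#' Parses the standard 6-column CT format: a header line whose first
#' whitespace-delimited token is the sequence length (the remainder is a
#' title, possibly including an energy annotation, which is ignored), then
#' one row per nucleotide holding index, base, previous index, next index,
#' pairing partner (0 = unpaired) and the natural index. Files containing
#' several concatenated structures keep only the first, with a warning.
#' Partner columns are checked for symmetry: if row i claims partner j, row j
#' must claim partner i.
#'
#' @param path Path to a CT file.
#' @param id Record identifier; default is the file name without extension.
#' @param family Optional family label to attach.
#' @return An [rna_record()].
#' @export
read_ct <- function(path, id = NULL, family = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty CT file: ", path)
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  n <- suppressWarnings(as.integer(header[[1L]]))
  if (is.na(n)) stop("CT header does not start with an integer length: ", path)
  if (length(lines) - 1L < n)
    stop("CT file has fewer rows (", length(lines) - 1L, ") than header length ", n)
  if (length(lines) - 1L > n)
    warning("CT file contains more than one structure; keeping the first")
  rows <- strsplit(trimws(lines[2L:(n + 1L)]), "\\s+")
  bad <- which(vapply(rows, length, 1L) < 6L)
  if (length(bad)) stop("CT row ", bad[[1L]] , " has fewer than 6 columns")
  mat <- t(vapply(rows, function(r) r[1:6], character(6L)))
  idx <- suppressWarnings(as.integer(mat[, 1L]))
  partner <- suppressWarnings(as.integer(mat[, 5L]))
  if (any(is.na(idx)) || any(is.na(partner)))
    stop("non-integer index or partner field in CT file: ", path)
  if (!identical(idx, seq_len(n)))
    stop("CT rows are not numbered 1..", n)
  seq <- paste(mat[, 2L], collapse = "")
  # symmetry: partner[partner[i]] == i for every paired i
  paired <- which(partner > 0L)
  if (any(partner[paired] > n))
    stop("partner index out of range in CT file: ", path)
  back <- partner[partner[paired]]
  if (any(back != paired)) {
    k <- paired[which(back != paired)[[1L]]]
    stop(sprintf("inconsistent partners in CT file: row %d says %d but row %d says %d",
                 k, partner[k], partner[k], partner[partner[k]]))
  }
  keep <- paired[paired < partner[paired]]
  pairs <- cbind(keep, partner[keep])
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  rna_record(id, seq, pairs, family = family)
}

#' Write a record as a CT file
#'
#' Emits the standard 6-column layout with partner 0 for unpaired bases and
#' both directions of every pair filled in.
#'
#' @param record An [rna_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct <- function(record, path) {
  n <- seq_length(record)
  partner <- integer(n)
  if (nrow(record$pairs)) {
    partner[record$pairs[, 1L]] <- record$pairs[, 2L]
    partner[record$pairs[, 2L]] <- record$pairs[, 1L]
  }
  bases <- strsplit(record$sequence, "")[[1L]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %s", n, record$id), con)
  if (n > 0L)
    writeLines(sprintf("%d %s %d %d %d %d",
                       seq_len(n), bases, seq_len(n) - 1L,
                       c(seq_len(n - 1L) + 1L, 0L)[seq_len(n)],
                       partner, seq_len(n)), con)
  invisible(path)
}

.BRACKET_OPEN  <- c("(", "[", "{", "<")
.BRACKET_CLOSE <- c(")", "]", "}", ">")

#' Parse a dot-bracket structure string
#'
#' Unpaired positions are dots; paired positions are matched brackets, with
#' additional bracket alphabets (`[]`, `{}`, `<>`) encoding pairs that cross
#' the primary layer (pseudoknots).
#'
#' @param s Structure string over `. ( ) [ ] { } < >`.
#' @return Two-column integer matrix of 1-based pairs, `i < j`.
#' @export
parse_dotbracket <- function(s) {
  chars <- strsplit(s, "")[[1L]]
  bad <- setdiff(unique(chars), c(".", .BRACKET_OPEN, .BRACKET_CLOSE))
  if (length(bad))
    stop("invalid dot-bracket character(s): ", paste(bad, collapse = " "))
  pairs <- list()
  for (layer in seq_along(.BRACKET_OPEN)) {
    stack <- integer(0)
    op <- .BRACKET_OPEN[[layer]]; cl <- .BRACKET_CLOSE[[layer]]
    for (p in seq_along(chars)) {
      if (chars[[p]] == op) {
        stack <- c(stack, p)
      } else if (chars[[p]] == cl) {
        if (!length(stack)) stop("unbalanced brackets: unmatched '", cl, "'")
        pairs[[length(pairs) + 1L]] <- c(stack[[length(stack)]], p)
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack)) stop("unbalanced brackets: unmatched '", op, "'")
  }
  if (!length(pairs)) return(matrix(integer(0), ncol = 2L,
                                    dimnames = list(NULL, c("i", "j"))))
  m <- do.call(rbind, pairs)
  m <- m[order(m[, 1L]), , drop = FALSE]
  storage.mode(m) <- "integer"
  colnames(m) <- c("i", "j")
  m
}

#' Render a record's pairs as a dot-bracket string
#'
#' Nested pairs use `()`; crossing pairs are assigned greedily (left to
#' right) to the lowest bracket layer in which they cross no
#' already-assigned pair, matching the common pseudoknot extension of the
#' format.
#'
#' @param record An [rna_record()].
#' @return Dot-bracket string of the record's length.
#' @export
to_dotbracket <- function(record) {
  n <- seq_length(record)
  chars <- rep(".", n)
  pairs <- record$pairs
  if (nrow(pairs)) {
    layers <- list()  # each: matrix of assigned pairs
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      placed <- FALSE
      for (l in seq_len(length(layers) + 1L)) {
        if (l > length(layers)) layers[[l]] <- matrix(integer(0), ncol = 2L)
        lay <- layers[[l]]
        crosses <- nrow(lay) > 0L &&
          any((lay[, 1L] < i & i < lay[, 2L] & lay[, 2L] < j) |
              (i < lay[, 1L] & lay[, 1L] < j & j < lay[, 2L]))
        if (!crosses) {
          if (l > length(.BRACKET_OPEN))
            stop("structure needs more crossing layers than available bracket alphabets")
          layers[[l]] <- rbind(lay, c(i, j))
          chars[i] <- .BRACKET_OPEN[[l]]
          chars[j] <- .BRACKET_CLOSE[[l]]
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("failed to place pair")  # unreachable
    }
  }
  paste(chars, collapse = "")
}

#' Compute a structure's shadow
#'
#' The shadow is the binary paired/unpaired labelling of each nucleotide:
#' position i is 1 exactly when i occurs in some pair of the record
#' (crossing pairs included).
#'
#' @param record An [rna_record()].
#' @return Integer vector of 0/1, length `seq_length(record)`.
#' @export
shadow_of <- function(record) {
  v <- integer(seq_length(record))
  v[as.vector(record$pairs)] <- 1L
  v
}

.BASE_ROWS <- c(A = 1L, C = 2L, G = 3L, U = 4L)

#' One-hot encode a record for the shadow network
#'
#' Sequences become 4 x `pad_to` one-hot matrices (row order A, C, G, U) and
#' shadows become length-`pad_to` 0/1 vectors, both zero-padded at the 3'
#' end. Ambiguity letters encode as all-zero columns, indistinguishable from
#' padding — the most conservative treatment.
#'
#' @param record An [rna_record()].
#' @param pad_to Padded length (default 512).
#' @return List with elements `x` (4 x pad_to matrix), `y` (length-pad_to
#'   integer vector) and `true_length`.
#' @export
encode_record <- function(record, pad_to = 512L) {
  n <- seq_length(record)
  if (n > pad_to)
    stop("sequence length ", n, " exceeds pad_to = ", pad_to)
  x <- matrix(0, nrow = 4L, ncol = pad_to,
              dimnames = list(c("A", "C", "G", "U"), NULL))
  if (n > 0L) {
    bases <- strsplit(record$sequence, "")[[1L]]
    rows <- .BASE_ROWS[bases]              # NA for ambiguity letters
    ok <- which(!is.na(rows))
    x[cbind(rows[ok], ok)] <- 1
  }
  y <- integer(pad_to)
  y[seq_len(n)] <- shadow_of(record)
  list(x = x, y = y, true_length = n)
}

#' Drop records longer than a maximum length
#'
#' Keeps exactly the records whose sequence length does not exceed
#' `max_len`, preserving order, and reports how many were removed.
#'
#' @param records List of [rna_record()]s.
#' @param max_len Maximum length kept (default 512).
#' @param quiet Suppress the removal message.
#' @return Filtered list.
#' @export
length_filter <- function(records, max_len = 512L, quiet = FALSE) {
  keep <- vapply(records, seq_length, 1L) <= max_len
  if (!quiet)
    message(sum(!keep), " record(s) longer than ", max_len, " nt removed; ",
            sum(keep), " remain")
  records[keep]
}

#' Read sequences from a FASTA file as records
#'
#' Sequence-only input for prediction runs; records get empty pair sets.
#'
#' @param path FASTA file path.
#' @param family Optional family label for all records.
#' @return List of [rna_record()]s.
#' @export
read_fasta_records <- function(path, family = NA_character_) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readBStringSet(path)
    seqs <- as.character(set)
    ids <- sub("\\s.*$", "", names(set))
  } else {
    lines <- readLines(path, warn = FALSE)
    hdr <- grepl("^>", lines)
    ids <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr]))
    grp <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, "", collapse = "")
  }
  mapply(function(s, i) rna_record(i, s, family = family),
         seqs, ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write records to per-record CT files plus a manifest
#'
#' @param records List of [rna_record()]s.
#' @param dir Output directory (created if needed).
#' @return Tibble manifest (id, family, length, path), invisibly; also
#'   written as `manifest.csv` in `dir`.
#' @export
write_corpus_ct <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(records, function(r) {
    p <- file.path(dir, paste0(r$id, ".ct"))
    write_ct(r, p)
    p
  }, "")
  manifest <- tibble::tibble(
    id = vapply(records, `[[`, "", "id"),
    family = vapply(records, `[[`, "", "family"),
    length = vapply(records, seq_length, 1L),
    path = paths
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
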