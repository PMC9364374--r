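#' Specify a synthetic RNA family
#'
#' A synthetic family emulates the statistical property real curated corpora
#' rest on: members share a near-identical conserved secondary structure
#' while their sequences have diverged. Here the conservation is exact —
#' every member carries the family's consensus pair set — and divergence is
#' controlled by `resample_fraction`, the expected fraction of positions
#' re-drawn per member under the same base-pairing constraints.
#'
#' @param name Family label.
#' @param n_members Number of member records.
#' @param length Sequence length (nt), `>= 10`.
#' @param structure_seed Seed for the consensus structure draw; families with
#'   different structure seeds have unrelated structures.
#' @param pair_weights Probabilities over pair types GC, CG, AU, UA, GU, UG.
#'   The default favours G-C pairs so that minimum-free-energy folds of
#'   member sequences stay close to the consensus.
#' @param unpaired_weights Probabilities over A, C, G, U for unpaired
#'   positions.
#' @param resample_fraction Proportion of positions re-drawn per member.
#'   The default 0.25 yields a mean pairwise sequence identity just under
#'   60% between members while their structures stay identical — the
#'   conserved-structure/diverged-sequence regime real RNA families show.
#' @return A `family_spec` list.
#' @export
family_spec <- function(name, n_members, length, structure_seed,
                        pair_weights = c(GC = 0.35, CG = 0.35, AU = 0.12,
                                         UA = 0.12, GU = 0.03, UG = 0.03),
                        unpaired_weights = c(A = 0.3, C = 0.2, G = 0.2, U = 0.3),
                        resample_fraction = 0.25) {
  stopifnot(length >= 10L, n_members >= 1L,
            abs(sum(pair_weights) - 1) < 1e-8,
            abs(sum(unpaired_weights) - 1) < 1e-8,
            resample_fraction >= 0, resample_fraction <= 1)
  structure(list(name = name, n_members = as.integer(n_members),
                 length = as.integer(length),
                 structure_seed = as.integer(structure_seed),
                 pair_weights = pair_weights,
                 unpaired_weights = unpaired_weights,
                 resample_fraction = resample_fraction),
            class = "family_spec")
}

#' Draw a random non-crossing secondary structure
#'
#' Recursive stem/loop construction: helix lengths are geometric with mean
#' 4 pairs, terminal/internal loop stretches are uniform on 3–8 nt, and
#' regions branch into two sub-regions with probability 0.2. All emitted
#' pairs are non-crossing and satisfy the minimum hairpin constraint
#' `j - i > 3`.
#'
#' @param length Sequence length, `>= 10`.
#' @param seed Optional seed; the draw is deterministic given the seed.
#' @param stem_mean Mean helix length in pairs.
#' @param loop_range Inclusive range of loop stretch sizes.
#' @param branch_prob Probability a region splits into two sub-regions.
#' @return Two-column integer pair matrix.
#' @export
sample_structure <- function(length, seed = NULL, stem_mean = 4,
                             loop_range = c(3L, 8L), branch_prob = 0.2) {
  stopifnot(length >= 10L)
  draw <- function() {
    pairs <- list()
    loop_draw <- function() sample(loop_range[[1L]]:loop_range[[2L]], 1L)
    # fill region [i, j]; a helix of s pairs needs 2s + 3 positions
    fill <- function(i, j) {
      L <- j - i + 1L
      if (L < 5L) return(invisible(NULL))        # too short for any pair
      if (L >= 24L && runif(1) < branch_prob) {
        m <- i + sample(10L:(L - 11L), 1L)       # both halves can hold a stem
        fill(i, m); fill(m + 1L, j)
        return(invisible(NULL))
      }
      # unpaired margins, then a helix closing the region, then recurse inside
      lead <- sample(0L:2L, 1L); trail <- sample(0L:2L, 1L)
      a <- i + lead; b <- j - trail
      if (b - a < 4L) return(invisible(NULL))    # margins ate the stem room
      s_max <- (b - a - 2L) %/% 2L               # keep interior >= 3
      s <- min(1L + rgeom(1L, 1 / stem_mean), s_max)
      if (s < 1L) return(invisible(NULL))
      for (t in seq_len(s) - 1L)
        pairs[[length(pairs) + 1L]] <<- c(a + t, b - t)
      ii <- a + s; jj <- b - s                   # interior region
      if (jj - ii + 1L > loop_range[[2L]]) {
        ld <- loop_draw()                        # interior loop, then recurse
        fill(ii + (ld + 1L) %/% 2L, jj - ld %/% 2L)
      }                                          # else: hairpin loop
      invisible(NULL)
    }
    fill(1L, as.integer(length))
    if (!length(pairs)) return(matrix(integer(0), ncol = 2L))
    m <- do.call(rbind, pairs)
    storage.mode(m) <- "integer"
    m[order(m[, 1L]), , drop = FALSE]
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

.PAIR_TYPES <- rbind(GC = c("G", "C"), CG = c("C", "G"), AU = c("A", "U"),
                     UA = c("U", "A"), GU = c("G", "U"), UG = c("U", "G"))

# Draw one member sequence compatible with a consensus structure.
.draw_member_sequence <- function(n, pairs, pair_weights, unpaired_weights) {
  bases <- character(n)
  unp <- setdiff(seq_len(n), as.vector(pairs))
  bases[unp] <- sample(names(unpaired_weights), length(unp), replace = TRUE,
                       prob = unpaired_weights)
  if (nrow(pairs)) {
    types <- sample(rownames(.PAIR_TYPES), nrow(pairs), replace = TRUE,
                    prob = pair_weights[rownames(.PAIR_TYPES)])
    bases[pairs[, 1L]] <- .PAIR_TYPES[types, 1L]
    bases[pairs[, 2L]] <- .PAIR_TYPES[types, 2L]
  }
  bases
}

#' Generate the members of one synthetic family
#'
#' Draws the family's consensus structure and one structure-compatible
#' consensus sequence from `structure_seed` (paired positions drawn jointly
#' so every pair is canonical; unpaired positions independently). Each
#' member starts from the consensus sequence and re-draws
#' `resample_fraction` of its positions under the same constraints —
#' unpaired positions independently, pairs jointly so they stay canonical.
#' All members carry the identical pair set and the family label, emulating
#' diverged sequences with conserved structure.
#'
#' @param spec A [family_spec()].
#' @param seed Seed for the member sequence draws (the structure uses
#'   `spec$structure_seed`).
#' @return List of [rna_record()]s.
#' @export
sample_family <- function(spec, seed = 1L) {
  pairs <- sample_structure(spec$length, seed = spec$structure_seed)
  n <- spec$length
  consensus <- with_seed(spec$structure_seed + 1L,
                         .draw_member_sequence(n, pairs, spec$pair_weights,
                                               spec$unpaired_weights))
  with_seed(seed, {
    lapply(seq_len(spec$n_members), function(k) {
      bases <- consensus
      if (spec$resample_fraction > 0) {
        hit <- runif(n) < spec$resample_fraction
        # unpaired positions re-draw independently
        unp <- setdiff(which(hit), as.vector(pairs))
        if (length(unp))
          bases[unp] <- sample(names(spec$unpaired_weights), length(unp),
                               replace = TRUE, prob = spec$unpaired_weights)
        # a pair re-draws its type jointly if either endpoint was hit
        if (nrow(pairs)) {
          hp <- which(hit[pairs[, 1L]] | hit[pairs[, 2L]])
          if (length(hp)) {
            types <- sample(rownames(.PAIR_TYPES), length(hp), replace = TRUE,
                            prob = spec$pair_weights[rownames(.PAIR_TYPES)])
            bases[pairs[hp, 1L]] <- .PAIR_TYPES[types, 1L]
            bases[pairs[hp, 2L]] <- .PAIR_TYPES[types, 2L]
          }
        }
      }
      rna_record(sprintf("%s_%03d", spec$name, k),
                 paste(bases, collapse = ""), pairs, family = spec$name)
    })
  })
}

#' Default six-family benchmark fixture specification
#'
#' Six structurally unrelated families of 40 members each with lengths 60,
#' 80, 100, 120, 150 and 200 nt — small enough for CPU training in minutes
#' while preserving the corpus shape the benchmark needs (several families,
#' conserved structure within, divergence across).
#'
#' @param n_members Members per family (default 40).
#' @return List of [family_spec()]s.
#' @export
default_corpus_specs <- function(n_members = 40L) {
  lens <- c(60L, 80L, 100L, 120L, 150L, 200L)
  mapply(function(i, len)
    family_spec(sprintf("fam%02d_len%d", i, len), n_members, len,
                structure_seed = 1000L + 17L * i),
    seq_along(lens), lens, SIMPLIFY = FALSE)
}

#' Generate a multi-family synthetic corpus
#'
#' @param specs List of [family_spec()]s with distinct names and structure
#'   seeds.
#' @param seed Master seed for member sequence draws.
#' @return List of [rna_record()]s, families concatenated in spec order.
#' @export
generate_corpus <- function(specs, seed = 1L) {
  stopifnot(length(specs) >= 1L)
  nms <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate family names in specs")
  out <- list()
  for (k in seq_along(specs))
    out <- c(out, sample_family(specs[[k]], seed = seed + 131L * k))
  out
}

#' Mean pairwise sequence identity of a set of records
#'
#' Fraction of positions identical between two aligned equal-length
#' sequences, averaged over all (or `max_pairs` sampled) record pairs.
#'
#' @param records List of equal-length [rna_record()]s.
#' @param max_pairs Cap on compared pairs.
#' @return Mean identity in \[0, 1\].
#' @export
mean_pairwise_identity <- function(records, max_pairs = 200L) {
  stopifnot(length(records) >= 2L)
  mats <- lapply(records, function(r) strsplit(r$sequence, "")[[1L]])
  combs <- utils::combn(length(records), 2L)
  if (ncol(combs) > max_pairs) combs <- combs[, seq_len(max_pairs), drop = FALSE]
  mean(apply(combs, 2L, function(ab)
    mean(mats[[ab[[1L]]]] == mats[[ab[[2L]]]])))
}
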