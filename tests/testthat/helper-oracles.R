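# Independent oracles used to cross-check the package's algorithms.
# Each is a deliberately naive implementation (enumeration, recursion,
# exhaustive comparison) kept separate from the code paths it checks.

# Enumerate every non-crossing structure over positions i..j with the
# minimum hairpin constraint j - i > min_sep, as a list of pair matrices.
enumerate_structures <- function(n, min_sep = 3L) {
  memo <- new.env()
  rec <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), ncol = 2L)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- lapply(rec(i + 1L, j), identity)           # i unpaired
    ks <- if (j >= i + min_sep + 1L) (i + min_sep + 1L):j else integer(0)
    for (k in ks) {
      inner <- rec(i + 1L, k - 1L)
      outer <- rec(k + 1L, j)
      for (a in inner) for (b in outer)
        out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

# Brute-force minimum energy over all enumerated structures.
brute_force_fold <- function(sequence, dg = NULL,
                             pair_energy = c(GC = -3, AU = -2, GU = -1)) {
  bases <- strsplit(sequence, "")[[1L]]
  n <- length(bases)
  pe <- function(i, j) {
    key <- paste0(sort(c(bases[[i]], bases[[j]])), collapse = "")
    e <- switch(key, "CG" = pair_energy[["GC"]], "AU" = pair_energy[["AU"]],
                "GU" = pair_energy[["GU"]], Inf)
    if (is.finite(e) && !is.null(dg)) e <- e + dg[[i]] + dg[[j]]
    e
  }
  best <- 0; best_pairs <- matrix(integer(0), ncol = 2L)
  for (st in enumerate_structures(n)) {
    if (nrow(st)) {
      es <- vapply(seq_len(nrow(st)), function(r) pe(st[r, 1L], st[r, 2L]), 0)
      if (any(!is.finite(es))) next
      tot <- sum(es)
    } else tot <- 0
    if (tot < best - 1e-9) { best <- tot; best_pairs <- st }
  }
  list(score = best, pairs = best_pairs)
}

# Brute-force slippage matcher: per-pair loop over the five displacement
# variants, counted independently on each side.
brute_slippage <- function(predicted, reference, slippage = TRUE) {
  in_set <- function(i, j, set) {
    if (!NROW(set)) return(FALSE)
    any(set[, 1L] == i & set[, 2L] == j)
  }
  matched <- function(a, b) {
    if (!NROW(a)) return(0L)
    sum(vapply(seq_len(nrow(a)), function(r) {
      i <- a[r, 1L]; j <- a[r, 2L]
      hit <- in_set(i, j, b)
      if (slippage)
        hit <- hit || in_set(i - 1L, j, b) || in_set(i + 1L, j, b) ||
          in_set(i, j - 1L, b) || in_set(i, j + 1L, b)
      hit
    }, FALSE))
  }
  list(matched_pred = matched(predicted, reference),
       matched_ref = matched(reference, predicted))
}

# Exhaustive pairwise-comparison AUC: fraction of (paired, unpaired)
# position pairs won, ties half.
brute_auc <- function(y_hat, shadow) {
  p1 <- y_hat[shadow == 1L]; p0 <- y_hat[shadow == 0L]
  if (!length(p1) || !length(p0)) return(NA_real_)
  tot <- 0
  for (a in p1) for (b in p0)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(p1) * length(p0))
}

# Independent ordered-forest edit distance by memoized textbook recursion
# on (rightmost-root decomposition of) forests. Trees are nested lists:
# list(label = chr, children = list(...)).
oracle_ted <- function(t1, t2) {
  memo <- new.env()
  fkey <- function(f) paste(vapply(f, tkey, ""), collapse = ",")
  tkey <- function(t) paste0(t$label, "(", fkey(t$children), ")")
  fsize <- function(f) sum(vapply(f, function(t) 1L + fsize(t$children), 0L))
  fdist <- function(f1, f2) {
    if (!length(f1)) return(fsize(f2))
    if (!length(f2)) return(fsize(f1))
    key <- paste(fkey(f1), "|", fkey(f2))
    if (!is.null(memo[[key]])) return(memo[[key]])
    a <- f1[[length(f1)]]; f1r <- f1[-length(f1)]
    b <- f2[[length(f2)]]; f2r <- f2[-length(f2)]
    d <- min(
      fdist(c(f1r, a$children), f2) + 1,                       # delete a
      fdist(f1, c(f2r, b$children)) + 1,                       # insert b
      fdist(f1r, f2r) + fdist(a$children, b$children) +
        (a$label != b$label)                                   # match a~b
    )
    memo[[key]] <- d
    d
  }
  fdist(list(t1), list(t2))
}

# Build the nested-list tree encoding of a record for oracle_ted,
# mirroring the pair/leaf encoding but through an independent code path.
oracle_tree <- function(record) {
  n <- seq_length(record)
  pairs <- record$pairs
  partner <- integer(n)
  if (nrow(pairs)) {
    partner[pairs[, 1L]] <- pairs[, 2L]
    partner[pairs[, 2L]] <- pairs[, 1L]
  }
  build <- function(i, j) {
    kids <- list()
    p <- i
    while (p <= j) {
      if (p <= n && partner[p] > p) {
        kids[[length(kids) + 1L]] <- list(label = "P",
                                          children = build(p + 1L, partner[p] - 1L))
        p <- partner[p] + 1L
      } else {
        kids[[length(kids) + 1L]] <- list(label = "U", children = list())
        p <- p + 1L
      }
    }
    kids
  }
  list(label = "R", children = if (n > 0L) build(1L, n) else list())
}

# Small random corpus helper used across test files.
tiny_corpus <- function(n_fam = 3L, members = 6L, lens = c(40L, 50L, 60L),
                        seed_base = 100L, resample = 0.25) {
  specs <- lapply(seq_len(n_fam), function(i)
    family_spec(sprintf("tf%02d", i), members, lens[((i - 1L) %% length(lens)) + 1L],
                structure_seed = seed_base + 31L * i,
                resample_fraction = resample))
  generate_corpus(specs, seed = seed_base)
}

# Random pseudoknot-bearing record: a sampled nested structure plus a few
# crossing pairs injected among leftover unpaired positions.
random_pk_record <- function(id, len = 60L, seed = 1L) {
  pairs <- sample_structure(len, seed = seed)
  set.seed(seed + 1000L)
  free <- setdiff(seq_len(len), as.vector(pairs))
  cross <- NULL
  # try to add one pair crossing an existing pair
  if (nrow(pairs) && length(free) >= 6L) {
    p <- pairs[sample(nrow(pairs), 1L), ]
    lo <- free[free > p[[1L]] & free < p[[2L]]]
    hi <- free[free > p[[2L]]]
    if (length(lo) && length(hi))
      cross <- c(lo[[sample.int(length(lo), 1L)]],
                 hi[[sample.int(length(hi), 1L)]])
  }
  if (!is.null(cross) && cross[[2L]] - cross[[1L]] > 3L)
    pairs <- rbind(pairs, cross)
  seqs <- paste(sample(c("A", "C", "G", "U"), len, TRUE), collapse = "")
  rna_record(id, seqs, pairs, family = "pk")
}
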