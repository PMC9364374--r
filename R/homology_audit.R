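#' Encode a secondary structure as an ordered rooted tree
#'
#' Internal nodes are base pairs, leaves are unpaired nucleotides attached
#' to the innermost enclosing pair (or to the virtual root), and children
#' follow 5'→3' order, so the nesting of pairs becomes ancestry. Crossing
#' pairs cannot be nested; the maximum-cardinality non-crossing subset of
#' the record's pairs (computed by dynamic programming) is kept first and
#' the stripped endpoints become ordinary leaves.
#'
#' @param record An [rna_record()].
#' @return A `structure_tree`: list with postorder integer `labels`
#'   (1 = root, 2 = pair, 3 = leaf), `lml` (leftmost-leaf-descendant
#'   postorder indices) and `n_nodes`.
#' @export
structure_to_tree <- function(record) {
  n <- seq_length(record)
  pairs <- record$pairs
  if (nrow(pairs) > 1L)
    pairs <- max_noncross_subset_cpp(n, pairs)
  partner <- integer(n)
  if (nrow(pairs)) {
    partner[pairs[, 1L]] <- pairs[, 2L]
    partner[pairs[, 2L]] <- pairs[, 1L]
  }

  labels <- integer(0)
  lml <- integer(0)
  # postorder emission; returns the postorder index of the subtree root
  emit <- function(lab, child_idx) {
    k <- length(labels) + 1L
    labels[[k]] <<- lab
    lml[[k]] <<- if (length(child_idx)) lml[[child_idx[[1L]]]] else k
    k
  }
  build_region <- function(i, j) {   # returns child postorder indices
    kids <- integer(0)
    p <- i
    while (p <= j) {
      if (partner[p] > p) {
        inner <- build_region(p + 1L, partner[p] - 1L)
        kids <- c(kids, emit(2L, inner))
        p <- partner[p] + 1L
      } else {
        kids <- c(kids, emit(3L, integer(0)))
        p <- p + 1L
      }
    }
    kids
  }
  root_kids <- if (n > 0L) build_region(1L, n) else integer(0)
  emit(1L, root_kids)
  structure(list(labels = labels, lml = lml, n_nodes = length(labels)),
            class = "structure_tree")
}

#' Ordered tree edit distance between two structure trees
#'
#' Minimum total cost of node insertions, deletions and relabelings (unit
#' costs) transforming one ordered tree into the other, computed by the
#' Zhang–Shasha dynamic program. Symmetric by construction.
#'
#' @param a,b [structure_to_tree()] objects.
#' @return Non-negative numeric distance.
#' @export
tree_edit_distance <- function(a, b) {
  stopifnot(inherits(a, "structure_tree"), inherits(b, "structure_tree"))
  tree_edit_distance_cpp(a$labels, a$lml, b$labels, b$lml)
}

#' Mean minimum tree edit distance from a test set to a training set
#'
#' For each test record, the distance to its structurally nearest training
#' record; the mean of those minima quantifies how much near-identical
#' structure a split leaks from training into testing (near 0 = heavy
#' leakage, large = structurally novel test set). All-vs-all tree edit
#' distance is expensive, so both sides are (seeded) subsampled above the
#' configurable caps, and the sizes actually used are reported.
#'
#' @param test,train Nonempty lists of [rna_record()]s.
#' @param max_test,max_train Subsampling caps.
#' @param seed Subsampling seed.
#' @return List: `mean_min` (the summary number), `per_test` (tibble:
#'   test_id, nearest_train_id, distance), `n_test_used`, `n_train_used`.
#' @export
mean_min_ted <- function(test, train, max_test = 50L, max_train = 100L,
                         seed = 1L) {
  if (!length(test) || !length(train))
    stop("both test and train sets must be nonempty")
  if (length(test) > max_test)
    test <- with_seed(seed, sample(test, max_test))
  if (length(train) > max_train)
    train <- with_seed(seed + 1L, sample(train, max_train))
  ttrees <- lapply(test, structure_to_tree)
  rtrees <- lapply(train, structure_to_tree)
  per <- lapply(seq_along(test), function(i) {
    d <- vapply(rtrees, tree_edit_distance, 0, a = ttrees[[i]])
    k <- which.min(d)
    tibble::tibble(test_id = test[[i]]$id, nearest_train_id = train[[k]]$id,
                   distance = d[[k]])
  })
  per <- dplyr::bind_rows(per)
  list(mean_min = mean(per$distance), per_test = per,
       n_test_used = length(test), n_train_used = length(train))
}

#' Audit the train/test structural overlap of split plans
#'
#' Runs [mean_min_ted()] for every plan in a split and returns one row per
#' fold — the instrument for comparing how much structural homology
#' different splitting strategies leak.
#'
#' @param plans List of [split_plan()]s.
#' @param records Corpus the plans index into.
#' @param ... Passed to [mean_min_ted()] (caps, seed).
#' @return Tibble: fold, mean_min_ted, n_test_used, n_train_used.
#' @export
audit_splits <- function(plans, records, ...) {
  ids <- record_ids(records)
  rows <- lapply(plans, function(p) {
    res <- mean_min_ted(records[ids %in% p$test_ids],
                        records[ids %in% c(p$train_ids, p$val_ids)], ...)
    tibble::tibble(fold = as.character(p$fold_id),
                   mean_min_ted = res$mean_min,
                   n_test_used = res$n_test_used,
                   n_train_used = res$n_train_used)
  })
  dplyr::bind_rows(rows)
}
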