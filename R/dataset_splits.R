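#' Split plans for intra- and inter-family benchmarking
#'
#' A split plan records one cross-validation fold's membership: disjoint
#' train/validation/test id sets whose union is the full corpus.
#'
#' @param fold_id Integer fold index or family name.
#' @param train_ids,val_ids,test_ids Character vectors of record ids.
#' @param seed Seed used to build the plan (`NA` for deterministic plans).
#' @param k Number of folds for k-fold plans, `NA` otherwise.
#' @return A `split_plan` list.
#' @export
split_plan <- function(fold_id, train_ids, val_ids = character(0), test_ids,
                       seed = NA_integer_, k = NA_integer_) {
  all <- c(train_ids, val_ids, test_ids)
  if (anyDuplicated(all))
    stop("train/val/test sets must be pairwise disjoint")
  structure(list(fold_id = fold_id, train_ids = train_ids, val_ids = val_ids,
                 test_ids = test_ids, seed = seed, k = k),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> fold %s: %d train / %d val / %d test\n",
              x$fold_id, length(x$train_ids), length(x$val_ids),
              length(x$test_ids)))
  invisible(x)
}

record_ids <- function(records) vapply(records, `[[`, "", "id")

#' k-fold cross-validation split
#'
#' Seeded uniform shuffle, then k contiguous chunks as test sets; no family
#' stratification. Every record lands in exactly one test set and test-set
#' sizes differ by at most one. Validation sets are empty; carve them with
#' [carve_validation()].
#'
#' @param records List of [rna_record()]s.
#' @param k Number of folds (default 5).
#' @param seed Shuffle seed.
#' @return List of `k` [split_plan()]s.
#' @export
kfold_split <- function(records, k = 5L, seed = 1L) {
  if (k < 2L) stop("k must be at least 2")
  ids <- record_ids(records)
  if (length(ids) < k) stop("need at least k records")
  shuffled <- with_seed(seed, sample(ids))
  fold_of <- rep(seq_len(k), length.out = length(ids))
  fold_of <- sort(fold_of)              # contiguous chunks, sizes differ <= 1
  lapply(seq_len(k), function(f) {
    test <- shuffled[fold_of == f]
    split_plan(f, train_ids = setdiff(shuffled, test), test_ids = test,
               seed = seed, k = as.integer(k))
  })
}

#' Family-fold (leave-one-family-out) cross-validation split
#'
#' One plan per family: that family's records form the test set and all
#' other families form the training pool, so no family label ever crosses
#' the train/test boundary.
#'
#' @param records List of [rna_record()]s with family labels.
#' @return List of [split_plan()]s, one per family (sorted by name).
#' @export
familyfold_split <- function(records) {
  fams <- vapply(records, `[[`, "", "family")
  if (anyNA(fams)) stop("all records need family labels for family-fold splits")
  ids <- record_ids(records)
  ufams <- sort(unique(fams))
  if (length(ufams) < 2L)
    stop("cannot form an inter-family split from a single family")
  lapply(ufams, function(f)
    split_plan(f, train_ids = ids[fams != f], test_ids = ids[fams == f]))
}

#' Carve a validation subset out of a plan's training set
#'
#' Moves a seeded-random fraction (default 10%) of the training records into
#' the validation set, rounding to the nearest integer with a floor of one;
#' the test set is untouched. For family-fold plans the validation set
#' deliberately still shares families with training — the benchmark's point
#' is what that does to early stopping.
#'
#' @param plan A [split_plan()] with empty `val_ids`.
#' @param fraction Proportion moved (in (0, 1)).
#' @param seed Sampling seed.
#' @return A new [split_plan()].
#' @export
carve_validation <- function(plan, fraction = 0.10, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (length(plan$val_ids)) stop("plan already has a validation set")
  n <- length(plan$train_ids)
  n_val <- max(1L, as.integer(round(fraction * n)))
  val <- with_seed(seed, sample(plan$train_ids, n_val))
  split_plan(plan$fold_id, train_ids = setdiff(plan$train_ids, val),
             val_ids = val, test_ids = plan$test_ids,
             seed = plan$seed, k = plan$k)
}

#' Serialize split plans to JSON
#'
#' Plans are written as an array of `{fold, train, val, test, seed}` objects
#' so third-party predictors can consume identical splits.
#'
#' @param plans List of [split_plan()]s.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_split_json <- function(plans, path) {
  obj <- lapply(plans, function(p)
    list(fold = p$fold_id, train = I(p$train_ids), val = I(p$val_ids),
         test = I(p$test_ids), seed = p$seed, k = p$k))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read split plans back from JSON
#' @param path JSON path written by [write_split_json()].
#' @return List of [split_plan()]s.
#' @export
read_split_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(obj)), function(r)
    split_plan(obj$fold[[r]],
               train_ids = unlist(obj$train[r]),
               val_ids = as.character(unlist(obj$val[r])),
               test_ids = unlist(obj$test[r]),
               seed = if (is.null(obj$seed[[r]])) NA_integer_ else obj$seed[[r]],
               k = if (is.null(obj$k[[r]])) NA_integer_ else obj$k[[r]]))
}
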