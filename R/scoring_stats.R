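#' Slippage-tolerant base-pair scoring
#'
#' Compares a predicted pair set against a reference allowing each pair to
#' be displaced by one nucleotide on either side: a predicted pair (i, j)
#' matches if the reference contains (i, j), (i±1, j) or (i, j±1), and
#' symmetrically for reference pairs against the prediction. The two
#' directions are counted independently (no one-to-one assignment), the
#' convention of the standard structure-comparison lineage. Pseudoknotted
#' reference pairs participate fully.
#'
#' PPV with zero predicted pairs is 0 when the reference is nonempty; when
#' both sets are empty all three scores are 1 (a correctly predicted
#' unpaired molecule).
#'
#' @param predicted,reference Two-column pair matrices.
#' @param n Sequence length (for index validation).
#' @param slippage Allow the ±1 displacement (default TRUE).
#' @return List: `matched_pred`, `matched_ref`, `n_pred`, `n_ref`, `ppv`,
#'   `sensitivity`, `f1`.
#' @export
score_pairs_slippage <- function(predicted, reference, n, slippage = TRUE) {
  predicted <- .as_pairs(predicted)
  reference <- .as_pairs(reference)
  if ((nrow(predicted) && max(predicted) > n) ||
      (nrow(reference) && max(reference) > n) ||
      (nrow(predicted) && min(predicted) < 1L) ||
      (nrow(reference) && min(reference) < 1L))
    stop("pair index out of range [1, ", n, "]")
  np <- nrow(predicted); nr <- nrow(reference)
  if (np == 0L && nr == 0L)
    return(list(matched_pred = 0L, matched_ref = 0L, n_pred = 0L, n_ref = 0L,
                ppv = 1, sensitivity = 1, f1 = 1))
  key <- function(m) m[, 1L] * (n + 2L) + m[, 2L]
  match_count <- function(a, b) {
    if (!nrow(a) || !nrow(b)) return(0L)
    bk <- key(b)
    hit <- key(a) %in% bk
    if (slippage) {
      hit <- hit |
        (key(cbind(a[, 1L] - 1L, a[, 2L])) %in% bk) |
        (key(cbind(a[, 1L] + 1L, a[, 2L])) %in% bk) |
        (key(cbind(a[, 1L], a[, 2L] - 1L)) %in% bk) |
        (key(cbind(a[, 1L], a[, 2L] + 1L)) %in% bk)
    }
    sum(hit)
  }
  mp <- match_count(predicted, reference)
  mr <- match_count(reference, predicted)
  ppv <- if (np > 0L) mp / np else 0
  sens <- if (nr > 0L) mr / nr else 0
  list(matched_pred = mp, matched_ref = mr, n_pred = np, n_ref = nr,
       ppv = ppv, sensitivity = sens, f1 = f1_score(ppv, sens))
}

.as_pairs <- function(p) {
  if (is.null(p) || NROW(p) == 0L) return(matrix(integer(0), ncol = 2L))
  matrix(as.integer(as.matrix(p)), ncol = 2L)
}

#' Harmonic mean of PPV and sensitivity
#' @param ppv,sensitivity Proportions in \[0, 1\].
#' @return F1 score; 0 when both inputs are 0.
#' @export
f1_score <- function(ppv, sensitivity) {
  ifelse(ppv + sensitivity == 0, 0, 2 * ppv * sensitivity / (ppv + sensitivity))
}

#' ROC AUC of a predicted shadow
#'
#' Rank-based (Mann-Whitney) computation of the area under the ROC curve
#' for classifying nucleotides as paired vs unpaired, restricted to the
#' unpadded positions; ties count one half. Interpretable as the
#' probability that a randomly chosen paired position outranks a randomly
#' chosen unpaired one. When the record has no paired or no unpaired
#' positions the AUC is undefined and flagged (`NA`), to be excluded from
#' aggregates.
#'
#' @param y_hat Numeric probability vector.
#' @param shadow 0/1 reference shadow.
#' @param true_length Number of unpadded positions evaluated (default: full
#'   length of `shadow`).
#' @return List: `auc` (possibly `NA`), `n_paired`, `n_unpaired`.
#' @export
auc_shadow <- function(y_hat, shadow, true_length = length(shadow)) {
  idx <- seq_len(true_length)
  y <- shadow[idx]; p <- y_hat[idx]
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    return(list(auc = NA_real_, n_paired = n1, n_unpaired = n0))
  r <- rank(p)                                   # midranks handle ties
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(auc = auc, n_paired = n1, n_unpaired = n0)
}

#' Two-tailed paired t-test
#'
#' Classic paired t on per-sequence score differences. When the differences
#' have zero variance no finite t exists; the result is flagged degenerate
#' with `NA` statistics rather than an error.
#'
#' @param scores_a,scores_b Equal-length numeric vectors paired by sequence.
#' @return List: `t`, `p`, `df`, `degenerate`.
#' @export
paired_ttest <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 2L)
  d <- scores_a - scores_b
  if (sd(d) == 0) {
    if (all(d == 0))                             # identical vectors: t = 0
      return(list(t = 0, p = 1, df = length(d) - 1L, degenerate = FALSE))
    return(list(t = NA_real_, p = NA_real_, df = length(d) - 1L,
                degenerate = TRUE))
  }
  ht <- t.test(scores_a, scores_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       degenerate = FALSE)
}

#' Min-max normalize a vector to \[0, 1\]
#'
#' Used to compare nudge-response curves across families with different
#' underlying prediction performance.
#'
#' @param values Numeric vector, length >= 2, not all equal.
#' @return `(v - min) / (max - min)`.
#' @export
minmax_normalize <- function(values) {
  stopifnot(length(values) >= 2L)
  rng <- range(values)
  if (rng[[1L]] == rng[[2L]]) stop("cannot min-max normalize a constant vector")
  (values - rng[[1L]]) / (rng[[2L]] - rng[[1L]])
}

#' Aggregate per-sequence scores into a per-family report
#'
#' Produces one row per family with the mean of each metric over that
#' family's sequences, plus a final `"Mean"` row holding the UNWEIGHTED mean
#' of the per-family means (families count equally regardless of size).
#' Undefined (`NA`) metric values are excluded from means; the number of
#' contributing sequences per metric is implicit in `n`.
#'
#' @param per_sequence Data frame / tibble with columns `id`, `family` and
#'   one or more numeric metric columns.
#' @return Tibble: `family`, `n`, one mean column per metric, with the
#'   overall `"Mean"` row last.
#' @export
aggregate_report <- function(per_sequence) {
  stopifnot(all(c("id", "family") %in% names(per_sequence)))
  metrics <- setdiff(names(per_sequence), c("id", "family"))
  by_fam <- per_sequence |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(metrics), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop")
  overall <- tibble::tibble(family = "Mean", n = sum(by_fam$n))
  for (m in metrics) overall[[m]] <- mean(by_fam[[m]], na.rm = TRUE)
  dplyr::bind_rows(by_fam, overall)
}

#' @importFrom rlang .data
NULL
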