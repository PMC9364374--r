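#' Benchmark intra- vs inter-family structure prediction
#'
#' The core experiment: for each cross-validation fold, carve a 10%
#' validation set out of the training pool, train the shadow network,
#' predict test-set shadows, convert them to pseudo-free energies with the
#' (deliberately not refit) slope/intercept defaults, fold with the chosen
#' backend and score against the reference structures with slippage. The
#' folding backend run without any pseudo-energy input provides the
#' baseline column, which by construction is identical across split modes.
#' Per-family aggregation puts one row per family plus an unweighted Mean
#' row; paired t-tests compare model vs baseline F1 per family.
#'
#' @param records Corpus of [rna_record()]s with family labels.
#' @param split `"kfold"`, `"familyfold"` or `"both"`.
#' @param config [shadow_config()] for the network.
#' @param params [energy_params()] used to convert shadows to energies.
#' @param backend A [fold_backend()].
#' @param k Folds for the k-fold mode.
#' @param val_fraction Validation carve-out fraction.
#' @param seed Master seed; fold f carves validation with `seed + f` and
#'   trains with `seed + 100 + f`.
#' @param monitor_test Record per-epoch test AUC in training histories
#'   (diagnostic only, never used for stopping).
#' @param verbose Progress messages.
#' @return List with `report` (per-family tibble incl. Mean row),
#'   `per_sequence` (tibble: id, family, split, baseline_f1, f1, auc),
#'   `histories` (named list of training-history tibbles) and `ttests`
#'   (per-family model-vs-baseline paired tests).
#' @export
run_intra_vs_inter <- function(records, split = c("both", "kfold", "familyfold"),
                               config = shadow_config(), params = energy_params(),
                               backend = fold_backend(), k = 5L,
                               val_fraction = 0.10, seed = 1L,
                               monitor_test = FALSE, verbose = FALSE) {
  split <- match.arg(split)
  ids <- record_ids(records)
  fams <- vapply(records, `[[`, "", "family")

  baseline_f1 <- vapply(records, function(r) {
    fr <- backend$fold(r)
    score_pairs_slippage(fr$pairs, r$pairs, seq_length(r))$f1
  }, 0)
  names(baseline_f1) <- ids

  run_mode <- function(mode) {
    plans <- if (mode == "kfold") kfold_split(records, k = k, seed = seed)
             else familyfold_split(records)
    rows <- list()
    histories <- list()
    for (f in seq_along(plans)) {
      plan <- carve_validation(plans[[f]], fraction = val_fraction,
                               seed = seed + f)
      if (verbose) message(sprintf("[%s] fold %s: training ...", mode,
                                   plan$fold_id))
      model <- train_shadow_model(records, plan, config = config,
                                  seed = seed + 100L + f,
                                  monitor_test = monitor_test)
      histories[[as.character(plan$fold_id)]] <- model$training_history
      test_rec <- records[ids %in% plan$test_ids]
      y_hats <- predict_shadow(model, test_rec)
      rows[[f]] <- dplyr::bind_rows(lapply(test_rec, function(r) {
        yh <- y_hats[[r$id]]
        prof <- pseudo_energy(shadow_to_shape(yh, r$id), params)
        fr <- if (backend$name == "reference") backend$fold(r, profile = prof)
              else backend$fold(r, profile = shadow_to_shape(yh, r$id),
                                params = params)
        sc <- score_pairs_slippage(fr$pairs, r$pairs, seq_length(r))
        tibble::tibble(id = r$id, family = r$family, split = mode,
                       baseline_f1 = baseline_f1[[r$id]], f1 = sc$f1,
                       auc = auc_shadow(yh, shadow_of(r), seq_length(r))$auc)
      }))
    }
    list(per_sequence = dplyr::bind_rows(rows), histories = histories)
  }

  modes <- if (split == "both") c("kfold", "familyfold") else split
  res <- lapply(modes, run_mode)
  names(res) <- modes
  per_sequence <- dplyr::bind_rows(lapply(res, `[[`, "per_sequence"))
  histories <- unlist(lapply(names(res), function(m) {
    h <- res[[m]]$histories
    names(h) <- paste(m, names(h), sep = ":")
    h
  }), recursive = FALSE)

  report <- NULL
  for (m in modes) {
    ps <- per_sequence[per_sequence$split == m, ]
    rep_m <- aggregate_report(ps[, c("id", "family", "baseline_f1", "auc", "f1")])
    names(rep_m)[names(rep_m) %in% c("auc", "f1")] <-
      paste0(m, c("_auc", "_f1"))
    report <- if (is.null(report)) rep_m
              else dplyr::left_join(report,
                                    rep_m[, setdiff(names(rep_m), c("n", "baseline_f1"))],
                                    by = "family")
  }

  ttests <- dplyr::bind_rows(lapply(modes, function(m) {
    ps <- per_sequence[per_sequence$split == m, ]
    dplyr::bind_rows(lapply(split(ps, ps$family), function(g) {
      if (nrow(g) < 2L) return(NULL)
      tt <- paired_ttest(g$f1, g$baseline_f1)
      tibble::tibble(split = m, family = g$family[[1L]], n = nrow(g),
                     t = tt$t, p = tt$p, degenerate = tt$degenerate)
    }))
  }))

  list(report = report, per_sequence = per_sequence, histories = histories,
       ttests = ttests)
}

#' Uniform pseudo-energy nudge sweep
#'
#' Folds every record once per intercept value in the grid with a constant
#' (sequence-independent) pseudo-energy offset `ddG = b` applied to every
#' nucleotide — 101 folds per sequence under the default grid — and traces
#' mean F1 per family against b. Because the offsets carry no information
#' about any sequence, differences between the family curves expose
#' family-specific behaviour of the underlying energy model itself. Curves
#' are min–max normalized per family for comparability, and each b is
#' tested against b = 0 with a paired t-test per family. Defaults to the
#' reference backend, which carries hundredths precision (external engines
#' may round uniform offsets to tenths).
#'
#' @param records Corpus with family labels.
#' @param grid List of [energy_params()] from [make_nudge_grid()].
#' @param backend A [fold_backend()].
#' @param verbose Progress messages.
#' @return List: `curves` (tibble family, b, mean_f1, normalized_f1),
#'   `per_sequence` (id, family, b, f1), `significance` (family, b, t, p).
#' @export
run_nudge_experiment <- function(records, grid = make_nudge_grid(),
                                 backend = fold_backend(), verbose = FALSE) {
  bs <- vapply(grid, `[[`, 0, "b")
  stopifnot(all(vapply(grid, `[[`, 0, "m") == 0))
  per <- lapply(seq_along(grid), function(gi) {
    b <- bs[[gi]]
    if (verbose) message(sprintf("nudge %d/%d (b = %+.2f)", gi, length(grid), b))
    f1 <- vapply(records, function(r) {
      prof <- uniform_nudge(seq_length(r), b, id = r$id)
      fr <- backend$fold(r, profile = prof)
      score_pairs_slippage(fr$pairs, r$pairs, seq_length(r))$f1
    }, 0)
    tibble::tibble(id = record_ids(records),
                   family = vapply(records, `[[`, "", "family"),
                   b = b, f1 = f1)
  })
  per_sequence <- dplyr::bind_rows(per)

  curves <- per_sequence |>
    dplyr::group_by(.data$family, .data$b) |>
    dplyr::summarise(mean_f1 = mean(.data$f1), .groups = "drop_last") |>
    dplyr::mutate(normalized_f1 = if (dplyr::n() >= 2L &&
                                      max(.data$mean_f1) > min(.data$mean_f1))
                    minmax_normalize(.data$mean_f1) else NA_real_) |>
    dplyr::ungroup()

  significance <- NULL
  if (any(bs == 0)) {
    base <- per_sequence[per_sequence$b == 0, c("id", "family", "f1")]
    names(base)[[3L]] <- "f1_zero"
    significance <- per_sequence |>
      dplyr::left_join(base, by = c("id", "family")) |>
      dplyr::group_by(.data$family, .data$b) |>
      dplyr::group_modify(function(g, key) {
        if (nrow(g) < 2L) return(tibble::tibble(t = NA_real_, p = NA_real_))
        tt <- paired_ttest(g$f1, g$f1_zero)
        tibble::tibble(t = tt$t, p = tt$p)
      }) |>
      dplyr::ungroup()
  }
  list(curves = curves, per_sequence = per_sequence,
       significance = significance)
}

#' Slope/intercept grid search over a validation set
#'
#' Thin orchestration over [grid_search_params()]: predicts validation
#' shadows with a trained model, evaluates the full grid and optionally
#' archives the score surface as CSV.
#'
#' @param model Trained `shadow_model`.
#' @param records Corpus.
#' @param plan [split_plan()] whose `val_ids` form the search set.
#' @param backend A [fold_backend()].
#' @param grid_m,grid_b Grid axes (default 11 x 11).
#' @param surface_csv Optional path to write the surface.
#' @return As [grid_search_params()].
#' @export
run_grid_search <- function(model, records, plan, backend = fold_backend(),
                            grid_m = seq(0, 3, by = 0.3),
                            grid_b = seq(-1.5, 0.5, by = 0.2),
                            surface_csv = NULL) {
  ids <- record_ids(records)
  val_rec <- records[ids %in% plan$val_ids]
  if (!length(val_rec)) stop("plan has no validation records to search on")
  y_hats <- predict_shadow(model, val_rec)
  res <- grid_search_params(val_rec, y_hats, backend = backend,
                            grid_m = grid_m, grid_b = grid_b)
  if (!is.null(surface_csv))
    utils::write.csv(res$surface, surface_csv, row.names = FALSE)
  res
}
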