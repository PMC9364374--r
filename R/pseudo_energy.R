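#' Slope/intercept parameters for pseudo-free-energy terms
#'
#' The per-nucleotide pseudo-free-energy change is
#' `dG'(i) = m * log(alpha(i) + 1) + b` (natural log), the standard
#' SHAPE-directed folding rule. The defaults m = 1.8, b = −0.6 kcal/mol are
#' the values fit on experimental SHAPE data and deliberately not refit —
#' refitting them on a validation set that shares families with training
#' invites exactly the overfitting this package measures.
#'
#' @param m Slope, kcal/mol.
#' @param b Intercept, kcal/mol.
#' @return An `energy_params` list.
#' @export
energy_params <- function(m = 1.8, b = -0.6) {
  stopifnot(is.finite(m), is.finite(b))
  structure(list(m = m, b = b), class = "energy_params")
}

#' Convert predicted shadows to SHAPE-like reactivities
#'
#' A predicted pairing probability near 1 means "likely paired", whereas
#' SHAPE reactivity near 0 means the same; the bridge is simply
#' `alpha(i) = 1 - y_hat(i)`. No further normalization is performed.
#'
#' @param y_hat Numeric vector of pairing probabilities in \[0, 1\].
#' @param id Optional record id to attach.
#' @return A `shape_like_profile`: list with `alpha`, `id`.
#' @export
shadow_to_shape <- function(y_hat, id = NA_character_) {
  if (any(y_hat < 0 | y_hat > 1))
    stop("pairing probabilities must lie in [0, 1]")
  structure(list(alpha = 1 - y_hat, id = id), class = "shape_like_profile")
}

#' @rdname shadow_to_shape
#' @param alpha Reactivity-like values (unitless).
#' @export
shape_like_profile <- function(alpha, id = NA_character_) {
  structure(list(alpha = alpha, id = id), class = "shape_like_profile")
}

#' Per-nucleotide pseudo-free-energy terms from reactivities
#'
#' Applies `dG'(i) = m * log(alpha(i) + 1) + b` elementwise (natural
#' logarithm). Applied to shadow-derived reactivities
#' `alpha = 1 - y_hat` this is identically `dG'(i) = m * log(2 - y_hat) + b`.
#' With m = 0 the profile is the constant `b` — a uniform "nudge".
#'
#' @param alpha A [shape_like_profile()] or bare numeric vector (values
#'   > −1).
#' @param params [energy_params()].
#' @param id Record id (taken from the profile when available).
#' @return A `pseudo_energy_profile`: list with `dG` (kcal/mol), `id`,
#'   `provenance`.
#' @export
pseudo_energy <- function(alpha, params = energy_params(), id = NULL) {
  if (inherits(alpha, "shape_like_profile")) {
    if (is.null(id)) id <- alpha$id
    alpha <- alpha$alpha
  }
  if (any(alpha <= -1))
    stop("reactivities must exceed -1 (log domain)")
  dg <- params$m * log(alpha + 1) + params$b
  structure(list(dG = dg, id = if (is.null(id)) NA_character_ else id,
                 provenance = if (params$m == 0) "uniform-nudge"
                              else "shadow-derived"),
            class = "pseudo_energy_profile")
}

#' Constant pseudo-energy profile (uniform nudge)
#'
#' Convenience for the nudge sweep: every nucleotide receives the same
#' offset `ddG = b`, i.e. `pseudo_energy` with `alpha = 0` and `m = 0`.
#'
#' @param n Sequence length.
#' @param b Offset, kcal/mol.
#' @param id Optional record id.
#' @return A `pseudo_energy_profile`.
#' @export
uniform_nudge <- function(n, b, id = NA_character_) {
  pseudo_energy(rep(0, n), energy_params(m = 0, b = b), id = id)
}

#' Enumerate the uniform-nudge parameter grid
#'
#' The inclusive arithmetic sequence of intercepts with slope fixed at 0;
#' the default −1.00 to 1.00 in steps of 0.02 yields 101 parameter sets
#' (101 folds per sequence).
#'
#' @param b_min,b_max Range of intercepts, kcal/mol.
#' @param step Grid step, kcal/mol; must divide the range.
#' @return List of [energy_params()] with `m = 0`.
#' @export
make_nudge_grid <- function(b_min = -1.00, b_max = 1.00, step = 0.02) {
  stopifnot(step > 0, b_min <= b_max)
  n <- (b_max - b_min) / step
  if (abs(n - round(n)) > 1e-9)
    stop("step must divide the range b_max - b_min")
  b <- round(b_min + step * (0:round(n)), 10)
  lapply(b, function(bi) energy_params(m = 0, b = bi))
}

#' Write a SHAPE-convention data file
#'
#' Two-column whitespace text: 1-based position then value, with the
#' conventional −999 sentinel for missing positions. Consumed by the
#' external folding engines.
#'
#' @param values A `shape_like_profile`, `pseudo_energy_profile` or bare
#'   numeric vector (NA = missing).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shape_file <- function(values, path) {
  if (inherits(values, "shape_like_profile")) values <- values$alpha
  if (inherits(values, "pseudo_energy_profile")) values <- values$dG
  v <- ifelse(is.na(values), -999, values)
  writeLines(sprintf("%d %.6f", seq_along(v), v), path)
  invisible(path)
}

#' Grid search of slope and intercept on a validation set
#'
#' Exhaustively evaluates every (m, b) cell: each validation record's
#' predicted shadow becomes reactivities, then pseudo-energies under the
#' cell's parameters, is folded by the backend, and scored against the
#' reference structure with slippage; the cell score is the unweighted
#' per-sequence mean F1. Returns the maximizing cell (ties broken toward
#' the weakest intervention: smallest |m|, then smallest |b|) together with
#' the full score surface for inspection. The default grid is 11 x 11,
#' bracketing the slope/intercept optima published for experimental SHAPE
#' data.
#'
#' @param val_records Validation [rna_record()]s.
#' @param y_hats Named list of predicted shadow vectors (names = record
#'   ids), e.g. from [predict_shadow()].
#' @param backend A [fold_backend()].
#' @param grid_m,grid_b Numeric vectors of slopes and intercepts.
#' @return List: `params` ([energy_params()]), `surface` (tibble m, b,
#'   mean_f1, n).
#' @export
grid_search_params <- function(val_records, y_hats, backend = fold_backend(),
                               grid_m = seq(0, 3, by = 0.3),
                               grid_b = seq(-1.5, 0.5, by = 0.2)) {
  stopifnot(length(val_records) >= 1L)
  cells <- expand.grid(m = grid_m, b = grid_b)
  alphas <- lapply(val_records, function(r) 1 - y_hats[[r$id]])
  mean_f1 <- vapply(seq_len(nrow(cells)), function(ci) {
    pars <- energy_params(m = cells$m[[ci]], b = cells$b[[ci]])
    f1s <- vapply(seq_along(val_records), function(ri) {
      r <- val_records[[ri]]
      prof <- pseudo_energy(alphas[[ri]], pars, id = r$id)
      fr <- tryCatch(
        if (backend$name == "reference") backend$fold(r, profile = prof)
        else backend$fold(r, profile = shape_like_profile(alphas[[ri]], r$id),
                          params = pars),
        error = function(e) stop("folding failed at grid cell (m=", pars$m,
                                 ", b=", pars$b, "), record ", r$id, ": ",
                                 conditionMessage(e)))
      score_pairs_slippage(fr$pairs, r$pairs, seq_length(r))$f1
    }, 0)
    mean(f1s)
  }, 0)
  surface <- tibble::tibble(m = cells$m, b = cells$b, mean_f1 = mean_f1,
                            n = length(val_records))
  ord <- order(-surface$mean_f1, abs(surface$m), abs(surface$b))
  best <- surface[ord[[1L]], ]
  list(params = energy_params(m = best$m, b = best$b), surface = surface)
}
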