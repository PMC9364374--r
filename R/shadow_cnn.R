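#' Configuration of the demonstrative shadow-prediction network
#'
#' The network maps a one-hot sequence (4 x `pad_to`) to per-nucleotide
#' pairing probabilities: two 1D convolution layers (256 filters, kernel 3,
#' stride 1, no dilation, length-preserving padding), each followed by
#' ReLU, with spatial dropout 0.25 between them; then a fully connected
#' block — the convolution output is flattened and passed through a dense
#' layer (`fc_units`, ReLU), dropout 0.25, and a final dense layer of
#' `pad_to` units with sigmoid activation, aligning the output with the
#' 1 x `pad_to` zero-padded shadow target. Training uses Adam
#' (gamma = 0.001, beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8), binary
#' cross-entropy over all `pad_to` positions, mini-batches of 256 and early
#' stopping with patience 5 on validation loss. All defaults are
#' overridable; an alternative `fc_mode = "per_position"` applies the dense
#' block position-wise instead of on the flattened features.
#'
#' @param conv_filters,kernel_length,stride Convolution block geometry.
#' @param spatial_dropout Channel dropout rate between the convolutions.
#' @param fc_units Width of the first dense layer.
#' @param fc_dropout Dropout rate between the dense layers.
#' @param learning_rate,adam_beta1,adam_beta2,adam_epsilon Adam settings.
#' @param batch_size Mini-batch size.
#' @param patience Early-stopping patience (epochs).
#' @param max_epochs Hard cap on training epochs.
#' @param pad_to Padded sequence length; also the output width.
#' @param fc_mode `"flatten"` (default) or `"per_position"`.
#' @return A `shadow_config` list.
#' @export
shadow_config <- function(conv_filters = 256L, kernel_length = 3L, stride = 1L,
                          spatial_dropout = 0.25, fc_units = 512L,
                          fc_dropout = 0.25, learning_rate = 0.001,
                          adam_beta1 = 0.9, adam_beta2 = 0.999,
                          adam_epsilon = 1e-8, batch_size = 256L,
                          patience = 5L, max_epochs = 100L, pad_to = 512L,
                          fc_mode = c("flatten", "per_position")) {
  if (stride != 1L) stop("only stride 1 is supported")
  structure(list(conv_layers = 2L, conv_filters = as.integer(conv_filters),
                 kernel_length = as.integer(kernel_length), stride = 1L,
                 spatial_dropout = spatial_dropout,
                 fc_layers = 2L, fc_units = as.integer(fc_units),
                 fc_dropout = fc_dropout, learning_rate = learning_rate,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_epsilon = adam_epsilon,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 pad_to = as.integer(pad_to),
                 fc_mode = match.arg(fc_mode)),
            class = "shadow_config")
}

#' Desk-scale variant of the shadow configuration
#'
#' The same architecture at a size trainable on one CPU in seconds per
#' epoch (32 filters, 128 dense units, 256-position padding, mini-batches
#' of 64); optimizer, dropout, patience and loss keep their full-scale
#' values. This is the configuration the packaged experiments and the
#' bundled analysis scripts train at; the full-scale configuration remains
#' the [shadow_config()] default.
#'
#' @param ... Overrides forwarded to [shadow_config()].
#' @return A `shadow_config`.
#' @export
shadow_config_desk <- function(...) {
  args <- utils::modifyList(list(conv_filters = 32L, fc_units = 128L,
                                 pad_to = 256L, batch_size = 64L,
                                 max_epochs = 20L, patience = 5L),
                            list(...))
  do.call(shadow_config, args)
}

#' Build an untrained shadow model
#'
#' Allocates and initializes all parameter tensors (He initialization for
#' the ReLU layers, Glorot for the sigmoid output layer).
#'
#' @param config A [shadow_config()].
#' @param seed Initialization seed.
#' @return A `shadow_model` list with `params`, `config`, `seed`,
#'   `training_history` (`NULL` until trained).
#' @export
build_shadow_model <- function(config = shadow_config(), seed = 1L) {
  F <- config$conv_filters; k <- config$kernel_length; P <- config$pad_to
  he <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)),
                                        nr, nc)
  glorot <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / (nr + nc))),
                                    nr, nc)
  params <- with_seed(seed, {
    p <- list(
      W1 = he(F, 4L * k, 4L * k), b1 = numeric(F),
      W2 = he(F, F * k, F * k),   b2 = numeric(F)
    )
    if (config$fc_mode == "flatten") {
      D <- F * P
      p$Wf1 <- he(config$fc_units, D, D)
      p$bf1 <- numeric(config$fc_units)
      p$Wf2 <- glorot(P, config$fc_units)
      p$bf2 <- numeric(P)
    } else {
      p$Wf1 <- he(config$fc_units, F, F)
      p$bf1 <- numeric(config$fc_units)
      p$Wf2 <- glorot(1L, config$fc_units)
      p$bf2 <- numeric(1L)
    }
    p
  })
  structure(list(params = params, config = config, seed = seed,
                 training_history = NULL),
            class = "shadow_model")
}

#' Trainable parameter count of a shadow model
#' @param model A `shadow_model`.
#' @return Integer-valued numeric count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, 1L))
}

#' @export
print.shadow_model <- function(x, ...) {
  cat(sprintf("<shadow_model> %d filters, fc %d (%s), pad %d — %s params%s\n",
              x$config$conv_filters, x$config$fc_units, x$config$fc_mode,
              x$config$pad_to, format(n_params(x), big.mark = ","),
              if (is.null(x$training_history)) " (untrained)" else ""))
  invisible(x)
}

# ---- network primitives -----------------------------------------------------
# Batches are stored as arrays of dim (channels, positions, batch). The
# im2col trick turns each same-padded width-3 convolution into one BLAS
# matrix multiplication.

.im2col <- function(X, k) {
  d <- dim(X); C <- d[[1L]]; P <- d[[2L]]; B <- d[[3L]]
  half <- (k - 1L) %/% 2L
  out <- matrix(0, C * k, P * B)
  for (t in seq_len(k)) {
    off <- t - 1L - half
    Xs <- array(0, d)
    if (off < 0) Xs[, (1 - off):P, ] <- X[, 1:(P + off), , drop = FALSE]
    else if (off > 0) Xs[, 1:(P - off), ] <- X[, (1 + off):P, , drop = FALSE]
    else Xs <- X
    out[((t - 1L) * C + 1L):(t * C), ] <- matrix(Xs, C, P * B)
  }
  out
}

.col2im <- function(dXcol, k, d) {
  C <- d[[1L]]; P <- d[[2L]]; B <- d[[3L]]
  half <- (k - 1L) %/% 2L
  dX <- array(0, d)
  for (t in seq_len(k)) {
    off <- t - 1L - half
    block <- array(dXcol[((t - 1L) * C + 1L):(t * C), ], d)
    if (off < 0) dX[, 1:(P + off), ] <- dX[, 1:(P + off), , drop = FALSE] +
        block[, (1 - off):P, , drop = FALSE]
    else if (off > 0) dX[, (1 + off):P, ] <- dX[, (1 + off):P, , drop = FALSE] +
        block[, 1:(P - off), , drop = FALSE]
    else dX <- dX + block
  }
  dX
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass. X: (4, P, B). Returns probabilities (P_out x B) plus the
# caches needed for backprop. Dropout masks are drawn only when training.
.forward <- function(params, config, X, training = FALSE) {
  k <- config$kernel_length
  d <- dim(X); P <- d[[2L]]; B <- d[[3L]]
  Xc1 <- .im2col(X, k)
  Z1 <- params$W1 %*% Xc1 + params$b1          # (F, P*B)
  A1 <- pmax(Z1, 0)
  mask_sd <- NULL
  if (training && config$spatial_dropout > 0) { # drop whole channels/sample
    keep <- matrix(rbinom(nrow(A1) * B, 1L, 1 - config$spatial_dropout) /
                     (1 - config$spatial_dropout), nrow(A1), B)
    # expand to the (position, batch) column layout: p varies fastest
    mask_sd <- keep[, rep(seq_len(B), each = P), drop = FALSE]
    A1 <- A1 * mask_sd
  }
  A1arr <- array(A1, c(nrow(A1), P, B))
  Xc2 <- .im2col(A1arr, k)
  Z2 <- params$W2 %*% Xc2 + params$b2
  A2 <- pmax(Z2, 0)                            # (F, P*B)

  if (config$fc_mode == "flatten") {
    Xf <- matrix(A2, nrow(A2) * P, B)          # (F*P, B), F fastest
    H <- params$Wf1 %*% Xf + params$bf1
  } else {
    Xf <- A2                                   # (F, P*B): dense per position
    H <- params$Wf1 %*% Xf + params$bf1
  }
  Ah <- pmax(H, 0)
  mask_fc <- NULL
  if (training && config$fc_dropout > 0) {
    mask_fc <- matrix(rbinom(length(Ah), 1L, 1 - config$fc_dropout) /
                        (1 - config$fc_dropout), nrow(Ah), ncol(Ah))
    Ah <- Ah * mask_fc
  }
  Zo <- params$Wf2 %*% Ah + params$bf2
  Yhat <- .sigmoid(Zo)                          # flatten: (P, B); per-pos: (1, P*B)
  if (config$fc_mode == "per_position") Yhat <- matrix(Yhat, P, B)
  list(Yhat = Yhat, caches = list(X = X, Xc1 = Xc1, Z1 = Z1, A1arr = A1arr,
                                  Xc2 = Xc2, Z2 = Z2, A2 = A2, Xf = Xf,
                                  H = H, Ah = Ah, mask_sd = mask_sd,
                                  mask_fc = mask_fc))
}

# Mean binary cross-entropy over every output position (padding included:
# padded targets are 0, i.e. labelled unpaired).
.bce <- function(Yhat, Y) {
  eps <- 1e-12
  -mean(Y * log(Yhat + eps) + (1 - Y) * log(1 - Yhat + eps))
}

.backward <- function(params, config, fwd, Y) {
  cc <- fwd$caches
  k <- config$kernel_length
  d <- dim(cc$X); P <- d[[2L]]; B <- d[[3L]]
  Yhat <- fwd$Yhat
  dZo <- (Yhat - Y) / length(Y)                 # BCE + sigmoid
  if (config$fc_mode == "per_position") dZo <- matrix(dZo, 1L, P * B)
  g <- list()
  g$Wf2 <- dZo %*% t(cc$Ah)
  g$bf2 <- rowSums(dZo)
  dAh <- t(params$Wf2) %*% dZo
  if (!is.null(cc$mask_fc)) dAh <- dAh * cc$mask_fc
  dH <- dAh * (cc$H > 0)
  g$Wf1 <- dH %*% t(cc$Xf)
  g$bf1 <- rowSums(dH)
  dXf <- t(params$Wf1) %*% dH
  dA2 <- if (config$fc_mode == "flatten") matrix(dXf, config$conv_filters, P * B)
         else dXf
  dZ2 <- dA2 * (cc$Z2 > 0)
  g$W2 <- dZ2 %*% t(cc$Xc2)
  g$b2 <- rowSums(dZ2)
  dXc2 <- t(params$W2) %*% dZ2
  dA1 <- matrix(.col2im(dXc2, k, dim(cc$A1arr)), config$conv_filters, P * B)
  if (!is.null(cc$mask_sd)) dA1 <- dA1 * cc$mask_sd
  dZ1 <- dA1 * (cc$Z1 > 0)
  g$W1 <- dZ1 %*% t(cc$Xc1)
  g$b1 <- rowSums(dZ1)
  g
}

.adam_step <- function(state, params, grads, config, t) {
  b1 <- config$adam_beta1; b2 <- config$adam_beta2
  lr <- config$learning_rate; eps <- config$adam_epsilon
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / (1 - b1^t)
    vhat <- state$v[[nm]] / (1 - b2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

.encode_batch <- function(records, pad_to) {
  B <- length(records)
  X <- array(0, c(4L, pad_to, B))
  Y <- matrix(0, pad_to, B)
  lens <- integer(B)
  for (i in seq_len(B)) {
    e <- encode_record(records[[i]], pad_to)
    X[, , i] <- e$x
    Y[, i] <- e$y
    lens[[i]] <- e$true_length
  }
  list(X = X, Y = Y, lens = lens, ids = record_ids(records))
}

# Mean per-record shadow AUC over a batch (padding excluded; undefined AUCs
# dropped).
.mean_shadow_auc <- function(Yhat, Y, lens) {
  aucs <- vapply(seq_along(lens), function(i)
    auc_shadow(Yhat[, i], Y[, i], lens[[i]])$auc, 0)
  mean(aucs, na.rm = TRUE)
}

#' Train the shadow model on a split plan
#'
#' Mini-batch Adam on binary cross-entropy over all output positions
#' (padded targets count as unpaired), with early stopping on validation
#' loss (patience per the config) and best-epoch parameters restored.
#' Per-epoch history — training loss, validation loss/AUC and, when
#' `monitor_test = TRUE`, test AUC — is recorded for learning-curve
#' diagnostics; test metrics are never used for stopping.
#'
#' @param records Full corpus of [rna_record()]s.
#' @param plan A [split_plan()] with nonempty train and val sets.
#' @param config A [shadow_config()].
#' @param seed Seed governing initialization, shuffling and dropout.
#' @param monitor_test Record per-epoch test AUC.
#' @param verbose Print per-epoch progress.
#' @return A trained `shadow_model` with a `training_history` tibble
#'   (epoch, train_loss, val_loss, val_auc\[, test_auc\]).
#' @export
train_shadow_model <- function(records, plan, config = shadow_config(),
                               seed = 1L, monitor_test = FALSE,
                               verbose = FALSE) {
  ids <- record_ids(records)
  train_rec <- records[ids %in% plan$train_ids]
  val_rec <- records[ids %in% plan$val_ids]
  if (!length(train_rec)) stop("plan has an empty training set")
  if (!length(val_rec)) stop("cannot early-stop with an empty validation set")
  test_rec <- if (monitor_test) records[ids %in% plan$test_ids] else list()

  tr <- .encode_batch(train_rec, config$pad_to)
  va <- .encode_batch(val_rec, config$pad_to)
  te <- if (length(test_rec)) .encode_batch(test_rec, config$pad_to) else NULL

  model <- build_shadow_model(config, seed = seed)
  params <- model$params
  state <- list(m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  n_train <- length(train_rec)
  history <- list()
  best_val <- Inf; best_params <- params; best_epoch <- 0L; wait <- 0L
  step <- 0L

  with_seed(seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(n_train)
      batch_losses <- numeric(0)
      for (start in seq(1L, n_train, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n_train)]
        Xb <- tr$X[, , idx, drop = FALSE]
        Yb <- tr$Y[, idx, drop = FALSE]
        fwd <- .forward(params, config, Xb, training = TRUE)
        batch_losses <- c(batch_losses, .bce(fwd$Yhat, Yb))
        grads <- .backward(params, config, fwd, Yb)
        step <- step + 1L
        upd <- .adam_step(state, params, grads, config, step)
        state <- upd$state; params <- upd$params
      }
      vfwd <- .forward(params, config, va$X, training = FALSE)
      val_loss <- .bce(vfwd$Yhat, va$Y)
      val_auc <- .mean_shadow_auc(vfwd$Yhat, va$Y, va$lens)
      row <- list(epoch = epoch, train_loss = mean(batch_losses),
                  val_loss = val_loss, val_auc = val_auc)
      if (!is.null(te)) {
        tfwd <- .forward(params, config, te$X, training = FALSE)
        row$test_auc <- .mean_shadow_auc(tfwd$Yhat, te$Y, te$lens)
      }
      history[[epoch]] <- tibble::as_tibble(row)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  val_auc %.3f%s",
                        epoch, row$train_loss, val_loss, val_auc,
                        if (!is.null(row$test_auc))
                          sprintf("  test_auc %.3f", row$test_auc) else ""))
      if (val_loss < best_val - 1e-9) {
        best_val <- val_loss; best_params <- params
        best_epoch <- epoch; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })

  model$params <- best_params
  model$best_epoch <- best_epoch
  model$training_history <- dplyr::bind_rows(history)
  model
}

#' Predict pairing-probability shadows
#'
#' Runs the trained network (dropout off) and truncates each output to the
#' record's true length.
#'
#' @param model A trained `shadow_model`.
#' @param records List of [rna_record()]s no longer than the model's
#'   `pad_to`.
#' @param batch_size Records per forward pass.
#' @return Named list (by record id) of probability vectors in \[0, 1\].
#' @export
predict_shadow <- function(model, records, batch_size = 64L) {
  config <- model$config
  out <- vector("list", length(records))
  for (start in seq(1L, length(records), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(records))
    enc <- .encode_batch(records[idx], config$pad_to)
    fwd <- .forward(model$params, config, enc$X, training = FALSE)
    for (k in seq_along(idx))
      out[[idx[[k]]]] <- fwd$Yhat[seq_len(enc$lens[[k]]), k]
  }
  names(out) <- record_ids(records)
  out
}

#' Save / load a shadow model
#'
#' Checkpoints are plain-text JSON (config, seed, flattened parameter
#' tensors) so they survive text-only archiving.
#'
#' @param model A `shadow_model`.
#' @param path Checkpoint path (`.json`).
#' @return `path` / the restored model.
#' @export
save_shadow_model <- function(model, path) {
  obj <- list(config = unclass(model$config), seed = model$seed,
              params = lapply(model$params, function(p)
                list(dim = dim(p) %||% length(p), data = as.numeric(p))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_shadow_model
#' @export
load_shadow_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfgargs <- obj$config
  cfgargs$conv_layers <- NULL; cfgargs$fc_layers <- NULL; cfgargs$stride <- NULL
  config <- do.call(shadow_config, cfgargs)
  params <- lapply(obj$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[[1L]], p$dim[[2L]])
    else as.numeric(p$data)
  })
  structure(list(params = params, config = config, seed = obj$seed,
                 training_history = NULL),
            class = "shadow_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
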