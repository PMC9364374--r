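# A small architecture keeps the training tests fast; the default
# (paper-scale) architecture is exercised for construction and counting only.
small_cfg <- function(...) {
  args <- utils::modifyList(list(conv_filters = 16L, fc_units = 64L,
                                 pad_to = 64L, batch_size = 8L), list(...))
  do.call(shadow_config, args)
}

overfit_fixture <- function(n_copies = 20L) {
  rec <- sample_family(family_spec("f", 1L, 50L, 3L), seed = 1L)[[1]]
  recs <- lapply(seq_len(n_copies + 2L), function(i)
    rna_record(sprintf("c%02d", i), rec$sequence, rec$pairs, "f"))
  plan <- split_plan("ov", train_ids = sprintf("c%02d", seq_len(n_copies)),
                     val_ids = sprintf("c%02d", n_copies + 1:2),
                     test_ids = character(0))
  list(records = recs, plan = plan, truth = shadow_of(rec))
}

test_that("the default architecture has the expected trainable parameter count", {
  # layer-wise arithmetic, frozen independently of the builder:
  # conv1 4*3*256+256 = 3,328; conv2 256*3*256+256 = 196,864;
  # dense1 (256*512)*512+512 = 67,109,376; dense2 512*512+512 = 262,656
  m <- build_shadow_model(shadow_config(), seed = 1L)
  expect_equal(n_params(m), 3328 + 196864 + 67109376 + 262656)
  expect_equal(n_params(m), 67572224)
  rm(m)
  invisible(gc(FALSE))
})

test_that("forward passes give [0,1] outputs of the padded length", {
  cfg <- small_cfg()
  model <- build_shadow_model(cfg, seed = 2L)
  recs <- sample_family(family_spec("f", 5L, 40L, 8L), seed = 2L)
  y <- predict_shadow(model, recs)
  expect_length(y, 5L)
  expect_true(all(vapply(y, function(v) all(v >= 0 & v <= 1), TRUE)))
  # outputs truncated to true length
  expect_equal(lengths(y), setNames(rep(40L, 5L), names(y)))
  # per-position dense mode also aligns with the target
  cfgp <- small_cfg(fc_mode = "per_position")
  yp <- predict_shadow(build_shadow_model(cfgp, seed = 2L), recs)
  expect_equal(lengths(yp), lengths(y))
})

test_that("analytic gradients agree with finite differences", {
  cfg <- small_cfg(conv_filters = 3L, fc_units = 5L, pad_to = 12L,
                   spatial_dropout = 0, fc_dropout = 0)
  model <- build_shadow_model(cfg, seed = 3L)
  recs <- sample_family(family_spec("f", 2L, 12L, 5L), seed = 3L)
  enc <- shadowfold:::.encode_batch(recs, cfg$pad_to)
  fwd <- shadowfold:::.forward(model$params, cfg, enc$X, training = FALSE)
  grads <- shadowfold:::.backward(model$params, cfg, fwd, enc$Y)
  eps <- 1e-6
  set.seed(99)
  for (nm in c("W1", "b2", "Wf1", "bf2")) {
    idx <- sample(length(model$params[[nm]]), 3L)
    for (i in idx) {
      pp <- model$params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      up <- shadowfold:::.bce(shadowfold:::.forward(pp, cfg, enc$X)$Yhat, enc$Y)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      dn <- shadowfold:::.bce(shadowfold:::.forward(pp, cfg, enc$X)$Yhat, enc$Y)
      expect_equal(grads[[nm]][i], (up - dn) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("training is deterministic under a fixed seed", {
  fx <- overfit_fixture(6L)
  cfg <- small_cfg(max_epochs = 2L)
  h1 <- train_shadow_model(fx$records, fx$plan, cfg, seed = 11L)$training_history
  h2 <- train_shadow_model(fx$records, fx$plan, cfg, seed = 11L)$training_history
  expect_identical(h1$train_loss[[1L]], h2$train_loss[[1L]])
  expect_identical(h1, h2)
})

test_that("the network memorizes a single repeated structure (overfit oracle)", {
  fx <- overfit_fixture(20L)
  cfg <- small_cfg(max_epochs = 120L, patience = 120L, learning_rate = 0.003)
  model <- train_shadow_model(fx$records, fx$plan, cfg, seed = 5L)
  yh <- predict_shadow(model, fx$records[1])[[1]]
  res <- auc_shadow(yh, fx$truth)
  expect_gte(res$auc, 0.99)
  # predicted probabilities sit close to the 0/1 truth nearly everywhere
  expect_gte(mean(abs(yh - fx$truth) < 0.1), 0.95)
  # training loss decreases over the early epochs
  h <- model$training_history
  expect_lt(h$train_loss[[5L]], h$train_loss[[1L]])
  expect_lt(min(h$train_loss), 0.05)
})

test_that("early stopping restores the best validation epoch", {
  fx <- overfit_fixture(8L)
  cfg <- small_cfg(max_epochs = 60L, patience = 3L)
  model <- train_shadow_model(fx$records, fx$plan, cfg, seed = 6L)
  h <- model$training_history
  expect_lte(nrow(h), 60L)
  expect_equal(model$best_epoch, which.min(h$val_loss))
  # stopped patience epochs after the best epoch (unless the cap hit)
  if (nrow(h) < 60L) expect_equal(nrow(h), model$best_epoch + 3L)
})

test_that("checkpoints round-trip through plain-text JSON", {
  fx <- overfit_fixture(6L)
  cfg <- small_cfg(max_epochs = 2L)
  model <- train_shadow_model(fx$records, fx$plan, cfg, seed = 7L)
  td <- withr::local_tempdir()
  path <- file.path(td, "model.json")
  save_shadow_model(model, path)
  back <- load_shadow_model(path)
  y1 <- predict_shadow(model, fx$records[1])[[1]]
  y2 <- predict_shadow(back, fx$records[1])[[1]]
  expect_equal(y1, y2, tolerance = 1e-12)
})

test_that("training requires nonempty train and validation sets", {
  fx <- overfit_fixture(4L)
  bad <- split_plan("b", train_ids = fx$plan$train_ids, val_ids = character(0),
                    test_ids = character(0))
  expect_error(train_shadow_model(fx$records, bad, small_cfg()),
               "validation")
})
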