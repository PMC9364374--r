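test_that("slippage scoring matches the displaced-pair rules", {
  ref <- rbind(c(1L, 10L), c(2L, 9L))
  expect_equal(score_pairs_slippage(ref, ref, 12L)[c("ppv", "sensitivity", "f1")],
               list(ppv = 1, sensitivity = 1, f1 = 1))
  # predicted (1,9) matches both (1,10) [j+1] and (2,9) [i-1]; only one of
  # two reference pairs finds a match in the single predicted pair... both do
  sc <- score_pairs_slippage(rbind(c(1L, 9L)), ref, 12L)
  expect_equal(sc$ppv, 1)
  expect_equal(sc$sensitivity, 1)      # both ref pairs match (1,9) by slippage
  # a genuinely partial case: reference pair (5,14) has no displaced partner
  sc2 <- score_pairs_slippage(rbind(c(1L, 9L)), rbind(c(1L, 10L), c(5L, 14L)), 14L)
  expect_equal(sc2$ppv, 1)
  expect_equal(sc2$sensitivity, 0.5)
  expect_equal(sc2$f1, 2 / 3)
  # empty prediction vs nonempty reference
  expect_equal(score_pairs_slippage(NULL, ref, 12L)$f1, 0)
  # both empty: correctly predicted unpaired molecule
  expect_equal(score_pairs_slippage(NULL, NULL, 12L)$f1, 1)
  expect_error(score_pairs_slippage(rbind(c(1L, 20L)), ref, 12L), "out of range")
})

test_that("slippage scorer agrees with a brute-force matcher on random structures", {
  for (s in 1:200) {
    n <- 30L
    a <- sample_structure(n, seed = 2000L + s)
    b <- sample_structure(n, seed = 4000L + s)
    for (slip in c(TRUE, FALSE)) {
      fast <- score_pairs_slippage(a, b, n, slippage = slip)
      slow <- brute_slippage(a, b, slippage = slip)
      expect_equal(fast$matched_pred, slow$matched_pred)
      expect_equal(fast$matched_ref, slow$matched_ref)
    }
  }
  # with slippage disabled the counts reduce to exact set intersection
  a <- sample_structure(40L, seed = 1L)
  sc <- score_pairs_slippage(a, a, 40L, slippage = FALSE)
  expect_equal(sc$matched_pred, nrow(a))
})

test_that("f1 is the harmonic mean with a guarded zero case", {
  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(0, 0.7), 0)
  expect_equal(f1_score(1, 0.5), 2 / 3)
  expect_equal(f1_score(0, 0), 0)
  # f1 never exceeds the larger input
  for (i in 1:50) {
    p <- runif(1); s <- runif(1)
    expect_lte(f1_score(p, s), max(p, s) + 1e-12)
  }
})

test_that("shadow AUC equals the pairwise-comparison probability", {
  expect_equal(auc_shadow(c(0.9, 0.8, 0.7, 0.1), c(1L, 0L, 1L, 0L))$auc, 0.75)
  sh <- c(1L, 0L, 1L, 0L, 1L)
  expect_equal(auc_shadow(as.numeric(sh), sh)$auc, 1)
  expect_equal(auc_shadow(rep(0.4, 5L), sh)$auc, 0.5)
  # undefined for single-class shadows
  expect_true(is.na(auc_shadow(runif(4), rep(1L, 4L))$auc))
  expect_true(is.na(auc_shadow(runif(4), rep(0L, 4L))$auc))
  # padding exclusion: positions beyond true_length are ignored
  expect_equal(auc_shadow(c(0.9, 0.1, 0.99, 0.99), c(1L, 0L, 0L, 0L),
                          true_length = 2L)$auc, 1)
  # oracle equivalence on random instances (with ties)
  set.seed(77)
  for (i in 1:40) {
    n <- sample(5:50, 1L)
    sh <- rbinom(n, 1L, 0.5)
    if (all(sh == sh[[1L]])) sh[[1L]] <- 1L - sh[[1L]]
    yh <- round(runif(n), 1)           # coarse grid forces ties
    expect_equal(auc_shadow(yh, sh)$auc, brute_auc(yh, sh))
  }
})

test_that("paired t-tests match the closed form and flag degenerate input", {
  x <- c(0.5, 0.6, 0.7)
  expect_equal(paired_ttest(x, x), list(t = 0, p = 1, df = 2L,
                                        degenerate = FALSE))
  r <- paired_ttest(c(1, 0), c(0, 1))  # differences (1, -1)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  # differences (1,2,3): t = 2 sqrt(3), p ~ 0.0742
  r2 <- paired_ttest(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r2$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r2$p, 2 * pt(2 * sqrt(3), df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  # constant nonzero differences: no finite t
  dg <- paired_ttest(c(1, 2, 3), c(0, 1, 2))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$t))
})

test_that("min-max normalization spans [0,1] and rejects constants", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(0, 0.3, 1)), c(0, 0.3, 1))
  expect_equal(minmax_normalize(c(-1, 0, 3)), c(0, 0.25, 1))
  expect_error(minmax_normalize(c(2, 2, 2)), "constant")
})

test_that("per-family aggregation uses an unweighted overall mean", {
  # the printed nine-family summary: family-fold F1 column
  ff <- c(0.46, 0.50, 0.65, 0.41, 0.48, 0.49, 0.48, 0.45, 0.54)
  tab <- tibble::tibble(id = paste0("r", 1:9), family = paste0("fam", 1:9),
                        f1 = ff)
  rep <- aggregate_report(tab)
  expect_equal(rep$f1[rep$family == "Mean"], mean(ff))
  expect_equal(round(rep$f1[rep$family == "Mean"], 2), 0.50)
  # single family: overall mean equals the family mean
  one <- aggregate_report(tibble::tibble(id = c("a", "b"), family = "f",
                                         f1 = c(0.2, 0.4)))
  expect_equal(one$f1[one$family == "Mean"], 0.3)
  # unweightedness: sizes 1000 and 10 with means 1 and 0 -> 0.5
  two <- aggregate_report(tibble::tibble(
    id = paste0("r", 1:1010),
    family = rep(c("big", "small"), c(1000L, 10L)),
    f1 = rep(c(1, 0), c(1000L, 10L))))
  expect_equal(two$f1[two$family == "Mean"], 0.5)
  # NA metric values are excluded from means
  na_tab <- aggregate_report(tibble::tibble(
    id = paste0("r", 1:4), family = rep(c("x", "y"), each = 2L),
    auc = c(0.8, NA, 0.6, 0.4)))
  expect_equal(na_tab$auc[na_tab$family == "x"], 0.8)
})
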