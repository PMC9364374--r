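test_that("structure trees encode pairs as internal nodes, unpaired as leaves", {
  # no pairs: root with n leaves
  t0 <- structure_to_tree(rna_record("u", "ACGU"))
  expect_equal(t0$n_nodes, 5L)
  expect_equal(sum(t0$labels == 3L), 4L)
  # the 14-nt worked example: 3 pairs + 8 unpaired + root
  r <- rna_record("x", strrep("A", 14), parse_dotbracket("...(((....)))."))
  tr <- structure_to_tree(r)
  expect_equal(tr$n_nodes, 3L + 8L + 1L)
  expect_equal(sum(tr$labels == 2L), 3L)
  # identical structures give identical trees
  r2 <- rna_record("y", strrep("G", 14), parse_dotbracket("...(((....)))."))
  expect_identical(structure_to_tree(r2)[c("labels", "lml")],
                   tr[c("labels", "lml")])
  # node count = kept pairs + unpaired + 1 on random pseudoknotted records
  for (s in 1:10) {
    rec <- random_pk_record(paste0("t", s), len = 50L, seed = 600L + s)
    tt <- structure_to_tree(rec)
    n_pairs_kept <- sum(tt$labels == 2L)
    expect_equal(tt$n_nodes, n_pairs_kept + (50L - 2L * n_pairs_kept) + 1L)
    # crossing removal keeps the maximum non-crossing subset
    expect_gte(n_pairs_kept, nrow(rec$pairs) - 1L)
  }
})

test_that("tree edit distance matches an independent recursion and is a metric", {
  d_id <- tree_edit_distance(structure_to_tree(rna_record("a", "ACGUA")),
                             structure_to_tree(rna_record("b", "ACGUA")))
  expect_equal(d_id, 0)
  # empty tree vs n-node tree: n insertions
  e <- structure_to_tree(rna_record("e", ""))
  t5 <- structure_to_tree(rna_record("f", "ACGUA"))
  expect_equal(tree_edit_distance(e, t5), 5)
  # oracle equality on small structures, including the bulge-vs-hairpin case
  cases <- list(c("((..))", "(...)"), c("(....)", "......"),
                c("((...))", "(....)"), c(".(....).", "((....))"))
  for (cs in cases) {
    ra <- rna_record("a", strrep("A", nchar(cs[[1L]])), parse_dotbracket(cs[[1L]]))
    rb <- rna_record("b", strrep("A", nchar(cs[[2L]])), parse_dotbracket(cs[[2L]]))
    expect_equal(tree_edit_distance(structure_to_tree(ra), structure_to_tree(rb)),
                 oracle_ted(oracle_tree(ra), oracle_tree(rb)))
  }
  # randomized oracle check + symmetry + triangle inequality
  set.seed(808)
  recs <- lapply(1:12, function(s) {
    len <- sample(12:18, 1L)
    rna_record(paste0("r", s), strrep("A", len),
               sample_structure(len, seed = 700L + s, loop_range = c(3L, 5L)))
  })
  trees <- lapply(recs, structure_to_tree)
  otrees <- lapply(recs, oracle_tree)
  D <- matrix(0, 12L, 12L)
  for (i in 1:12) for (j in 1:12) D[i, j] <- tree_edit_distance(trees[[i]], trees[[j]])
  for (i in 1:6) for (j in 1:6)
    expect_equal(D[i, j], oracle_ted(otrees[[i]], otrees[[j]]))
  expect_equal(D, t(D))
  for (t in 1:100) {
    ijk <- sample(12L, 3L, replace = TRUE)
    expect_lte(D[ijk[1L], ijk[3L]],
               D[ijk[1L], ijk[2L]] + D[ijk[2L], ijk[3L]] + 1e-9)
  }
})

test_that("mean minimum TED is zero under containment and separates split types", {
  fam <- sample_family(family_spec("f", 6L, 60L, 41L), seed = 9L)
  # test subset of train -> 0 (identical structures within a family)
  res <- mean_min_ted(fam[1:2], fam)
  expect_equal(res$mean_min, 0)
  # singleton sides: plain tree edit distance
  other <- sample_family(family_spec("g", 1L, 60L, 97L), seed = 9L)
  single <- mean_min_ted(other, fam[1])
  expect_equal(single$mean_min,
               tree_edit_distance(structure_to_tree(other[[1]]),
                                  structure_to_tree(fam[[1]])))
  expect_error(mean_min_ted(list(), fam), "nonempty")
  # intra-family splits leak structure; family-fold splits do not
  corpus <- tiny_corpus(3L, 8L, lens = c(50L, 60L, 70L))
  kplans <- kfold_split(corpus, k = 3L, seed = 5L)
  fplans <- familyfold_split(corpus)
  ka <- audit_splits(kplans, corpus, max_test = 10L, max_train = 20L, seed = 2L)
  fa <- audit_splits(fplans, corpus, max_test = 10L, max_train = 20L, seed = 2L)
  expect_lt(mean(ka$mean_min_ted), mean(fa$mean_min_ted))
  expect_equal(mean(ka$mean_min_ted), 0)  # every test structure seen in training
  expect_gt(min(fa$mean_min_ted), 5)
})

test_that("subsampling caps are applied and reported", {
  fam <- sample_family(family_spec("f", 12L, 50L, 55L), seed = 1L)
  res <- mean_min_ted(fam, fam, max_test = 4L, max_train = 6L, seed = 3L)
  expect_equal(res$n_test_used, 4L)
  expect_equal(res$n_train_used, 6L)
  expect_equal(nrow(res$per_test), 4L)
})
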