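test_that("dot-bracket parsing handles nesting, crossing and errors", {
  expect_equal(parse_dotbracket("...(((....)))."),
               matrix(c(4L, 5L, 6L, 13L, 12L, 11L), ncol = 2L,
                      dimnames = list(NULL, c("i", "j"))))
  expect_equal(nrow(parse_dotbracket("....")), 0L)
  # crossing pairs on extra bracket layers (hand-derived stack simulation)
  pk <- parse_dotbracket("((..[[..))..]]")
  expect_equal(unname(pk), matrix(c(1L, 2L, 5L, 6L, 10L, 9L, 14L, 13L),
                                  ncol = 2L))
  expect_error(parse_dotbracket("(((..)"), "unbalanced")
  expect_error(parse_dotbracket("..x.."), "invalid")
})

test_that("dot-bracket rendering inverts parsing, including pseudoknots", {
  r <- rna_record("x", strrep("A", 14), parse_dotbracket("...(((....)))."))
  expect_equal(to_dotbracket(r), "...(((....))).")
  expect_equal(to_dotbracket(rna_record("e", "ACGU")), "....")
  for (s in 1:200) {
    rec <- random_pk_record(paste0("pk", s), len = 40L, seed = s)
    round <- parse_dotbracket(to_dotbracket(rec))
    expect_true(pairs_identical(round, rec$pairs))
  }
})

test_that("shadows mark exactly the paired positions", {
  r <- rna_record("x", strrep("A", 14), parse_dotbracket("...(((....)))."))
  expect_equal(shadow_of(r), c(0L, 0L, 0L, 1L, 1L, 1L, 0L, 0L, 0L, 0L,
                               1L, 1L, 1L, 0L))
  expect_equal(shadow_of(rna_record("e", "ACGU")), rep(0L, 4L))
  full <- rna_record("f", "GGGGGCCCCC",
                     cbind(1:5, 10:6))  # fully paired even-length record
  expect_equal(shadow_of(full), rep(1L, 10L))
  # sum(shadow) = 2 |pairs| whenever indices are unique (always, by type)
  for (s in 1:25) {
    rec <- random_pk_record(paste0("s", s), len = 50L, seed = s)
    expect_equal(sum(shadow_of(rec)), 2L * nrow(rec$pairs))
  }
})

test_that("one-hot encoding follows the A,C,G,U row convention with 3' zero padding", {
  e <- encode_record(rna_record("x", "UCG"), pad_to = 8L)
  expect_equal(unname(e$x[, 1]), c(0, 0, 0, 1))   # U
  expect_equal(unname(e$x[, 2]), c(0, 1, 0, 0))   # C
  expect_equal(unname(e$x[, 3]), c(0, 0, 1, 0))   # G
  expect_true(all(e$x[, 4:8] == 0))
  expect_equal(e$true_length, 3L)
  # ambiguity letters encode as all-zero columns
  en <- encode_record(rna_record("n", "ANG"), pad_to = 4L)
  expect_true(all(en$x[, 2] == 0))
  expect_equal(sum(en$x), 2)
  # empty sequence
  e0 <- encode_record(rna_record("z", ""), pad_to = 4L)
  expect_true(all(e0$x == 0) && all(e0$y == 0))
  expect_error(encode_record(rna_record("l", strrep("A", 9)), pad_to = 8L),
               "exceeds")
  # nonzero column count equals true length for unambiguous sequences
  rec <- tiny_corpus(1L, 2L)[[1]]
  ee <- encode_record(rec, pad_to = 64L)
  expect_equal(sum(colSums(ee$x) > 0), seq_length(rec))
  expect_equal(ee$y[seq_len(seq_length(rec))], as.numeric(shadow_of(rec)))
})

test_that("CT files round-trip sequence and pairs", {
  td <- withr::local_tempdir()
  # single hairpin-closing pair
  r1 <- rna_record("h", "GAAAC", cbind(1L, 5L))
  f1 <- file.path(td, "h.ct")
  write_ct(r1, f1)
  back <- read_ct(f1)
  expect_equal(back$sequence, "GAAAC")
  expect_true(pairs_identical(back$pairs, r1$pairs))
  # all-unpaired molecule
  r0 <- rna_record("u", "ACGUA")
  f0 <- file.path(td, "u.ct")
  write_ct(r0, f0)
  expect_equal(nrow(read_ct(f0)$pairs), 0L)
  # 50 random synthetic records round-trip
  for (s in 1:50) {
    rec <- random_pk_record(paste0("rt", s), len = 45L, seed = 300L + s)
    f <- file.path(td, paste0(rec$id, ".ct"))
    write_ct(rec, f)
    b <- read_ct(f)
    expect_equal(b$sequence, rec$sequence)
    expect_true(pairs_identical(b$pairs, rec$pairs))
  }
})

test_that("malformed CT files are rejected", {
  td <- withr::local_tempdir()
  bad <- file.path(td, "bad.ct")
  # inconsistent partners: row 1 says 5, row 5 says 3
  writeLines(c("5 bad",
               "1 G 0 2 5 1", "2 A 1 3 0 2", "3 A 2 4 0 3",
               "4 A 3 5 0 4", "5 C 4 0 3 5"), bad)
  expect_error(read_ct(bad), "inconsistent partners")
  writeLines(c("2 bad", "1 G 0 2 x 1", "2 A 1 0 0 2"), bad)
  expect_error(read_ct(bad), "non-integer")
  # multi-structure file: first structure kept, with a warning
  r <- rna_record("m", "GAAAC", cbind(1L, 5L))
  f <- file.path(td, "m.ct")
  write_ct(r, f)
  lines <- readLines(f)
  writeLines(c(lines, lines), f)
  expect_warning(b <- read_ct(f), "more than one structure")
  expect_true(pairs_identical(b$pairs, r$pairs))
})

test_that("length_filter keeps exactly the short-enough records, in order", {
  recs <- lapply(c(10L, 30L, 20L, 40L), function(n)
    rna_record(paste0("r", n), strrep("A", n)))
  kept <- length_filter(recs, max_len = 25L, quiet = TRUE)
  expect_equal(vapply(kept, `[[`, "", "id"), c("r10", "r20"))
  expect_equal(length_filter(list(), quiet = TRUE), list())
  expect_equal(length_filter(recs, max_len = 100L, quiet = TRUE), recs)
  expect_message(length_filter(recs, max_len = 25L), "2 record")
})

test_that("FASTA input yields structure-less records with T read as U", {
  td <- withr::local_tempdir()
  fa <- file.path(td, "in.fa")
  writeLines(c(">seq1 some description", "ACGT", ">seq2", "GGAA", "CCUU"), fa)
  recs <- read_fasta_records(fa)
  expect_equal(length(recs), 2L)
  expect_equal(recs[[1]]$id, "seq1")
  expect_equal(recs[[1]]$sequence, "ACGU")
  expect_equal(recs[[2]]$sequence, "GGAACCUU")
  expect_equal(nrow(recs[[1]]$pairs), 0L)
})
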