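test_that("random sequences respect length, alphabet and composition", {
  set.seed(3)
  s <- random_sequence(50)
  expect_equal(nchar(s), 50L)
  expect_true(all(strsplit(s, "")[[1]] %in% AA_CODES))
  set.seed(9); s1 <- random_sequence(80)
  set.seed(9); s2 <- random_sequence(80)
  expect_identical(s1, s2)
  # composition of 10000 residues within 2 binomial s.d. of uniform
  set.seed(5)
  counts <- table(factor(strsplit(random_sequence(10000), "")[[1]],
                         levels = AA_CODES))
  sd2 <- 2 * sqrt(10000 * 0.05 * 0.95)
  expect_true(all(abs(counts - 500) <= sd2))
})

test_that("datasets have the configured shape and are seed-deterministic", {
  cfg <- synthetic_config(n_pos = 40L, n_neg = 30L, seed = 5L)
  d <- generate_pair_dataset(cfg)
  expect_equal(nrow(d$pairs), 70L)
  expect_equal(sum(d$pairs$label == 1L), 40L)
  expect_equal(length(d$sequences), 140L)
  expect_false(anyDuplicated(names(d$sequences)) > 0)
  lens <- nchar(d$sequences)
  expect_true(all(lens >= 32L & lens <= 70L))
  expect_identical(generate_pair_dataset(cfg), d)
  d2 <- generate_pair_dataset(synthetic_config(n_pos = 40L, n_neg = 30L,
                                               seed = 6L))
  expect_false(identical(d2$sequences, d$sequences))
  # train/test partition the pairs
  expect_equal(nrow(d$train) + nrow(d$test), 70L)
})

test_that("configuration is validated", {
  expect_error(synthetic_config(motif_length = 40L), "infeasible")
  expect_error(synthetic_config(length_range = c(10L, 50L)), "at least 16")
  expect_error(synthetic_config(signal_strength = 1.5))
})

test_that("the planted signal lives in low-lag hydrophobicity AC", {
  d <- tiny_dataset(200L, 200L, seed = 13L)
  lowlag <- function(id) {
    f <- seq_features(d$sequences[[id]], default_scales["hydrophobicity"])
    mean(f[1:7])
  }
  pos_ids <- with(d$pairs, c(idA[label == 1L], idB[label == 1L]))
  neg_ids <- with(d$pairs, c(idA[label == 0L], idB[label == 0L]))
  pos <- vapply(pos_ids, lowlag, 0)
  neg <- vapply(neg_ids, lowlag, 0)
  tt <- stats::t.test(pos, neg)
  expect_lt(tt$p.value, 1e-6)
  expect_gt(mean(pos), mean(neg))
})

test_that("zero signal strength reduces binders to background", {
  d0 <- generate_pair_dataset(synthetic_config(n_pos = 150L, n_neg = 150L,
                                               seed = 17L,
                                               signal_strength = 0))
  lowlag <- function(id) {
    f <- seq_features(d0$sequences[[id]], default_scales["hydrophobicity"])
    mean(f[1:7])
  }
  pos <- vapply(with(d0$pairs, idA[label == 1L]), lowlag, 0)
  neg <- vapply(with(d0$pairs, idA[label == 0L]), lowlag, 0)
  expect_gt(stats::t.test(pos, neg)$p.value, 0.01)
})

test_that("fixtures round-trip through FASTA + TSV", {
  d <- tiny_dataset(20L, 20L, seed = 19L)
  dir <- file.path(tempfile(), "fx")
  paths <- write_fixture(d, dir)
  expect_true(all(file.exists(paths)))
  seqs <- read_fasta(paths[["fasta"]])
  expect_identical(seqs, d$sequences)
  expect_equal(length(readLines(paths[["fasta"]])),
               2L * length(d$sequences))
  pairs <- read_pairs(paths[["pairs"]])
  expect_identical(pairs$idA, d$pairs$idA)
  expect_identical(pairs$label, d$pairs$label)
  expect_identical(read_pairs(paths[["train"]])$idA, d$train$idA)
})
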