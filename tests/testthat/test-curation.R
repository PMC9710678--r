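test_that("sequence similarity matches definition and oracle", {
  expect_equal(sequence_similarity("PEPTIDE", "PEPTIDE"), 1.0)
  expect_equal(sequence_similarity("AAAA", "CCCC"), 0.0)
  expect_equal(sequence_similarity("ACDEFG", "ACDEFA"), 5 / 6)
  # brute-force enumeration oracle on tiny random strings
  set.seed(13)
  for (rep in 1:8) {
    a <- random_aa(sample(3:7, 1)); b <- random_aa(sample(3:7, 1))
    expect_equal(sequence_similarity(a, b), oracle_similarity(a, b))
    expect_equal(sequence_similarity(a, b), sequence_similarity(b, a))
  }
  expect_error(sequence_similarity("", "AA"))
})

test_that("pair similarity picks the better of the two combinations", {
  a1 <- random_aa(50, seed = 5); a2 <- random_aa(50)
  expect_equal(as.numeric(pair_similarity(a1, a2, a1, a2)), c(1, 1))
  # swapping within-pair order leaves the (sorted) result unchanged
  b1 <- random_aa(50); b2 <- random_aa(50)
  s1 <- pair_similarity(a1, a2, b1, b2)
  s2 <- pair_similarity(a1, a2, b2, b1)
  expect_equal(sort(as.numeric(s1)), sort(as.numeric(s2)))
  s3 <- pair_similarity(a2, a1, b1, b2)
  expect_equal(sort(as.numeric(s1)), sort(as.numeric(s3)))
  # unrelated random 50-mers stay dissimilar and match the direct evaluation
  sims <- c(sequence_similarity(a1, b1), sequence_similarity(a2, b2),
            sequence_similarity(a1, b2), sequence_similarity(a2, b1))
  expect_true(all(s1 < 0.3))
  best <- if (sims[1] + sims[2] >= sims[3] + sims[4]) sims[1:2] else sims[3:4]
  expect_equal(as.numeric(s1), best)
})

test_that("similarity histogram conserves counts and localizes mass", {
  seqs <- c(p1 = random_aa(30, seed = 9), p2 = random_aa(30))
  one <- data.frame(idA = "p1", idB = "p2")
  H <- similarity_histogram(one, one, seqs, bins = 10L)
  expect_equal(H[10L, 10L], 1L)
  expect_equal(sum(H), 1L)
  set.seed(10)
  seqs2 <- setNames(vapply(1:12, function(i) random_aa(40), ""),
                    paste0("s", 1:12))
  set1 <- data.frame(idA = paste0("s", 1:3), idB = paste0("s", 4:6))
  set2 <- data.frame(idA = paste0("s", 7:9), idB = paste0("s", 10:12))
  H2 <- similarity_histogram(set1, set2, seqs2, bins = 5L)
  expect_equal(sum(H2), nrow(set1) * nrow(set2))
  # unrelated pairs: all mass in the low-similarity corner
  expect_equal(sum(H2[1:2, 1:2]), sum(H2))
  expect_error(similarity_histogram(set1[0, ], set2, seqs2), "empty")
})

test_that("redundancy filter keeps the long representative and drops copies", {
  set.seed(23)
  base <- random_aa(60)
  mutate <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    idx <- sample(length(v), k)
    v[idx] <- sample(AA_CODES, k, replace = TRUE)
    paste(v, collapse = "")
  }
  seqs <- c(a1 = base, a2 = random_aa(60),
            b1 = mutate(base, 3L), b2 = mutate(random_aa(60), 0L),
            c1 = random_aa(45), c2 = random_aa(45))
  seqs["b2"] <- seqs["a2"]  # pair2 ~ 95%-identical copy of pair1
  pairs <- data.frame(idA = c("a1", "b1", "c1"), idB = c("a2", "b2", "c2"),
                      label = c(1L, 1L, 1L))
  kept <- redundancy_filter(pairs, seqs, threshold = 0.5)
  expect_identical(kept$idA, c("a1", "c1"))
  # oracle audit: survivors pairwise below threshold
  cat_seq <- paste0(seqs[kept$idA], seqs[kept$idB])
  for (i in seq_along(cat_seq))
    for (j in seq_len(i - 1L))
      expect_lte(sequence_similarity(cat_seq[i], cat_seq[j]), 0.5)
})

test_that("redundancy filter: duplicates collapse, dissimilar sets pass", {
  d <- tiny_dataset()
  pairs <- d$pairs[1:10, ]
  expect_identical(redundancy_filter(pairs, d$sequences), pairs)
  dup <- rbind(pairs, pairs[3, ], data.frame(idA = pairs$idB[5],
                                             idB = pairs$idA[5],
                                             label = pairs$label[5]))
  kept <- redundancy_filter(dup, d$sequences)
  expect_equal(nrow(kept), 10L)
  # full all-vs-all audit against the similarity matrix
  cs <- paste0(d$sequences[pmin(kept$idA, kept$idB)],
               d$sequences[pmax(kept$idA, kept$idB)])
  M <- outer(seq_along(cs), seq_along(cs), Vectorize(function(i, j)
    if (i == j) 0 else sequence_similarity(cs[i], cs[j])))
  expect_true(all(M <= 0.5))
})

test_that("negative sampling is seeded, sized and redundancy-controlled", {
  d <- tiny_dataset(100L, 100L, seed = 31L)
  positives <- d$pairs[d$pairs$label == 1L, ][1:50, ]
  candidates <- d$pairs[d$pairs$label == 0L, ]
  candidates$label <- NULL
  neg <- sample_negatives(positives, candidates, d$sequences, seed = 4L)
  expect_equal(nrow(neg), 50L)
  expect_true(all(neg$label == 0L))
  expect_identical(neg,
                   sample_negatives(positives, candidates, d$sequences,
                                    seed = 4L))
  neg2 <- sample_negatives(positives, candidates, d$sequences, seed = 5L)
  expect_false(identical(neg$idA, neg2$idA))
  # pool of exact duplicates collapses to one, with a warning
  dup_pool <- data.frame(idA = rep(candidates$idA[1], 5),
                         idB = rep(candidates$idB[1], 5))
  expect_warning(one <- sample_negatives(positives, dup_pool, d$sequences,
                                         seed = 1L), "exhausted")
  expect_equal(nrow(one), 1L)
  expect_error(sample_negatives(positives, candidates[0, ], d$sequences),
               "empty")
})

test_that("train/test split is stratified, disjoint and conservative", {
  d <- tiny_dataset(60L, 40L, seed = 41L)
  sp <- split_train_test(d$pairs, 0.25, seed = 2L)
  expect_equal(nrow(sp$test), 25L)
  expect_equal(sum(sp$test$label == 1L), 15L)
  expect_equal(sum(sp$test$label == 0L), 10L)
  key <- function(p) sort(paste(pmin(p$idA, p$idB), pmax(p$idA, p$idB)))
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)
  expect_setequal(c(key(sp$train), key(sp$test)), key(d$pairs))
  # 100 pairs at fraction 0.12 -> 12 test
  sp2 <- split_train_test(d$pairs, 0.12, seed = 3L)
  expect_equal(nrow(sp2$test), 12L)
  expect_error(split_train_test(d$pairs[d$pairs$label == 1L, ], 0.2),
               "at least 2")
})

test_that("FASTA and pair-list files round-trip", {
  d <- tiny_dataset()
  fa <- tempfile(fileext = ".fasta")
  write_fasta(d$sequences, fa)
  expect_identical(read_fasta(fa), d$sequences)
  expect_equal(length(readLines(fa)), 2L * length(d$sequences))
  tsv <- tempfile(fileext = ".tsv")
  write_pairs(d$pairs, tsv)
  back <- read_pairs(tsv)
  expect_identical(back$idA, d$pairs$idA)
  expect_identical(back$label, d$pairs$label)
  writeLines(c("a\tb\t7"), tsv)
  expect_error(read_pairs(tsv), "0 or 1")
  expect_error(read_fasta(tempfile()), "not found")
})
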