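test_that("AUC follows the rank statistic, verified by pair counting", {
  expect_equal(roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_curve(rep(0.4, 10), rep(c(1, 0), 5))$auc, 0.5)
  expect_equal(roc_curve(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4),
                         c(1, 1, 0, 1, 0, 0))$auc, 8 / 9)
  set.seed(14)
  for (rep in 1:5) {
    n <- sample(20:200, 1)
    scores <- round(runif(n), 2)  # rounding forces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_curve(scores, labels)$auc, oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(roc_curve(c(0.1, 0.9), c(1, 1)), "both classes")
  pts <- roc_curve(c(0.9, 0.1, 0.5, 0.3), c(1, 0, 1, 0))$points
  expect_true(all(diff(pts$fpr) >= 0), all(diff(pts$tpr) >= 0))
})

test_that("confusion statistics match a hand-rolled count oracle", {
  r <- confusion_at_threshold(c(0.9, 0.2), c(1, 0), 0.5)
  expect_equal(r$sensitivity, 1); expect_equal(r$specificity, 1)
  expect_equal(r$accuracy, 1)
  set.seed(15)
  scores <- runif(20); labels <- rbinom(20, 1, 0.5)
  labels[1:2] <- c(0L, 1L)
  for (thr in c(0, 0.3, 0.5, 0.8)) {
    got <- confusion_at_threshold(scores, labels, thr)
    want <- oracle_confusion(scores, labels, thr)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$specificity, want$specificity)
    expect_equal(got$accuracy, want$accuracy)
  }
  expect_equal(confusion_at_threshold(scores, labels, 0)$sensitivity, 1)
  expect_equal(confusion_at_threshold(scores, labels,
                                      max(scores) + 0.01)$specificity, 1)
})

test_that("proteome scan returns a complete ranked list with warnings", {
  model <- tiny_rf()
  d <- tiny_dataset()
  db <- d$sequences[1:10]
  query <- d$sequences[[11]]
  res <- scan_proteome(model, query, db)
  expect_equal(nrow(res), 10L)
  expect_setequal(res$target_id, names(db))
  expect_true(all(diff(res$score) <= 0))
  # ties broken by id: order is a deterministic function of the inputs
  expect_identical(res, scan_proteome(model, query, db))
  w <- capture_warnings(scan_proteome(model, "ANLMKWYSTRAC", db))
  expect_true(any(grepl("16", w)))
  dbx <- c(db, bad = "ACDEFXX")
  w2 <- capture_warnings(res2 <- scan_proteome(model, query, dbx))
  expect_true(any(grepl("skipping", w2)))
  expect_equal(attr(res2, "skipped"), "bad")
  expect_equal(nrow(res2), 10L)
  expect_error(scan_proteome(model, query, character(0)), "empty")
  # FASTA path input
  fa <- tempfile(fileext = ".fasta")
  write_fasta(db, fa)
  expect_identical(scan_proteome(model, query, fa)$target_id, res$target_id)
})

test_that("permutation importance validates blocks and sees null deltas", {
  model <- tiny_rf()
  d <- tiny_dataset()
  expect_error(permutation_feature_importance(model, d$pairs[1:4, ],
                                              d$sequences, "bogus"),
               "unknown feature block")
  # self-pairs make the block constant across all augmented rows (the
  # reversal-invariant descriptor gives every representation the same
  # features), so any permutation is a no-op => all deltas 0
  same <- data.frame(idA = rep(d$pairs$idA[1], 6),
                     idB = rep(d$pairs$idA[1], 6),
                     label = rep(c(1L, 0L), 3))
  delta <- permutation_feature_importance(model, same, d$sequences,
                                          "hydrophobicity", seed = 2L)
  expect_equal(unname(delta), rep(0, 4), tolerance = 1e-8)
})
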