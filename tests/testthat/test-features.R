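test_that("translation maps residues through every scale", {
  ts <- translate("ANLMK", default_scales)
  expect_equal(dim(ts$S), c(5L, 7L))
  for (j in seq_along(default_scales))
    expect_equal(ts$S[, j],
                 unname(default_scales[[j]]$values[c("A", "N", "L", "M", "K")]))
  # homogeneous sequence: constant columns
  expect_true(all(apply(translate("AAAA", default_scales)$S, 2,
                        function(x) length(unique(x)) == 1L)))
})

test_that("non-standard residues follow the strict/drop policy", {
  expect_error(translate("ACUX", default_scales), "U, X")
  expect_warning(ts <- translate("ACUX", default_scales,
                                 on_nonstandard = "drop"), "dropping")
  expect_equal(ts$n, 2L)
  expect_error(translate("  ", default_scales), "empty")
  expect_error(suppressWarnings(translate("UX", default_scales, "drop")),
               "empty")
})

test_that("descriptor dimensions are 7 x max_lag, 210 by default", {
  set.seed(5)
  f <- seq_features(random_aa(40), default_scales)
  expect_length(f, 210L)
  expect_length(seq_features(random_aa(40), default_scales, max_lag = 12L),
                7L * 12L)
  pf <- pair_features(random_aa(35), random_aa(50), default_scales)
  expect_length(pf, 420L)
})

test_that("autocorrelation matches the brute-force oracle", {
  set.seed(11)
  for (rep in 1:10) {
    ts <- translate(random_aa(sample(5:80, 1)), default_scales)
    expect_equal(unname(autocorrelation_quiet(ts)), oracle_ac(ts$S),
                 tolerance = 1e-10)
  }
})

test_that("autocorrelation conventions: homopolymer, short lags, warnings", {
  ts <- translate("AAAAAAAA", default_scales)
  expect_equal(unname(autocorrelation_quiet(ts)), rep(0, 210))
  # lag >= n zero-filled with a warning
  ts2 <- translate(random_aa(20, seed = 3), default_scales)
  expect_warning(f <- autocorrelation(ts2), "zero-filled")
  zero_lags <- as.vector(vapply(1:7, function(j)
    (j - 1L) * 30L + 20:30, integer(11)))
  expect_true(all(f[zero_lags] == 0))
  w <- capture_warnings(autocorrelation(translate(random_aa(10, seed = 4),
                                                  default_scales)))
  expect_true(any(grepl("minimum of 16", w)))
})

test_that("autocorrelation is invariant under sequence reversal", {
  set.seed(21)
  for (rep in 1:8) {
    s <- random_aa(sample(17:120, 1))
    expect_equal(seq_features(s, default_scales),
                 seq_features(reverse_seq(s), default_scales),
                 tolerance = 1e-10)
  }
})

test_that("permuting scale order permutes the 30-lag blocks", {
  s <- random_aa(60, seed = 31)
  perm <- c(3L, 1L, 7L, 2L, 6L, 4L, 5L)
  f1 <- seq_features(s, default_scales)
  f2 <- seq_features(s, default_scales[names(default_scales)[perm]])
  blocks <- function(f, j) f[(j - 1L) * 30L + 1:30]
  for (k in seq_along(perm))
    expect_equal(unname(blocks(f2, k)), unname(blocks(f1, perm[k])))
})

test_that("pair features are ordered and swap with their arguments", {
  a <- random_aa(40, seed = 41); b <- random_aa(55)
  fab <- pair_features(a, b, default_scales)
  fba <- pair_features(b, a, default_scales)
  expect_equal(unname(fab), unname(c(fba[211:420], fba[1:210])))
  faa <- pair_features(a, a, default_scales)
  expect_equal(unname(faa[1:210]), unname(faa[211:420]))
  expect_false(isTRUE(all.equal(fab, fba)))
})

test_that("augmentation yields the four stated representations", {
  reps <- augment_pair("ANLMK", "WYSTR", label = 1L)
  expect_length(reps, 4L)
  expect_identical(vapply(reps, `[[`, "", "a"),
                   c("ANLMK", "WYSTR", "ANLMK", "WYSTR"))
  expect_identical(reps[[3L]]$b, "RTSYW")  # B inverted
  expect_identical(reps[[4L]]$b, "KMLNA")  # A inverted: 'ANLMK' -> 'KMLNA'
  expect_identical(reverse_seq("ANLMK"), "KMLNA")
  expect_true(all(vapply(reps, `[[`, 0L, "label") == 1L))
})

test_that("reversal invariance collapses inverse representations in feature space", {
  a <- random_aa(45, seed = 51); b <- random_aa(38)
  expect_equal(pair_features(a, reverse_seq(b), default_scales),
               pair_features(a, b, default_scales), tolerance = 1e-10)
})
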