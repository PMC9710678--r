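gnn0 <- seqppi:::init_gnn(default_scales, gnn_config(seed = 3L))

test_that("chain graphs have the documented structure", {
  s <- random_aa(10, seed = 1)
  g <- build_graph(s, default_scales, gnn0)
  expect_equal(g$n, 10L)
  expect_equal(nrow(g$edges), 18L)            # 9 undirected adjacencies
  expect_equal(dim(g$node), c(32L, 10L))      # learned 32-dim encoding
  expect_equal(dim(g$node_raw), c(7L, 10L))
  expect_true(all(g$edge == 1))               # edges initialized to ones
  expect_warning(g1 <- build_graph("A", default_scales, gnn0), "length-1")
  expect_equal(nrow(g1$edges), 0L)
})

test_that("message passing preserves topology and is deterministic", {
  g <- build_graph(random_aa(15, seed = 2), default_scales, gnn0)
  g2 <- message_passing_round(g, gnn0)
  expect_equal(g2$n, g$n)
  expect_identical(g2$edges, g$edges)
  expect_equal(dim(g2$edge), dim(g$edge))
  g3 <- message_passing_round(g, gnn0)
  expect_identical(g2$node, g3$node)
  expect_identical(g2$global, g3$global)
  # edge storage order does not affect the update (mean aggregation)
  perm <- sample(nrow(g$edges))
  gp <- g
  gp$edges <- g$edges[perm, , drop = FALSE]
  gp$edge <- g$edge[, perm, drop = FALSE]
  gpu <- message_passing_round(gp, gnn0)
  expect_equal(gpu$node, g2$node, tolerance = 1e-12)
  expect_equal(gpu$global, g2$global, tolerance = 1e-12)
  expect_equal(gpu$edge[, order(perm), drop = FALSE], g2$edge,
               tolerance = 1e-12)
})

test_that("readout and pair head have dims 128 / 256 and sigmoid output", {
  z <- encode_sequence(random_aa(25, seed = 3), gnn0)
  expect_length(z, 128L)
  expect_equal(nrow(gnn0$params$head_W1), gnn0$config$pair_hidden)
  expect_equal(ncol(gnn0$params$head_W1), 256L)
  a <- random_aa(30); b <- random_aa(22)
  s <- predict_gnn(gnn0, a, b)
  expect_gt(s, 0); expect_lt(s, 1)
  expect_false(isTRUE(all.equal(predict_gnn(gnn0, a, b),
                                predict_gnn(gnn0, b, a))))
  sym <- predict_gnn(gnn0, a, b, symmetrize = TRUE)
  expect_equal(sym, (predict_gnn(gnn0, a, b) + predict_gnn(gnn0, b, a)) / 2)
  # zero-parameter network: sigmoid(0) everywhere
  z0 <- seqppi:::init_gnn(default_scales, gnn_config(), zero = TRUE)
  expect_equal(predict_gnn(z0, a, b), 0.5)
})

test_that("C++ training path and R prediction path agree", {
  set.seed(8)
  seqs <- setNames(vapply(1:8, function(i) random_aa(sample(18:40, 1)), ""),
                   paste0("q", 1:8))
  pairs <- data.frame(idA = paste0("q", 1:4), idB = paste0("q", 5:8))
  batch <- seqppi:::predict_gnn_batch(gnn0, pairs, seqs)
  single <- mapply(function(a, b) predict_gnn(gnn0, seqs[[a]], seqs[[b]]),
                   pairs$idA, pairs$idB)
  expect_equal(unname(batch), unname(single), tolerance = 1e-5)
})

test_that("analytic gradients match finite differences of the R forward", {
  sq <- c("ACDEFGHIKLMNPQRSTVWY", "MKLVFFAEDVGSNKGAIIGL", "PPPPGGGGSSSSTT")
  ia <- c(1L, 2L); ib <- c(2L, 3L); y <- c(1, 0)
  prof <- seqppi:::scale_profile_matrix(default_scales)
  codes <- lapply(sq, function(s) seqppi:::seq_to_codes(s) - 1L)
  g <- seqppi:::gnn_grad_cpp(gnn0$params, prof, codes, ia - 1L, ib - 1L, y,
                             5L, 0.01)
  rloss <- function(params) {
    mm <- gnn0; mm$params <- params
    s <- mapply(function(i, j) predict_gnn(mm, sq[i], sq[j]), ia, ib)
    s <- pmin(pmax(s, 1e-7), 1 - 1e-7)
    -mean(y * log(s) + (1 - y) * log(1 - s))
  }
  expect_equal(g$loss, rloss(gnn0$params), tolerance = 1e-5)
  set.seed(99)
  for (nm in names(gnn0$params)) {
    d <- dim(gnn0$params[[nm]])
    i <- sample(d[1], 1); j <- sample(d[2], 1)
    p1 <- gnn0$params; p1[[nm]][i, j] <- p1[[nm]][i, j] + 1e-6
    p2 <- gnn0$params; p2[[nm]][i, j] <- p2[[nm]][i, j] - 1e-6
    fd <- (rloss(p1) - rloss(p2)) / 2e-6
    an <- g$grads[[nm]][i, j]
    expect_equal(an, fd, tolerance = max(0.01, 1e-6 / max(abs(fd), 1e-8)),
                 label = paste("grad", nm))
  }
})

test_that("training reduces the loss and is reproducible under seed", {
  d <- tiny_dataset(100L, 100L, seed = 55L)
  cfg <- gnn_desk_config(epochs = 20L, seed = 4L)
  m1 <- train_gnn(d$pairs, d$sequences, default_scales, cfg)
  expect_length(m1$loss, 20L)
  expect_lt(mean(tail(m1$loss, 3)), mean(head(m1$loss, 3)))
  m2 <- train_gnn(d$pairs, d$sequences, default_scales, cfg)
  expect_identical(m1$params, m2$params)
  pos_only <- d$pairs[d$pairs$label == 1L, ]
  expect_error(train_gnn(pos_only, d$sequences, default_scales, cfg),
               "both classes")
  expect_error(train_gnn(d$pairs, d$sequences, default_scales[1:3],
                         gnn_desk_config(epochs = 1L)),
               "profile_count")
})

test_that("GNN models round-trip through disk", {
  d <- tiny_dataset()
  m <- train_gnn(d$pairs, d$sequences, default_scales,
                 gnn_desk_config(epochs = 2L, seed = 6L))
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  loaded <- load_model(path)
  probe <- d$pairs[1:5, ]
  expect_identical(seqppi:::predict_gnn_batch(loaded, probe, d$sequences),
                   seqppi:::predict_gnn_batch(m, probe, d$sequences))
})
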