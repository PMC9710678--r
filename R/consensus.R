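# Consensus combiner: a fully connected 2-8-8-1 network over the RF and
# GNN scores, leaky-ReLU hidden layers, sigmoid output, trained with
# binary cross-entropy + Adam (decoupled weight decay). Small enough to be
# implemented directly in R with hand-written gradients.

#' Construct a fresh consensus network
#'
#' Layer sizes 2-8-8-1: exactly 105 parameters
#' ((2x8+8) + (8x8+8) + (8x1+1)).
#'
#' @param seed integer seed for He-uniform initialization.
#' @param leaky_slope negative slope of the hidden activations.
#' @return object of class `consensus_net`.
#' @export
consensus_net <- function(seed = 1L, leaky_slope = 0.01) {
  params <- with_seed(seed, list(
    W1 = he_uniform(8L, 2L, leaky_slope), b1 = matrix(0, 8L, 1L),
    W2 = he_uniform(8L, 8L, leaky_slope), b2 = matrix(0, 8L, 1L),
    W3 = he_uniform(1L, 8L, leaky_slope), b3 = matrix(0, 1L, 1L)))
  structure(list(params = params, leaky_slope = leaky_slope,
                 loss = numeric(0), version = 1L, kind = "consensus"),
            class = "consensus_net")
}

#' Number of parameters of a consensus network
#' @param net a `consensus_net`.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "consensus_net"))
  sum(vapply(net$params, length, 1L))
}

consensus_forward <- function(params, X, slope) {
  H1 <- leaky(params$W1 %*% X + as.vector(params$b1), slope)
  H2 <- leaky(params$W2 %*% H1 + as.vector(params$b2), slope)
  s <- sigmoid(params$W3 %*% H2 + as.vector(params$b3))
  list(H1 = H1, H2 = H2, s = as.vector(s))
}

#' Train the consensus combiner
#'
#' Fits the 2-8-8-1 network on paired (RF score, GNN score) inputs with
#' binary cross-entropy, full-batch Adam with decoupled weight decay, and
#' early stopping on loss plateau. The score vectors must come from
#' predictions on data that was not used to train the base models (e.g. an
#' internal 80/20 split of the training set) to avoid leakage.
#'
#' @param rf_scores,gnn_scores numeric vectors in \[0, 1\], equal length.
#' @param labels 0/1 vector of the same length, both classes present.
#' @param seed integer seed.
#' @param epochs maximum epochs (default 500).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param weight_decay decoupled weight decay.
#' @param patience early-stop after this many epochs without improvement.
#' @return trained `consensus_net`.
#' @export
train_consensus <- function(rf_scores, gnn_scores, labels, seed = 1L,
                            epochs = 500L, learning_rate = 1e-3,
                            weight_decay = 1e-4, patience = 50L) {
  n <- length(labels)
  if (length(rf_scores) != n || length(gnn_scores) != n)
    stop("rf_scores, gnn_scores and labels must have equal length")
  if (any(rf_scores < 0 | rf_scores > 1) || any(gnn_scores < 0 | gnn_scores > 1))
    stop("scores must lie in [0, 1]")
  if (length(unique(labels)) < 2L)
    stop("training data must contain both classes")
  net <- consensus_net(seed)
  p <- net$params
  sl <- net$leaky_slope
  X <- rbind(rf = rf_scores, gnn = gnn_scores)
  y <- as.numeric(labels)
  m <- lapply(p, function(w) w * 0)
  v <- m
  b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
  best <- Inf; stall <- 0L
  loss_hist <- numeric(0)
  for (ep in seq_len(epochs)) {
    fw <- consensus_forward(p, X, sl)
    s <- pmin(pmax(fw$s, 1e-12), 1 - 1e-12)
    loss <- -mean(y * log(s) + (1 - y) * log(1 - s))
    loss_hist <- c(loss_hist, loss)
    if (loss < best - 1e-9) { best <- loss; stall <- 0L } else stall <- stall + 1L
    if (stall >= patience) break
    dlogit <- matrix((fw$s - y) / n, 1L)
    g <- list()
    g$W3 <- dlogit %*% t(fw$H2); g$b3 <- matrix(sum(dlogit), 1L)
    dH2 <- (t(p$W3) %*% dlogit) * ifelse(fw$H2 > 0, 1, sl)
    g$W2 <- dH2 %*% t(fw$H1); g$b2 <- matrix(rowSums(dH2), ncol = 1L)
    dH1 <- (t(p$W2) %*% dH2) * ifelse(fw$H1 > 0, 1, sl)
    g$W1 <- dH1 %*% t(X); g$b1 <- matrix(rowSums(dH1), ncol = 1L)
    for (k in names(p)) {
      p[[k]] <- p[[k]] * (1 - learning_rate * weight_decay)
      m[[k]] <- b1m * m[[k]] + (1 - b1m) * g[[k]]
      v[[k]] <- b2m * v[[k]] + (1 - b2m) * g[[k]]^2
      mh <- m[[k]] / (1 - b1m^ep)
      vh <- v[[k]] / (1 - b2m^ep)
      p[[k]] <- p[[k]] - learning_rate * mh / (sqrt(vh) + eps)
    }
  }
  net$params <- p
  net$loss <- loss_hist
  net
}

#' Consensus score for a pair of base-model scores
#'
#' @param net trained `consensus_net`.
#' @param rf_score,gnn_score scores in \[0, 1\] (scalars or equal-length
#'   vectors).
#' @return consensus score(s) strictly in (0, 1).
#' @export
predict_consensus <- function(net, rf_score, gnn_score) {
  stopifnot(inherits(net, "consensus_net"))
  if (any(rf_score < 0 | rf_score > 1) || any(gnn_score < 0 | gnn_score > 1))
    stop("scores must lie in [0, 1]")
  consensus_forward(net$params, rbind(rf_score, gnn_score),
                    net$leaky_slope)$s
}

#' @export
print.consensus_net <- function(x, ...) {
  cat("<consensus_net> 2-8-8-1,", count_parameters(x), "parameters,",
      if (length(x$loss)) paste("trained", length(x$loss), "epochs")
      else "untrained", "\n")
  invisible(x)
}
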