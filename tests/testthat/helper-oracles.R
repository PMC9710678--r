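# Independent brute-force oracles. These deliberately mirror the printed
# definitions with naive loops and stay independent of the package's
# computational paths.

# naive double-loop autocorrelation (scale-major output)
oracle_ac <- function(S, max_lag = 30L) {
  n <- nrow(S)
  p <- ncol(S)
  out <- numeric(p * max_lag)
  for (j in seq_len(p)) {
    mu <- sum(S[, j]) / n
    sigma2 <- sum((S[, j] - mu)^2) / n
    for (lag in seq_len(max_lag)) {
      if (lag >= n || sigma2 == 0) next
      acc <- 0
      for (i in seq_len(n - lag))
        acc <- acc + (S[i, j] - mu) * (S[i + lag, j] - mu)
      out[(j - 1L) * max_lag + lag] <- acc / ((n - lag) * sigma2)
    }
  }
  out
}

# exhaustive global-alignment score: max over all alignments of
# (#identical aligned positions) + gap * (#gap positions); pure recursion,
# only for tiny strings
oracle_align_score <- function(a, b, gap = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(av)) return(gap * (length(bv) - j + 1L))
    if (j > length(bv)) return(gap * (length(av) - i + 1L))
    max(rec(i + 1L, j + 1L) + as.integer(av[i] == bv[j]),
        rec(i + 1L, j) + gap,
        rec(i, j + 1L) + gap)
  }
  rec(1L, 1L)
}

oracle_similarity <- function(a, b) {
  max(0, oracle_align_score(a, b)) / max(nchar(a), nchar(b))
}

# AUC as the probability that a random positive outranks a random negative,
# ties counted half, by explicit pair enumeration
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos)
    for (q in neg)
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

oracle_confusion <- function(scores, labels, threshold) {
  tp <- fn <- tn <- fp <- 0L
  for (k in seq_along(scores)) {
    called <- scores[k] >= threshold
    if (labels[k] == 1 && called) tp <- tp + 1L
    if (labels[k] == 1 && !called) fn <- fn + 1L
    if (labels[k] == 0 && !called) tn <- tn + 1L
    if (labels[k] == 0 && called) fp <- fp + 1L
  }
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(scores))
}

autocorrelation_quiet <- function(ts, max_lag = 30L)
  suppressWarnings(seqppi::autocorrelation(ts, max_lag))

random_aa <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(seqppi::AA_CODES, n, replace = TRUE), collapse = "")
}
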