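# Proteome scanning and ROC-based evaluation.

#' Scan a proteome database for binding partners of a query
#'
#' Scores the query against every sequence of a FASTA database (or named
#' vector) and returns the ranked list, highest score first, ties broken by
#' target id so output is reproducible. Sequences shorter than 16 residues
#' trigger a warning (the predictors were tuned for length >= 16) but are
#' scored; sequences that cannot be translated under the strict residue
#' policy are skipped and listed in the `skipped` attribute.
#'
#' @param model a trained `ppi_rf` or `ppi_gnn`.
#' @param query_seq query amino-acid string.
#' @param db path to a FASTA file or a named character vector.
#' @param symmetrize for GNN models, average over both argument orders.
#' @return data.frame (`target_id`, `score`) sorted by descending score,
#'   with attributes `query_id`, `method` and `skipped`.
#' @export
scan_proteome <- function(model, query_seq, db, symmetrize = FALSE) {
  stopifnot(inherits(model, "ppi_model"))
  sequences <- if (is.character(db) && length(db) == 1L && is.null(names(db)))
    read_fasta(db) else db
  if (!length(sequences)) stop("empty database")
  if (is.null(names(sequences))) stop("database sequences must be named")
  if (nchar(clean_seq(query_seq)) < 16L)
    warning("query shorter than 16 residues; the prediction is computed ",
            "but the method was optimized for length >= 16")
  short <- nchar(sequences) < 16L
  if (any(short))
    warning(sum(short), " database sequence(s) shorter than 16 residues; ",
            "scored anyway")
  translatable <- vapply(sequences, function(s)
    !inherits(tryCatch(seq_to_codes(s), error = identity), "error"), TRUE)
  skipped <- names(sequences)[!translatable]
  if (length(skipped))
    warning("skipping ", length(skipped),
            " untranslatable sequence(s): ",
            paste(head(skipped, 5L), collapse = ", "))
  sequences <- sequences[translatable]
  if (!length(sequences)) stop("no translatable sequences in database")
  qid <- "query"
  while (qid %in% names(sequences)) qid <- paste0(".", qid)
  seqs <- c(stats::setNames(unname(clean_seq(query_seq)), qid), sequences)
  pairs <- data.frame(idA = qid, idB = names(sequences),
                      stringsAsFactors = FALSE)
  scores <- if (inherits(model, "ppi_rf"))
    predict_pairs(model, pairs, seqs)
  else
    predict_gnn_batch(model, pairs, seqs, symmetrize = symmetrize)
  ord <- order(-scores, names(sequences))
  out <- data.frame(target_id = names(sequences)[ord],
                    score = scores[ord], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "query_id") <- qid
  attr(out, "method") <- model$kind
  attr(out, "skipped") <- skipped
  out
}

check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2L)
    stop("both classes must be present")
}

#' ROC curve and AUC
#'
#' The AUC is computed by the rank (trapezoid) method and equals the
#' probability that a random positive outranks a random negative, with
#' ties counted half.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels (both classes present).
#' @return list with `points` (data.frame fpr, tpr, threshold, one row per
#'   distinct score plus endpoints) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  check_two_classes(labels)
  y <- as.integer(labels > 0)
  npos <- sum(y); nneg <- sum(1L - y)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(y == 1L & scores >= t) / npos, 0)
  fpr <- vapply(thr, function(t) sum(y == 0L & scores >= t) / nneg, 0)
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, thr))
  list(points = pts, auc = auc)
}

#' Confusion statistics at a score threshold
#'
#' A pair is called a binder when its score is at or above the threshold.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels (both classes present).
#' @param threshold decision threshold (default 0.5; stricter operating
#'   points such as 0.7/0.8/0.9 trade sensitivity for specificity).
#' @return object of class `roc_summary`: list with `auc`, `sensitivity`,
#'   `specificity`, `accuracy`, `threshold`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  check_two_classes(labels)
  y <- as.integer(labels > 0)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & y == 1L); fn <- sum(pred == 0L & y == 1L)
  tn <- sum(pred == 0L & y == 0L); fp <- sum(pred == 1L & y == 0L)
  structure(list(auc = roc_curve(scores, labels)$auc,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 accuracy = (tp + tn) / length(y),
                 threshold = threshold),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf(
    "<roc_summary> AUC %.3f | sens %.3f | spec %.3f | acc %.3f @ thr %.2f\n",
    x$auc, x$sensitivity, x$specificity, x$accuracy, x$threshold))
  invisible(x)
}

#' Permutation importance of one scale's feature block
#'
#' Shuffles, across the evaluation pairs, the feature block belonging to
#' one scale (its 30 lags in both halves of the 420-dim pair vector),
#' re-scores with the trained forest and reports the change in performance.
#' A negative delta means the permutation degraded that metric.
#'
#' @param model trained `ppi_rf`.
#' @param pairs labelled evaluation pairs.
#' @param sequences named character vector.
#' @param feature_block scale name (e.g. `"hydrophobicity"`).
#' @param seed integer seed for the shuffle.
#' @param threshold threshold for the confusion statistics.
#' @return named numeric deltas (permuted minus baseline) for auc,
#'   sensitivity, specificity, accuracy.
#' @export
permutation_feature_importance <- function(model, pairs, sequences,
                                           feature_block, seed = 1L,
                                           threshold = 0.5) {
  stopifnot(inherits(model, "ppi_rf"), "label" %in% names(pairs))
  j <- match(feature_block, model$meta$scale_names)
  if (is.na(j))
    stop("unknown feature block '", feature_block, "'; available: ",
         paste(model$meta$scale_names, collapse = ", "))
  ml <- model$meta$max_lag
  p <- length(model$meta$scale_names)
  X <- featurize_pairs(pairs, sequences, model$scales, ml, augment = TRUE)
  y4 <- attr(X, "labels")
  cols <- c((j - 1L) * ml + seq_len(ml),            # block in first half
            p * ml + (j - 1L) * ml + seq_len(ml))   # block in second half
  score_of <- function(M) colMeans(matrix(rf_predict_cpp(model$forest, M),
                                          nrow = 4L))
  base_scores <- score_of(X)
  perm <- with_seed(seed, sample.int(nrow(X)))
  Xp <- X
  Xp[, cols] <- X[perm, cols]
  perm_scores <- score_of(Xp)
  labels <- y4[seq(1L, length(y4), by = 4L)]
  base <- confusion_at_threshold(base_scores, labels, threshold)
  permd <- confusion_at_threshold(perm_scores, labels, threshold)
  c(auc = permd$auc - base$auc,
    sensitivity = permd$sensitivity - base$sensitivity,
    specificity = permd$specificity - base$specificity,
    accuracy = permd$accuracy - base$accuracy)
}
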