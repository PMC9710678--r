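# Dataset curation: sequence/pair similarity, redundancy filtering of
# concatenated pairs at an identity threshold (a self-contained stand-in
# for a CD-HIT-style clustering run), negative sampling, stratified
# splitting, and the cross-dataset pair-similarity 2D histogram.

check_pairs <- function(pairs, sequences) {
  stopifnot(is.data.frame(pairs), all(c("idA", "idB") %in% names(pairs)))
  ids <- c(pairs$idA, pairs$idB)
  missing <- setdiff(unique(ids), names(sequences))
  if (length(missing))
    stop("pair ids not found in sequence collection: ",
         paste(head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ...")
  invisible(TRUE)
}

# canonical unordered pair key: smaller id first
pair_key <- function(idA, idB) {
  ifelse(idA <= idB, paste(idA, idB, sep = "\r"), paste(idB, idA, sep = "\r"))
}

#' Sequence identity between two amino-acid sequences
#'
#' Global (Needleman-Wunsch) alignment with match +1, mismatch 0 and gap -1
#' per position; the similarity is the optimal score (identical aligned
#' positions net of the gap penalty), floored at 0 and divided by the length
#' of the longer sequence, so it is symmetric and lies in \[0, 1\] with 1.0
#' for identical sequences. An optional shared k-mer prefilter short-cuts
#' clearly unrelated sequences to 0 without aligning.
#'
#' @param a,b amino-acid strings.
#' @param kmer_prefilter if `TRUE`, return 0 without aligning when the two
#'   sequences share no 5-mer (fast approximate mode, off by default).
#' @return similarity in \[0, 1\].
#' @export
sequence_similarity <- function(a, b, kmer_prefilter = FALSE) {
  stopifnot(nzchar(a), nzchar(b))
  a <- clean_seq(a); b <- clean_seq(b)
  if (a == b) return(1.0)
  if (isTRUE(kmer_prefilter) && nchar(a) >= 5L && nchar(b) >= 5L) {
    ka <- substring(a, 1:(nchar(a) - 4L), 5:nchar(a))
    kb <- substring(b, 1:(nchar(b) - 4L), 5:nchar(b))
    if (!any(ka %in% kb)) return(0.0)
  }
  max(0L, nw_score_cpp(a, b)) / max(nchar(a), nchar(b))
}

#' Best-combination similarity between two sequence pairs
#'
#' The input data are unordered pairs, so pair A = (a1, a2) can match pair
#' B = (b1, b2) in two ways: (Sim(a1,b1), Sim(a2,b2)) or
#' (Sim(a1,b2), Sim(a2,b1)). The combination with the larger total
#' similarity is returned (ties resolve to the first).
#'
#' @param a1,a2 sequences of the first pair.
#' @param b1,b2 sequences of the second pair.
#' @return named numeric `c(s1, s2)` with attribute `combination` (1 or 2).
#' @export
pair_similarity <- function(a1, a2, b1, b2) {
  c1 <- c(s1 = sequence_similarity(a1, b1), s2 = sequence_similarity(a2, b2))
  c2 <- c(s1 = sequence_similarity(a1, b2), s2 = sequence_similarity(a2, b1))
  if (sum(c2) > sum(c1)) structure(c2, combination = 2L)
  else structure(c1, combination = 1L)
}

#' 2D histogram of cross-dataset pair similarities
#'
#' For every pair (p, q) in `set1` x `set2`, bins the two components of
#' [pair_similarity()] into a `bins` x `bins` count matrix over \[0, 1\].
#' Used to audit train/test redundancy: low mutual similarity concentrates
#' all mass in the low-low corner.
#'
#' @param set1,set2 data.frames of pairs (idA, idB).
#' @param sequences named character vector resolving all ids.
#' @param bins number of bins per axis.
#' @return integer matrix with attribute `breaks`; counts sum to
#'   `nrow(set1) * nrow(set2)`.
#' @export
similarity_histogram <- function(set1, set2, sequences, bins = 20L) {
  if (!nrow(set1) || !nrow(set2)) stop("empty input pair set")
  check_pairs(set1, sequences)
  check_pairs(set2, sequences)
  breaks <- seq(0, 1, length.out = bins + 1L)
  H <- matrix(0L, bins, bins)
  for (i in seq_len(nrow(set1))) {
    for (j in seq_len(nrow(set2))) {
      s <- pair_similarity(sequences[[set1$idA[i]]], sequences[[set1$idB[i]]],
                           sequences[[set2$idA[j]]], sequences[[set2$idB[j]]])
      b1 <- min(bins, 1L + floor(s[[1L]] * bins))
      b2 <- min(bins, 1L + floor(s[[2L]] * bins))
      H[b1, b2] <- H[b1, b2] + 1L
    }
  }
  attr(H, "breaks") <- breaks
  H
}

# concatenated sequence of a pair in canonical within-pair order
concat_pair_seq <- function(pairs, sequences) {
  swap <- pairs$idB < pairs$idA
  first <- ifelse(swap, pairs$idB, pairs$idA)
  second <- ifelse(swap, pairs$idA, pairs$idB)
  paste0(unname(sequences[first]), unname(sequences[second]))
}

#' Redundancy filter on concatenated sequence pairs
#'
#' Greedy representative clustering in the style of CD-HIT, applied to the
#' concatenation of each pair's two sequences (canonical order:
#' lexicographically smaller id first, so (A,B) and (B,A) concatenate
#' identically). Pairs are visited by descending concatenated length (ties:
#' by id); a pair is kept only if its concatenated-sequence similarity to
#' every previously kept representative is at most `threshold`.
#'
#' @param pairs data.frame (idA, idB, optionally label).
#' @param sequences named character vector.
#' @param threshold identity threshold in (0, 1]; default 0.5 (at most 50%
#'   identity among kept pairs).
#' @param kmer_prefilter passed to [sequence_similarity()].
#' @return the kept subset of `pairs` (original row order preserved).
#' @export
redundancy_filter <- function(pairs, sequences, threshold = 0.5,
                              kmer_prefilter = FALSE) {
  stopifnot(threshold > 0, threshold <= 1)
  check_pairs(pairs, sequences)
  if (!nrow(pairs)) return(pairs)
  cat_seq <- concat_pair_seq(pairs, sequences)
  ord <- order(-nchar(cat_seq), pairs$idA, pairs$idB)
  kept_seq <- character(0)
  kept_idx <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (r in kept_seq) {
      if (sequence_similarity(cat_seq[i], r, kmer_prefilter) > threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      kept_seq <- c(kept_seq, cat_seq[i])
      kept_idx <- c(kept_idx, i)
    }
  }
  pairs[sort(kept_idx), , drop = FALSE]
}

#' Sample a redundancy-controlled negative set
#'
#' Draws candidate non-binder pairs in seeded random order and keeps each
#' one only if its concatenated sequence stays at or below the identity
#' threshold against every negative already accepted, until `n` (default:
#' the size of the positive set) are collected. Warns when the pool cannot
#' supply enough.
#'
#' @param positives data.frame of positive pairs (sets the target count).
#' @param candidates data.frame of candidate negative pairs.
#' @param sequences named character vector.
#' @param threshold identity threshold, as in [redundancy_filter()].
#' @param n number to sample; defaults to `nrow(positives)`.
#' @param seed integer seed (deterministic selection).
#' @param kmer_prefilter passed to [sequence_similarity()].
#' @return data.frame of sampled negatives with `label = 0`.
#' @export
sample_negatives <- function(positives, candidates, sequences,
                             threshold = 0.5, n = NULL, seed = 1L,
                             kmer_prefilter = FALSE) {
  if (!nrow(candidates)) stop("empty candidate pool")
  check_pairs(candidates, sequences)
  if (is.null(n)) n <- nrow(positives)
  # drop duplicate unordered pairs up front
  candidates <- candidates[!duplicated(pair_key(candidates$idA,
                                                candidates$idB)), ,
                           drop = FALSE]
  ord <- with_seed(seed, sample.int(nrow(candidates)))
  cat_seq <- concat_pair_seq(candidates, sequences)
  kept_seq <- character(0)
  kept_idx <- integer(0)
  for (i in ord) {
    if (length(kept_idx) >= n) break
    ok <- TRUE
    for (r in kept_seq) {
      if (sequence_similarity(cat_seq[i], r, kmer_prefilter) > threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      kept_seq <- c(kept_seq, cat_seq[i])
      kept_idx <- c(kept_idx, i)
    }
  }
  if (length(kept_idx) < n)
    warning("candidate pool exhausted: returning ", length(kept_idx),
            " of ", n, " requested negatives")
  out <- candidates[kept_idx, , drop = FALSE]
  out$label <- 0L
  rownames(out) <- NULL
  out
}

#' Label-stratified train/test split
#'
#' Deterministic under `seed`; the two outputs are disjoint under unordered
#' pair identity and their union is the input. The test set receives
#' `round(test_fraction * n)` pairs per label class.
#'
#' @param pairs data.frame with idA, idB, label.
#' @param test_fraction fraction in (0, 1).
#' @param seed integer seed.
#' @return list with elements `train` and `test`.
#' @export
split_train_test <- function(pairs, test_fraction, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1,
            "label" %in% names(pairs))
  counts <- table(factor(pairs$label, levels = c(0L, 1L)))
  if (any(counts < 2L))
    stop("need at least 2 pairs per class to split; got ",
         paste(counts, collapse = "/"))
  test_idx <- integer(0)
  with_seed(seed, {
    for (lab in c(0L, 1L)) {
      idx <- which(pairs$label == lab)
      k <- round(test_fraction * length(idx))
      k <- max(1L, min(length(idx) - 1L, k))
      test_idx <- c(test_idx, sample(idx, k))
    }
  })
  list(train = pairs[-sort(test_idx), , drop = FALSE],
       test = pairs[sort(test_idx), , drop = FALSE])
}

# evaluate expr under a private RNG state, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}
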