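# Sequence translation, autocorrelation descriptors, pair feature assembly
# and the reverse/inverse 4-way augmentation.

clean_seq <- function(seq) toupper(gsub("[[:space:]]", "", seq))

#' Reverse an amino-acid sequence
#'
#' Character-level reversal, e.g. `"ANLMK"` becomes `"KMLNA"`.
#' @param seq amino-acid string.
#' @export
reverse_seq <- function(seq) {
  vapply(seq, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""), "",
    USE.NAMES = FALSE)
}

#' Translate a sequence through a scale set
#'
#' Maps each residue to its value under every scale in the set, yielding an
#' n x p numeric matrix (residues x scales).
#'
#' @param seq amino-acid string (whitespace is stripped, case-insensitive).
#' @param scales a [scale_set()].
#' @param on_nonstandard what to do with residues outside the 20 standard
#'   codes: `"strict"` (default) errors naming the offending codes,
#'   `"drop"` removes them with a warning (mirrors discarding
#'   selenocysteine-containing records during curation).
#' @param id optional sequence identifier carried through.
#' @return object of class `translated_seq`: list with `id`, `n`, and the
#'   matrix `S`.
#' @export
translate <- function(seq, scales, on_nonstandard = c("strict", "drop"),
                      id = NULL) {
  on_nonstandard <- match.arg(on_nonstandard)
  stopifnot(inherits(scales, "scale_set"))
  s <- clean_seq(seq)
  if (!nzchar(s)) stop("empty sequence")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% AA_CODES)
  if (any(bad)) {
    if (on_nonstandard == "strict")
      stop("non-standard residue(s): ",
           paste(sort(unique(chars[bad])), collapse = ", "))
    warning("dropping ", sum(bad), " non-standard residue(s): ",
            paste(sort(unique(chars[bad])), collapse = ", "))
    chars <- chars[!bad]
    if (!length(chars)) stop("empty sequence after dropping residues")
  }
  S <- vapply(scales, function(sc) unname(sc$values[chars]),
              numeric(length(chars)))
  if (length(chars) == 1L) S <- matrix(S, nrow = 1L,
                                       dimnames = list(NULL, names(scales)))
  structure(list(id = id, n = length(chars), S = S),
            class = "translated_seq")
}

#' Autocorrelation descriptor of a translated sequence
#'
#' For every scale column j with full-column mean and population standard
#' deviation, computes at each lag `1..max_lag` the normalized lagged
#' product sum over the `n - lag` positions. Output is scale-major: the 30
#' lags of scale 1, then scale 2, etc. Conventions: entries with
#' `lag >= n` are 0; a zero-variance column yields 0 for all its lags.
#' Sequences shorter than 16 residues trigger a warning (the method was
#' tuned for length >= 16) but are computed.
#'
#' @param ts a `translated_seq` from [translate()].
#' @param max_lag maximum lag (default 30).
#' @return numeric vector of length `p * max_lag` with names
#'   `<scale>_lag<k>`.
#' @export
autocorrelation <- function(ts, max_lag = 30L) {
  stopifnot(inherits(ts, "translated_seq"), max_lag >= 1L)
  if (ts$n < 1L) stop("empty translated sequence")
  if (ts$n < 16L)
    warning("sequence length ", ts$n,
            " is below the advised minimum of 16; computing anyway")
  if (ts$n <= max_lag)
    warning("sequence length ", ts$n, " <= max_lag ", max_lag,
            "; missing lags are zero-filled")
  out <- ac_features_cpp(ts$S, as.integer(max_lag))
  names(out) <- paste0(rep(colnames(ts$S), each = max_lag), "_lag",
                       rep(seq_len(max_lag), times = ncol(ts$S)))
  out
}

#' Per-sequence feature vector
#'
#' Convenience wrapper: [translate()] then [autocorrelation()].
#' @inheritParams translate
#' @inheritParams autocorrelation
#' @export
seq_features <- function(seq, scales, max_lag = 30L,
                         on_nonstandard = c("strict", "drop")) {
  autocorrelation(translate(seq, scales, on_nonstandard), max_lag)
}

#' Ordered pair feature vector
#'
#' Concatenation of the two per-sequence descriptors, first sequence first:
#' 420 dimensions in the default configuration. The vector is ordered
#' (`pair_features(A, B)` differs from `pair_features(B, A)` by swapping
#' the halves); order-invariant scoring is obtained at prediction time by
#' averaging over the augmented representations.
#'
#' @param seqA,seqB amino-acid strings.
#' @inheritParams translate
#' @inheritParams autocorrelation
#' @export
pair_features <- function(seqA, seqB, scales, max_lag = 30L,
                          on_nonstandard = c("strict", "drop")) {
  c(seq_features(seqA, scales, max_lag, on_nonstandard),
    seq_features(seqB, scales, max_lag, on_nonstandard))
}

#' Reverse/inverse augmentation of a sequence pair
#'
#' Expands an ordered pair (A, B) into the four representations used at
#' training time: (A, B), (B, A), (A, B_inv), (B, A_inv), where X_inv is
#' the character-reversed sequence. All four inherit the pair's label.
#' Because the autocorrelation descriptor is invariant under sequence
#' reversal, (A, B_inv) is feature-identical to (A, B); the four
#' representations are nevertheless produced exactly as stated.
#'
#' @param seqA,seqB amino-acid strings.
#' @param label optional label attached to every representation.
#' @return list of 4 lists with elements `a`, `b` (and `label`).
#' @export
augment_pair <- function(seqA, seqB, label = NULL) {
  ai <- reverse_seq(seqA)
  bi <- reverse_seq(seqB)
  lapply(list(list(a = seqA, b = seqB),
              list(a = seqB, b = seqA),
              list(a = seqA, b = bi),
              list(a = seqB, b = ai)),
         function(p) { p$label <- label; p })
}

# Feature matrix for a pairs table. Per-sequence descriptors are cached by
# id (and "rev:" id for inverted representations) so the 4-way augmentation
# costs two extra descriptor evaluations per sequence, not per pair.
# Returns a matrix with 4 * nrow(pairs) rows when augment = TRUE (grouped by
# pair, representation-major) and an attribute "labels".
featurize_pairs <- function(pairs, sequences, scales, max_lag = 30L,
                            augment = FALSE,
                            on_nonstandard = "strict") {
  check_pairs(pairs, sequences)
  ids <- unique(c(pairs$idA, pairs$idB))
  feat <- new.env(parent = emptyenv())
  getf <- function(id, rev = FALSE) {
    key <- if (rev) paste0("rev:", id) else id
    f <- feat[[key]]
    if (is.null(f)) {
      s <- if (rev) reverse_seq(sequences[[id]]) else sequences[[id]]
      f <- seq_features(s, scales, max_lag, on_nonstandard)
      feat[[key]] <- f
    }
    f
  }
  d <- length(scales) * max_lag
  nrep <- if (augment) 4L else 1L
  X <- matrix(0, nrow(pairs) * nrep, 2L * d)
  labels <- numeric(nrow(pairs) * nrep)
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$idA[k]; b <- pairs$idB[k]
    fa <- getf(a); fb <- getf(b)
    row0 <- (k - 1L) * nrep
    X[row0 + 1L, ] <- c(fa, fb)
    if (augment) {
      X[row0 + 2L, ] <- c(fb, fa)
      X[row0 + 3L, ] <- c(fa, getf(b, rev = TRUE))
      X[row0 + 4L, ] <- c(fb, getf(a, rev = TRUE))
    }
    if (!is.null(pairs$label))
      labels[row0 + seq_len(nrep)] <- pairs$label[k]
  }
  colnames(X) <- c(paste0("A_", names(getf(pairs$idA[1L]))),
                   paste0("B_", names(getf(pairs$idA[1L]))))
  attr(X, "labels") <- if (is.null(pairs$label)) NULL else labels
  X
}
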