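# Random-forest PPI classifier on 420-dim pair features: 4-way
# reverse/inverse augmentation at training time, order-invariant soft-vote
# scoring at prediction time.

#' Random-forest configuration
#'
#' @param n_trees number of trees (default 750).
#' @param mtry features considered per split; default
#'   `floor(sqrt(420)) = 20`, the standard classification heuristic for the
#'   default 420-dim feature space.
#' @param seed integer seed driving bootstrap and feature sampling.
#' @param max_lag autocorrelation lags per scale (default 30).
#' @param min_node minimum node size before a split is attempted; 1 grows
#'   unpruned trees.
#' @export
rf_config <- function(n_trees = 750L, mtry = 20L, seed = 1L, max_lag = 30L,
                      min_node = 1L) {
  stopifnot(n_trees >= 1L, mtry >= 1L, max_lag >= 1L, min_node >= 1L)
  structure(list(n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 seed = as.integer(seed), max_lag = as.integer(max_lag),
                 min_node = as.integer(min_node)),
            class = "rf_config")
}

#' Train the random-forest interaction classifier
#'
#' Every training pair is expanded into its four reverse/inverse
#' representations (labels inherited), featurized into 420-dim
#' autocorrelation vectors and fed to a bagged forest of unpruned Gini
#' trees with `mtry` candidate features per split. Deterministic under the
#' config seed.
#'
#' @param pairs data.frame with idA, idB, label (both classes present).
#' @param sequences named character vector of sequences.
#' @param scales a [scale_set()]; default the bundled seven.
#' @param config an [rf_config()].
#' @return object of class `ppi_rf`.
#' @export
train_rf <- function(pairs, sequences, scales = load_default_scale_set(),
                     config = rf_config()) {
  stopifnot(inherits(config, "rf_config"), "label" %in% names(pairs))
  if (length(unique(pairs$label)) < 2L)
    stop("training data must contain both classes")
  X <- featurize_pairs(pairs, sequences, scales, config$max_lag,
                       augment = TRUE)
  y <- as.integer(attr(X, "labels"))
  forest <- rf_train_cpp(X, y, config$n_trees, min(config$mtry, ncol(X)),
                         config$seed, config$min_node)
  structure(list(
    forest = forest,
    config = config,
    meta = list(scale_names = names(scales), max_lag = config$max_lag,
                n_features = ncol(X), feature_order = "scale-major",
                fingerprint = dataset_fingerprint(pairs)),
    scales = scales,
    version = 1L,
    kind = "rf"
  ), class = c("ppi_rf", "ppi_model"))
}

dataset_fingerprint <- function(pairs) {
  key <- sort(pair_key(pairs$idA, pairs$idB))
  sum(utf8ToInt(paste(substr(key, 1L, 4L), collapse = "")) *
        seq_len(nchar(paste(substr(key, 1L, 4L), collapse = "")))) %% 1e9 +
    nrow(pairs)
}

#' @export
print.ppi_rf <- function(x, ...) {
  cat("<ppi_rf> random forest of", length(x$forest), "trees,",
      x$meta$n_features, "features (", length(x$meta$scale_names),
      "scales x", x$meta$max_lag, "lags x 2 )\n")
  invisible(x)
}

#' Score a sequence pair with a trained model
#'
#' The four augmented representations of (A, B) are scored and their
#' forest vote-fractions averaged, which makes the score exactly symmetric
#' under argument swap.
#'
#' @param model a trained `ppi_rf`.
#' @param seqA,seqB amino-acid strings.
#' @return score in \[0, 1\] (binding propensity).
#' @export
predict_pair <- function(model, seqA, seqB) {
  stopifnot(inherits(model, "ppi_rf"))
  reps <- augment_pair(seqA, seqB)
  X <- t(vapply(reps, function(p)
    pair_features(p$a, p$b, model$scales, model$meta$max_lag),
    numeric(model$meta$n_features)))
  mean(rf_predict_cpp(model$forest, X))
}

#' Score a table of pairs with a trained model
#'
#' Vectorized version of [predict_pair()] over a pairs data.frame; scores
#' average the four augmented representations per pair.
#'
#' @param model trained `ppi_rf`.
#' @param pairs data.frame (idA, idB).
#' @param sequences named character vector.
#' @return numeric vector of scores, one per row of `pairs`.
#' @export
predict_pairs <- function(model, pairs, sequences) {
  stopifnot(inherits(model, "ppi_rf"))
  X <- featurize_pairs(pairs, sequences, model$scales, model$meta$max_lag,
                       augment = TRUE)
  s <- rf_predict_cpp(model$forest, X)
  colMeans(matrix(s, nrow = 4L))
}

#' Save a trained model to disk
#'
#' Models are plain R lists (forest/parameter matrices plus feature
#' metadata) serialized with `saveRDS`; a round trip reproduces
#' predictions exactly.
#'
#' @param model a `ppi_rf`, `ppi_gnn` or `consensus_net`.
#' @param path destination file.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("ppi_model", "consensus_net")))
  saveRDS(model, path)
  invisible(path)
}

#' Load a model saved with [save_model()]
#'
#' Feature metadata stored in the model (scale order, max_lag, dimensions)
#' is validated against the requested configuration; a mismatch is an
#' explicit error rather than a silent misprediction.
#'
#' @param path file written by [save_model()].
#' @param max_lag if given, require the model to have been trained with
#'   this lag count.
#' @param scales if given, require matching scale names in order.
#' @export
load_model <- function(path, max_lag = NULL, scales = NULL) {
  if (!file.exists(path)) stop("model file not found: ", path)
  model <- tryCatch(readRDS(path),
                    error = function(e) stop("corrupted model file '", path,
                                             "': ", conditionMessage(e)))
  if (!inherits(model, c("ppi_model", "consensus_net")) ||
      is.null(model$version))
    stop("corrupted model file '", path, "': not a seqppi model")
  if (!is.null(model$meta)) {
    if (!is.null(max_lag) && model$meta$max_lag != max_lag)
      stop("model was trained with max_lag ", model$meta$max_lag,
           " but the session requires ", max_lag)
    if (!is.null(scales) &&
        !identical(names(scales), model$meta$scale_names))
      stop("model scale order (",
           paste(model$meta$scale_names, collapse = ", "),
           ") does not match the session's scale set")
    if (inherits(model, "ppi_rf") &&
        model$meta$n_features != 2L * length(model$meta$scale_names) *
          model$meta$max_lag)
      stop("corrupted model file '", path, "': inconsistent dimensions")
  }
  model
}
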