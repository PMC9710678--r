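# Amino-acid scales: construction, file I/O, normalization and the default
# seven-scale set.

DEFAULT_SCALE_NAMES <- c("hydrophobicity", "hydrophilicity", "volume",
                         "polarity", "polarizability", "sasa", "net_charge")

#' Create an amino-acid scale
#'
#' A scale maps each of the 20 standard one-letter amino-acid codes to a real
#' number encoding a physicochemical property (hydrophobicity, polarity,
#' ...).
#'
#' @param name short identifier.
#' @param values named numeric vector over exactly the 20 standard codes.
#' @param source_ref free-text citation for the table's provenance.
#' @return object of class `aa_scale`.
#' @export
aa_scale <- function(name, values, source_ref = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.null(names(values)))
    stop("scale values must be named by amino-acid code")
  missing <- setdiff(AA_CODES, names(values))
  if (length(missing))
    stop("scale '", name, "' is missing amino acid(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(values), AA_CODES)
  if (length(extra))
    stop("scale '", name, "' has non-standard code(s): ",
         paste(extra, collapse = ", "))
  values <- as.numeric(values[AA_CODES])
  names(values) <- AA_CODES
  if (!all(is.finite(values)))
    stop("scale '", name, "' contains non-finite values")
  if (max(values) == min(values))
    stop("degenerate scale: all 20 values identical in '", name, "'")
  structure(list(name = name, values = values, source_ref = source_ref,
                 normalized = FALSE),
            class = "aa_scale")
}

#' @export
print.aa_scale <- function(x, ...) {
  cat("<aa_scale>", x$name,
      if (isTRUE(x$normalized)) "(normalized)" else "(raw)", "\n")
  print(round(x$values, 4))
  invisible(x)
}

#' Normalize a scale to mean 0 and population s.d. 1
#'
#' The 20 values are centered by their mean and divided by their population
#' standard deviation (divisor 20, not 19). Normalizing an already
#' normalized scale is a no-op up to floating-point tolerance, and the
#' result is invariant under positive affine transformations of the raw
#' values.
#'
#' @param scale an [aa_scale()].
#' @return normalized `aa_scale`.
#' @export
normalize_scale <- function(scale) {
  stopifnot(inherits(scale, "aa_scale"))
  v <- scale$values
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))  # population form
  if (sigma == 0) stop("degenerate scale: zero variance in '", scale$name, "'")
  out <- scale
  out$values <- (v - mu) / sigma
  out$normalized <- TRUE
  out
}

#' Read a scale table file
#'
#' Two whitespace-separated columns (one-letter code, value); `#` lines are
#' comments carrying provenance.
#'
#' @param path file path.
#' @param name scale name; defaults to the file name without extension.
#' @return raw (unnormalized) `aa_scale`.
#' @export
read_scale_file <- function(path, name = NULL) {
  if (!file.exists(path)) stop("scale table file not found: ", path)
  tab <- tryCatch(
    read.table(path, header = FALSE, comment.char = "#",
               col.names = c("aa", "value"),
               colClasses = c("character", "numeric")),
    error = function(e) stop("corrupted scale table '", path, "': ",
                             conditionMessage(e)))
  if (nrow(tab) != 20L)
    stop("corrupted scale table '", path, "': expected 20 rows, got ",
         nrow(tab))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  cmt <- grep("^#", readLines(path, warn = FALSE), value = TRUE)
  aa_scale(name, stats::setNames(tab$value, tab$aa),
           source_ref = paste(sub("^#\\s?", "", cmt), collapse = " "))
}

#' Bundle normalized scales into an ordered scale set
#'
#' @param scales list of `aa_scale` objects (normalized on the fly if raw).
#' @return object of class `scale_set` (an ordered list).
#' @export
scale_set <- function(scales) {
  if (inherits(scales, "aa_scale")) scales <- list(scales)
  stopifnot(length(scales) >= 1L,
            all(vapply(scales, inherits, TRUE, "aa_scale")))
  scales <- lapply(scales, function(s)
    if (isTRUE(s$normalized)) s else normalize_scale(s))
  names(scales) <- vapply(scales, `[[`, "", "name")
  if (anyDuplicated(names(scales))) stop("duplicate scale names in set")
  structure(scales, class = "scale_set")
}

#' @export
print.scale_set <- function(x, ...) {
  cat("<scale_set> of", length(x), "normalized scale(s):",
      paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.scale_set` <- function(x, i) {
  out <- unclass(x)[i]
  if (any(vapply(out, is.null, TRUE)))
    stop("unknown scale name(s): ",
         paste(i[!(i %in% names(x))], collapse = ", "))
  structure(out, class = "scale_set")
}

#' Load the default seven-scale set
#'
#' Returns the seven bundled physicochemical scales, normalized, in the
#' fixed documented order: hydrophobicity, hydrophilicity, side-chain
#' volume, polarity, polarizability, solvent-accessible surface area, net
#' charge index. Tables live under `inst/extdata/scales/` and can be
#' replaced by user-supplied files of the same format.
#'
#' @param names optional character vector selecting a subset (in the given
#'   order). Unknown names are an error.
#' @param dir directory containing the scale tables; defaults to the
#'   bundled ones.
#' @return a [scale_set()].
#' @export
load_default_scale_set <- function(names = NULL, dir = NULL) {
  if (is.null(dir))
    dir <- system.file("extdata", "scales", package = "seqppi")
  wanted <- if (is.null(names)) DEFAULT_SCALE_NAMES else names
  unknown <- setdiff(wanted, DEFAULT_SCALE_NAMES)
  if (is.null(names)) {
    # default configuration must be the full set of 7
  } else if (length(unknown)) {
    stop("unknown scale name(s): ", paste(unknown, collapse = ", "))
  }
  paths <- file.path(dir, paste0(wanted, ".tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing bundled scale table(s): ", paste(missing, collapse = ", "))
  scale_set(lapply(paths, read_scale_file))
}

# p x 20 profile matrix (scales x residues) for the GNN / translation
scale_profile_matrix <- function(scales) {
  stopifnot(inherits(scales, "scale_set"))
  t(vapply(scales, function(s) s$values[AA_CODES], numeric(20L)))
}
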