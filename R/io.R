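# FASTA and pair-list I/O. FASTA is delegated to Biostrings; the pair list
# is a 3-column TSV (idA, idB, label in {1,0}) with '#' comment lines.

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of amino-acid sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- tryCatch(Biostrings::readAAStringSet(path),
                error = function(e) stop("unreadable FASTA '", path, "': ",
                                         conditionMessage(e)))
  if (length(x) == 0L) stop("empty FASTA: ", path)
  out <- as.character(x)
  # keep only the first whitespace-delimited token of each header
  names(out) <- sub("\\s.*$", "", names(out))
  if (anyDuplicated(names(out)))
    stop("duplicate sequence ids in FASTA: ", path)
  out
}

#' Write sequences to a single-line FASTA file
#'
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(length(sequences) >= 1L, !is.null(names(sequences)))
  x <- Biostrings::AAStringSet(sequences)
  ok <- tryCatch({
    Biostrings::writeXStringSet(x, path, width = 200000L)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write FASTA to: ", path)
  invisible(path)
}

#' Read a labelled pair list
#'
#' Tab-separated columns `idA`, `idB`, `label` (1 = binder, 0 = non-binder);
#' lines starting with `#` are ignored. A two-column file is accepted for
#' unlabelled prediction input.
#'
#' @param path TSV file.
#' @return data.frame with columns idA, idB (and label if present).
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop("pair list not found: ", path)
  tab <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                    colClasses = "character")
  if (ncol(tab) < 2L) stop("pair list must have at least 2 columns: ", path)
  out <- data.frame(idA = tab[[1L]], idB = tab[[2L]],
                    stringsAsFactors = FALSE)
  if (ncol(tab) >= 3L) {
    lab <- suppressWarnings(as.integer(tab[[3L]]))
    if (anyNA(lab) || !all(lab %in% c(0L, 1L)))
      stop("labels must be 0 or 1 in: ", path)
    out$label <- lab
  }
  out
}

#' Write a labelled pair list
#'
#' @param pairs data.frame with idA, idB and optionally label.
#' @param path output TSV.
#' @export
write_pairs <- function(pairs, path) {
  cols <- intersect(c("idA", "idB", "label"), names(pairs))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(cols, collapse = "\t")), con)
  write.table(pairs[cols], con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
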