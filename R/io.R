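# Readers and writers: FASTA / plain-line string collections and TSV
# distance matrices.

#' Read a string collection
#'
#' @param path Input file.
#' @param format `"auto"` (detect FASTA by a leading `>`), `"fasta"` or
#'   `"lines"` (one sequence per line, ids are line numbers).
#' @param allow_missing_symbol Accept sequences containing the reserved
#'   `#` symbol (e.g. partial-sanitization output).  Off by default:
#'   sanitization inputs must be over the original alphabet.
#' @return A tibble with character columns `id` and `sequence`.
#' @export
read_strings <- function(path, format = c("auto", "fasta", "lines"),
                         allow_missing_symbol = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (length(first) && startsWith(first, ">")) "fasta" else "lines"
  }
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) {
                      ss_abort("parse", "cannot parse FASTA file '%s': %s",
                               path, conditionMessage(e))
                    })
    out <- tibble::tibble(id = names(set),
                          sequence = unname(as.character(set)))
  } else {
    lines <- readLines(path, warn = FALSE)
    out <- tibble::tibble(id = as.character(seq_along(lines)), sequence = lines)
  }
  if (anyDuplicated(out$id)) {
    ss_abort("duplicate_id", "duplicate record id(s) in '%s'", path)
  }
  if (!allow_missing_symbol &&
      any(grepl(MISSING_SYMBOL, out$sequence, fixed = TRUE))) {
    ss_abort("parse",
             "sequence contains the reserved symbol '%s' (set allow_missing_symbol = TRUE for partial-sanitization output)",
             MISSING_SYMBOL)
  }
  out
}

#' Write a string collection
#'
#' @param data Tibble with `id` and `sequence` (or a character vector).
#' @param path Output file.
#' @param format `"auto"` (FASTA for `.fa`/`.fasta`/`.fna`, otherwise
#'   lines), `"fasta"` or `"lines"`.
#' @return `path`, invisibly.
#' @export
write_strings <- function(data, path, format = c("auto", "fasta", "lines")) {
  format <- match.arg(format)
  if (is.character(data)) {
    data <- tibble::tibble(id = as.character(seq_along(data)), sequence = data)
  }
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE))
      "fasta" else "lines"
  }
  if (format == "fasta") {
    set <- Biostrings::BStringSet(stats::setNames(data$sequence, data$id))
    Biostrings::writeXStringSet(set, path)
  } else {
    writeLines(data$sequence, path)
  }
  invisible(path)
}

#' Write / read a distance matrix as TSV
#'
#' The TSV has a header row of ids and a square numeric block; integer
#' LIS k-gram distances round-trip losslessly.  `read_distance_matrix()`
#' rejects non-square, non-symmetric or nonzero-diagonal input.
#'
#' @param D Symmetric matrix (e.g. from [lk_dist_matrix()]).
#' @param path File path.
#' @return `write_distance_matrix()` returns `path` invisibly;
#'   `read_distance_matrix()` returns the matrix with dimnames.
#' @export
write_distance_matrix <- function(D, path) {
  utils::write.table(D, path, sep = "\t", quote = FALSE, row.names = TRUE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  D <- as.matrix(df)
  storage.mode(D) <- "double"
  if (nrow(D) != ncol(D) || !identical(rownames(D), colnames(D))) {
    ss_abort("shape_mismatch", "'%s' is not a square labelled matrix", path)
  }
  if (!isTRUE(all.equal(D, t(D))) || any(diag(D) != 0)) {
    ss_abort("shape_mismatch",
             "'%s' is not a symmetric matrix with zero diagonal", path)
  }
  D
}
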