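# Alphabets and antidictionaries (sets of forbidden patterns).

MISSING_SYMBOL <- "#"

ss_abort <- function(class, msg, ...) {
  rlang::abort(sprintf(msg, ...), class = paste0("stringsan_error_", class))
}

#' Construct an alphabet
#'
#' An alphabet is an ordered set of distinct single-character symbols.  The
#' rank of a symbol is its position (1-based) in the alphabet; ranks drive
#' the deterministic tie-breaking used throughout the package
#' (lexicographically smallest outputs are smallest with respect to rank
#' order).  The symbol `"#"` is reserved for missing values / partial
#' sanitization and can never be a member.
#'
#' @param letters Character vector of distinct single characters, or a single
#'   string whose characters are taken in order.
#' @return An object of class `ss_alphabet`: the character vector of letters
#'   in rank order.
#' @examples
#' alphabet("acgt")
#' alphabet(c("a", "b"))
#' @export
alphabet <- function(letters) {
  if (length(letters) == 1L && nchar(letters) > 1L) {
    letters <- strsplit(letters, "", fixed = TRUE)[[1]]
  }
  letters <- as.character(letters)
  if (length(letters) == 0L) {
    ss_abort("alphabet_violation", "an alphabet needs at least one letter")
  }
  if (any(nchar(letters) != 1L)) {
    ss_abort("alphabet_violation", "alphabet members must be single characters")
  }
  if (anyDuplicated(letters)) {
    ss_abort("alphabet_violation", "alphabet letters must be distinct")
  }
  if (MISSING_SYMBOL %in% letters) {
    ss_abort("alphabet_violation",
             "'%s' is the reserved missing-value symbol and cannot be an alphabet letter",
             MISSING_SYMBOL)
  }
  structure(letters, class = "ss_alphabet")
}

#' @export
print.ss_alphabet <- function(x, ...) {
  cat("<alphabet> {", paste(unclass(x), collapse = ", "), "}\n")
  invisible(x)
}

# Coerce: NULL -> alphabet inferred from the strings supplied; character vector
# or single string -> alphabet().
as_alphabet <- function(x, infer_from = NULL) {
  if (inherits(x, "ss_alphabet")) return(x)
  if (is.null(x)) {
    chars <- sort(unique(unlist(strsplit(infer_from, "", fixed = TRUE))))
    chars <- setdiff(chars, MISSING_SYMBOL)
    if (length(chars) == 0L) chars <- "a"  # degenerate: all-empty inputs
    return(alphabet(chars))
  }
  alphabet(x)
}

check_over_alphabet <- function(s, ab, what = "string",
                                error_class = "alphabet_violation") {
  chars <- unique(unlist(strsplit(s, "", fixed = TRUE)))
  bad <- setdiff(chars, unclass(ab))
  if (length(bad)) {
    ss_abort(error_class, "%s contains letters outside the alphabet: %s",
             what, paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Normalize a set of forbidden patterns
#'
#' Builds an antidictionary: duplicates are removed, and any pattern that
#' contains another pattern as a proper substring is dropped (it can never be
#' avoided without also avoiding the contained pattern, so it is redundant).
#' The result is *anti-factorial*: no element is a proper substring of
#' another.
#'
#' @param patterns Character vector of nonempty forbidden strings.
#' @param alphabet Optional [alphabet()]; inferred from the patterns when
#'   `NULL`.
#' @return A `pattern_set`: the retained patterns (in first-appearance
#'   order), with attributes `alphabet`, `total_length` (sum of pattern
#'   lengths after normalization) and `uniform_k` (the common pattern length,
#'   or `NA` if lengths differ; an empty set has `uniform_k = NA`).
#' @examples
#' pattern_set(c("ab", "aab"))            # "aab" contains "ab": dropped
#' pattern_set(c("bbbb", "abba", "aaba")) # already anti-factorial
#' @export
pattern_set <- function(patterns, alphabet = NULL) {
  patterns <- as.character(patterns)
  if (any(!nzchar(patterns))) {
    ss_abort("empty_pattern", "forbidden patterns must be nonempty")
  }
  if (any(grepl(MISSING_SYMBOL, patterns, fixed = TRUE))) {
    ss_abort("alphabet_violation",
             "forbidden patterns must not contain the reserved symbol '%s'",
             MISSING_SYMBOL)
  }
  ab <- as_alphabet(alphabet, infer_from = patterns)
  if (length(patterns)) check_over_alphabet(patterns, ab, "a pattern")
  patterns <- unique(patterns)
  # distinct equal-length strings cannot contain one another, so the
  # containment scan is only needed when lengths differ
  if (length(patterns) > 1L && length(unique(nchar(patterns))) > 1L) {
    contains_other <- vapply(seq_along(patterns), function(i) {
      any(vapply(patterns[-i], grepl, logical(1), x = patterns[i], fixed = TRUE))
    }, logical(1))
    patterns <- patterns[!contains_other]
  }
  lens <- nchar(patterns)
  structure(patterns,
            class = "pattern_set",
            alphabet = ab,
            total_length = sum(lens),
            uniform_k = if (length(lens) && length(unique(lens)) == 1L)
              lens[1] else NA_integer_)
}

as_pattern_set <- function(x, alphabet = NULL) {
  if (inherits(x, "pattern_set")) {
    if (is.null(alphabet)) return(x)
    # re-validate against the wider alphabet so contexts and patterns agree
    return(pattern_set(as.character(x), alphabet))
  }
  pattern_set(x, alphabet)
}

#' @export
print.pattern_set <- function(x, ...) {
  k <- attr(x, "uniform_k")
  cat(sprintf("<pattern_set> %d pattern(s), total length %d%s\n",
              length(x), attr(x, "total_length"),
              if (!is.na(k)) sprintf(", uniform length k = %d", k) else ""))
  if (length(x)) cat(" ", paste(unclass(x), collapse = " "), "\n")
  invisible(x)
}

#' Read forbidden patterns from a file
#'
#' One pattern per line; lines starting with `>` are treated as comments and
#' ignored.  Blank lines are rejected.
#'
#' @inheritParams pattern_set
#' @param path Path to a UTF-8 text file.
#' @return A [pattern_set()].
#' @export
read_patterns <- function(path, alphabet = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, ">")]
  if (any(!nzchar(lines))) {
    ss_abort("parse", "blank line in pattern file '%s'", path)
  }
  pattern_set(lines, alphabet)
}
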