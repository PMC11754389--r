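# Full and partial sanitization of a private string against an
# antidictionary of fixed-length forbidden patterns.

check_k_patterns <- function(k, S) {
  if (!is.numeric(k) || length(k) != 1L || k != as.integer(k) || k <= 1L) {
    ss_abort("bad_k", "k must be a single integer > 1")
  }
  uk <- attr(S, "uniform_k")
  if (length(S) && (is.na(uk) || uk != k)) {
    ss_abort("bad_k", "all forbidden patterns must have length exactly k = %d", k)
  }
  invisible(as.integer(k))
}

partial_string <- function(segments, k) {
  d <- max(0L, length(segments) - 1L)
  structure(list(segments = segments, d = d,
                 text = paste(segments, collapse = MISSING_SYMBOL), k = k),
            class = "partial_string")
}

#' @export
print.partial_string <- function(x, ...) {
  cat(sprintf("<partial_string> \"%s\" (d = %d gap(s), k = %d)\n",
              x$text, x$d, x$k))
  invisible(x)
}

#' Shortest partial sanitization (total-order, frequency-preserving)
#'
#' Computes the unique shortest string `x` over the alphabet extended with
#' the missing-value symbol `#` whose sequence of non-forbidden k-grams
#' equals that of `w` exactly.  The construction scans the non-forbidden
#' k-grams of `w` in order and either *extends* the current segment by one
#' letter (when the segment already ends with the gram's (k-1)-prefix, i.e.
#' consecutive kept grams overlap) or *restarts* a new segment preceded by
#' `#`.  Every segment has length at least `k`, no forbidden pattern occurs
#' in any segment, and the number of `#`s is at most the number of
#' forbidden-pattern occurrences in `w`.
#'
#' @param w Input string.
#' @param k Pattern length (> 1).
#' @param patterns Forbidden patterns, all of length exactly `k`.
#' @param alphabet Optional [alphabet()].
#' @return A `partial_string`: list with `segments`, `d` (number of `#`s),
#'   `text` (`x0#x1#...#xd`) and `k`.  When `w` is shorter than `k` its
#'   k-gram sequence is empty and the empty partial string is returned,
#'   with a warning.
#' @examples
#' tfs("abbbbaaabaa", 4, c("bbbb", "aaba", "abba"))$text  # "abbbaaab#abaa"
#' @export
tfs <- function(w, k, patterns, alphabet = NULL) {
  ab <- as_alphabet(alphabet, infer_from = c(w, as.character(patterns)))
  S <- as_pattern_set(patterns, ab)
  k <- check_k_patterns(k, S)
  check_over_alphabet(w, ab, "the input string")
  if (nchar(w) < k) {
    warning("input shorter than k: its k-gram sequence is empty, returning the empty string")
    return(partial_string(character(0), k))
  }
  grams <- kgrams(w, k)
  kept <- grams[!grams %in% as.character(S)]
  t <- length(kept)
  if (t == 0L) return(partial_string(character(0), k))
  chain <- c(FALSE, substr(kept[-1L], 1L, k - 1L) == substring(kept[-t], 2L, k))
  starts <- which(!chain)
  ends <- c(starts[-1L] - 1L, t)
  segments <- vapply(seq_along(starts), function(j) {
    idx <- seq(starts[j], ends[j])
    paste0(kept[idx[1L]],
           paste(substr(kept[idx[-1L]], k, k), collapse = ""))
  }, character(1))
  partial_string(segments, k)
}

#' Shortest fully-sanitized string
#'
#' Produces a shortest string `y` over the original alphabet such that no
#' forbidden pattern occurs in `y` and the non-forbidden k-gram sequence of
#' `w` is a subsequence of that of `y`.  The algorithm first computes the
#' unique shortest partial sanitization ([tfs()]); each of its `d` gaps is
#' then an independent missing-value replacement instance whose left context
#' is the (k-1)-suffix of the segment before the gap and whose right context
#' is the (k-1)-prefix of the segment after it, solved optimally by
#' [solve_mvrs()] on the shared avoidance automaton; the `d` solutions are
#' spliced back in place of the `#`s.
#'
#' @inheritParams tfs
#' @param gap_patterns Optional list of `d` pattern sets, one per gap, to use
#'   a different antidictionary for each replacement (the main `patterns`
#'   still drive the partial sanitization).
#' @param automaton Optional prebuilt [prefix_automaton()] for `patterns`.
#' @return The sanitized string.  If some gap admits no replacement, returns
#'   `NA` with attributes `failed_gap` (its index) and `reason`.
#' @examples
#' sfss("abbbbaaabaa", 4, c("bbbb", "aaba", "abba"))  # "abbbaaabbbabaa"
#' @export
sfss <- function(w, k, patterns, alphabet = NULL, gap_patterns = NULL,
                 automaton = NULL) {
  ab <- as_alphabet(alphabet, infer_from = c(w, as.character(patterns)))
  S <- as_pattern_set(patterns, ab)
  x <- tfs(w, k, S, ab)
  if (x$d == 0L) return(x$text)
  if (!is.null(gap_patterns) && length(gap_patterns) != x$d) {
    ss_abort("bad_k", "gap_patterns must have one pattern set per gap (d = %d)", x$d)
  }
  A <- if (is.null(gap_patterns)) {
    if (is.null(automaton)) prefix_automaton(S, ab) else automaton
  } else NULL
  out <- x$segments[1L]
  for (i in seq_len(x$d)) {
    seg_next <- x$segments[i + 1L]
    u <- substring(out, nchar(out) - k + 2L)
    v <- substr(seg_next, 1L, k - 1L)
    res <- if (is.null(gap_patterns)) {
      solve_mvrs(u, v, S, automaton = A)
    } else {
      solve_mvrs(u, v, as_pattern_set(gap_patterns[[i]], ab), alphabet = ab)
    }
    if (res$status != "SOLVED") {
      return(structure(NA_character_, failed_gap = i, reason = res$reason))
    }
    out <- paste0(substr(out, 1L, nchar(out) - k + 1L), res$x,
                  substring(seg_next, k))
  }
  out
}

#' Greedy fully-sanitized string (deletion baseline)
#'
#' Scans `w` left to right, appending each letter to the output unless the
#' resulting length-k suffix would be a forbidden pattern, in which case the
#' letter is dropped.  The output is always fully sanitized and never longer
#' than `w`, but deleting a letter can create a new occurrence of a
#' forbidden pattern out of the surrounding letters, forcing cascades of
#' further deletions; the k-gram sequence of `w` is therefore not guaranteed
#' to survive as a subsequence, unlike with [sfss()].
#'
#' @inheritParams tfs
#' @return The sanitized string.
#' @examples
#' gfss("CAAAAAC", 3, "AAA", alphabet("AC"))  # "CAAC"
#' @export
gfss <- function(w, k, patterns, alphabet = NULL) {
  ab <- as_alphabet(alphabet, infer_from = c(w, as.character(patterns)))
  S <- as_pattern_set(patterns, ab)
  k <- check_k_patterns(k, S)
  check_over_alphabet(w, ab, "the input string")
  chars <- strsplit(w, "", fixed = TRUE)[[1]]
  pats <- as.character(S)
  y <- character(length(chars))
  m <- 0L
  for (ch in chars) {
    if (m >= k - 1L) {
      cand <- paste(c(y[(m - k + 2L):m], ch), collapse = "")
      if (cand %in% pats) next
    }
    m <- m + 1L
    y[m] <- ch
  }
  paste(y[seq_len(m)], collapse = "")
}

#' Verify full sanitization
#'
#' Checks that no forbidden pattern occurs in `y` and that `y` contains no
#' occurrence of the missing-value symbol `#`.
#'
#' @param y String to check.
#' @param patterns Forbidden patterns.
#' @return A list with `ok` (logical) and `violations`, a tibble with
#'   columns `pattern` and `position` (1-based start) listing every
#'   offending occurrence (`#` occurrences are listed under pattern `"#"`).
#' @export
verify_sanitized <- function(y, patterns) {
  pats <- c(as.character(patterns), MISSING_SYMBOL)
  hits <- lapply(pats, function(p) {
    pos <- gregexpr(p, y, fixed = TRUE)[[1]]
    pos[pos > 0L]
  })
  nhit <- lengths(hits)
  violations <- tibble::tibble(
    pattern = rep(pats, nhit),
    position = as.integer(unlist(hits))
  )
  violations <- dplyr::arrange(violations, .data$position, .data$pattern)
  list(ok = nrow(violations) == 0L, violations = violations)
}

#' Sanitize a collection of strings
#'
#' Applies [sfss()], [gfss()] or [tfs()] to every sequence in a collection,
#' sharing one avoidance automaton across all of them.
#'
#' @param data A tibble/data frame with columns `id` and `sequence`, or a
#'   character vector of sequences.
#' @param k Pattern length (> 1).
#' @param patterns Forbidden patterns, all of length `k`.
#' @param method `"sfss"` (optimal full sanitization), `"gfss"` (greedy
#'   deletion baseline) or `"tfs"` (partial sanitization; output may contain
#'   `#`).
#' @param alphabet Optional [alphabet()].
#' @return The input tibble with columns `sanitized` (character; `NA` on
#'   FAIL) and `status` (`"ok"` or `"fail"`) appended.
#' @export
sanitize_strings <- function(data, k, patterns,
                             method = c("sfss", "gfss", "tfs"),
                             alphabet = NULL) {
  method <- match.arg(method)
  if (is.character(data)) {
    data <- tibble::tibble(id = as.character(seq_along(data)), sequence = data)
  }
  stopifnot(is.data.frame(data), "sequence" %in% names(data))
  seqs <- data$sequence
  ab <- as_alphabet(alphabet, infer_from = c(seqs, as.character(patterns)))
  S <- as_pattern_set(patterns, ab)
  check_k_patterns(k, S)
  A <- prefix_automaton(S, ab)
  out <- vapply(seqs, function(w) {
    switch(method,
           sfss = as.character(sfss(w, k, S, ab, automaton = A)),
           gfss = gfss(w, k, S, ab),
           tfs = tfs(w, k, S, ab)$text)
  }, character(1), USE.NAMES = FALSE)
  dplyr::mutate(tibble::as_tibble(data), sanitized = out,
                status = ifelse(is.na(out), "fail", "ok"))
}
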