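# Occurrence-list / longest-increasing-subsequence k-gram distance.

#' k-gram sequence of a string
#'
#' All length-`k` substrings of `x` in left-to-right order of their start
#' positions; optionally with forbidden patterns removed, giving the
#' non-forbidden k-gram sequence used as the utility constraint in
#' sanitization.
#'
#' @param x String.
#' @param k Window length (>= 1).
#' @param drop_patterns Optional patterns to filter out of the sequence.
#' @return Character vector of length `max(0, nchar(x) - k + 1)` (before
#'   filtering).
#' @examples
#' kgrams("abbbbaaabaa", 4)
#' @export
kgrams <- function(x, k, drop_patterns = NULL) {
  stopifnot(k >= 1)
  n <- nchar(x)
  if (n < k) return(character(0))
  g <- substring(x, 1:(n - k + 1L), k:n)
  if (!is.null(drop_patterns)) g <- g[!g %in% as.character(drop_patterns)]
  g
}

#' Concatenated occurrence lists of x's k-grams in y
#'
#' For each k-gram of `x` in order, the 1-based start positions of all its
#' occurrences in `y` (ascending); the per-gram lists are concatenated in
#' gram order, grams absent from `y` contributing nothing.  The longest
#' strictly increasing subsequence of this sequence measures how much of
#' `x`'s k-gram structure embeds into `y` in order.
#'
#' @param x,y Strings.
#' @param k Window length.
#' @return Integer vector of positions in `[1, nchar(y) - k + 1]`.
#' @examples
#' occ_positions("abbbbaaabaa", "abbbaaabbbabaa", 4)  # 1 7 2 8 3 4 5 11
#' @export
occ_positions <- function(x, y, k) {
  gx <- kgrams(x, k)
  gy <- kgrams(y, k)
  if (length(gx) == 0L || length(gy) == 0L) return(integer(0))
  by_gram <- split(seq_along(gy), gy)
  as.integer(unlist(by_gram[gx], use.names = FALSE))
}

#' Length of a longest strictly increasing subsequence
#'
#' Patience-sorting algorithm: one pass, maintaining for each subsequence
#' length the smallest possible tail value; each element replaces the first
#' tail that is `>=` it (strict increase), so runtime is O(h log h) for a
#' length-h sequence.
#'
#' @param v Numeric/integer sequence.
#' @return Integer LIS length (`0` for an empty sequence).
#' @examples
#' lis_length(c(1, 7, 2, 8, 3, 4, 5, 11))  # 6
#' @export
lis_length <- function(v) {
  tails <- numeric(0)
  for (e in v) {
    j <- findInterval(e - 0.5, tails) + 1L
    tails[j] <- e
  }
  length(tails)
}

#' Directed LIS similarity of k-gram occurrence lists
#'
#' `lis_k(x, y, k)` is the length of a longest strictly increasing
#' subsequence of [occ_positions()]`(x, y, k)`.  It is asymmetric in
#' general: repeated grams in `y` can match one gram of `x` many times in
#' one direction only.  `lis_k(x, x, k) = nchar(x) - k + 1`.
#'
#' @inheritParams occ_positions
#' @return Integer similarity.
#' @examples
#' lis_k("ab", "ababababab", 2)  # 5
#' lis_k("ababababab", "ab", 2)  # 1
#' @export
lis_k <- function(x, y, k) {
  lis_length(occ_positions(x, y, k))
}

#' LIS-based k-gram distance between two strings
#'
#' The distance is
#' `nchar(x) + nchar(y) - 2*(k - 1) - lis_k(x, y, k) - lis_k(y, x, k)`,
#' i.e. the total number of k-grams of both strings minus the two directed
#' LIS similarities.  It is symmetric, non-negative and zero on identical
#' strings, but is neither a metric (the triangle inequality can fail) nor
#' a semimetric (it can be zero for distinct strings).
#'
#' @inheritParams occ_positions
#' @return Integer distance.
#' @examples
#' lk_dist("aaabaaab", "abaaaaaa", 4)  # 6
#' lk_dist("aaa", "aaaaaaa", 3)        # 0 (distinct strings, distance zero)
#' @export
lk_dist <- function(x, y, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > min(nchar(x), nchar(y))) {
    ss_abort("bad_k", "k must satisfy 1 <= k <= min(nchar(x), nchar(y))")
  }
  k <- as.integer(k)
  nchar(x) + nchar(y) - 2L * (k - 1L) - lis_k(x, y, k) - lis_k(y, x, k)
}

#' Pairwise LIS k-gram distance matrix
#'
#' @param data A tibble/data frame with columns `id` and `sequence`, or a
#'   character vector of sequences (ids default to their indices).
#' @param k Window length; every sequence must have length at least `k`.
#' @return A symmetric `n x n` numeric matrix with zero diagonal and the
#'   sequence ids as dimnames.
#' @export
lk_dist_matrix <- function(data, k) {
  if (is.data.frame(data)) {
    ids <- as.character(data$id)
    seqs <- data$sequence
  } else {
    seqs <- as.character(data)
    ids <- as.character(seq_along(seqs))
  }
  n <- length(seqs)
  short <- which(nchar(seqs) < k)
  if (length(short)) {
    ss_abort("bad_k", "sequence(s) shorter than k = %d at index: %s",
             k, paste(short, collapse = ", "))
  }
  grams <- lapply(seqs, kgrams, k = k)
  occ_maps <- lapply(grams, function(g) split(seq_along(g), g))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  lens <- nchar(seqs)
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      fwd <- lis_length(unlist(occ_maps[[j]][grams[[i]]], use.names = FALSE))
      bwd <- lis_length(unlist(occ_maps[[i]][grams[[j]]], use.names = FALSE))
      D[i, j] <- D[j, i] <- lens[i] + lens[j] - 2 * (k - 1) - fwd - bwd
    }
  }
  D
}
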