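# Synthetic string collections with planted cluster structure, and random
# antidictionaries.

#' Apply random edit operations to a string
#'
#' Performs `e` edit operations in sequence.  Each operation's type
#' (substitution, insertion, deletion) is chosen uniformly; the position is
#' uniform over valid positions; inserted letters are uniform over the
#' alphabet and substituted letters are uniform over the alphabet excluding
#' the current letter.  The result is at edit distance at most `e` from the
#' input (later operations can cancel earlier ones, so the distance may be
#' smaller).
#'
#' @param x Input string.
#' @param e Number of edit operations (>= 0).
#' @param alphabet An [alphabet()] (or letters) to draw from.
#' @param seed Optional integer seed for reproducibility.
#' @return The edited string.
#' @export
random_edits <- function(x, e, alphabet, seed = NULL) {
  stopifnot(e >= 0)
  ab <- as_alphabet(alphabet, infer_from = x)
  letters <- unclass(ab)
  with_seed(seed, {
    chars <- strsplit(x, "", fixed = TRUE)[[1]]
    for (i in seq_len(e)) {
      op <- sample(c("sub", "ins", "del"), 1L)
      if (length(chars) == 0L && op != "ins") {
        ss_abort("empty_string", "deletions exhausted the string")
      }
      if (op == "sub") {
        p <- sample.int(length(chars), 1L)
        chars[p] <- sample(setdiff(letters, chars[p]), 1L)
      } else if (op == "ins") {
        p <- sample.int(length(chars) + 1L, 1L)
        chars <- append(chars, sample(letters, 1L), after = p - 1L)
      } else {
        p <- sample.int(length(chars), 1L)
        chars <- chars[-p]
      }
    }
    paste(chars, collapse = "")
  })
}

#' Simulate a string collection with planted clusters
#'
#' Draws `K` seed strings of length `seed_length` uniformly over the
#' alphabet (or uses supplied seeds) and builds one cluster per seed: the
#' seed itself plus `L - 1` strings obtained by applying `edits` random
#' edit operations to the seed ([random_edits()]).  The per-string noise
#' level is `delta = edits / seed_length`.
#'
#' @param K Number of clusters.
#' @param L Strings per cluster (including the seed).
#' @param seed_length Length of each seed string (default 2000).
#' @param edits Number of edit operations applied to derive each non-seed
#'   string.
#' @param alphabet An [alphabet()]; default DNA (`ACGT`).
#' @param seeds Optional character vector of `K` seed strings (e.g. drawn
#'   from real data) overriding the uniform seeds.
#' @param seed Integer RNG seed.
#' @return A tibble with columns `id`, `sequence` and `cluster` (the true
#'   label, `1..K`), with `delta` attached as an attribute.
#' @export
simulate_clustered_strings <- function(K, L, seed_length = 2000L, edits,
                                       alphabet = c("A", "C", "G", "T"),
                                       seeds = NULL, seed = NULL) {
  stopifnot(K >= 1L, L >= 1L, edits >= 0)
  ab <- as_alphabet(alphabet)
  letters <- unclass(ab)
  with_seed(seed, {
    if (is.null(seeds)) {
      seeds <- vapply(seq_len(K), function(i) {
        paste(sample(letters, seed_length, replace = TRUE), collapse = "")
      }, character(1))
    } else {
      stopifnot(length(seeds) == K)
    }
    rows <- lapply(seq_len(K), function(ci) {
      members <- c(seeds[ci], vapply(seq_len(L - 1L), function(j) {
        random_edits(seeds[ci], edits, ab)
      }, character(1)))
      tibble::tibble(id = sprintf("c%d_s%d", ci, seq_len(L)),
                     sequence = members, cluster = ci)
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "delta") <- edits / seed_length
    out
  })
}

# decode 0-based indices into length-k strings over `letters`
index_to_string <- function(idx0, letters, k) {
  sigma <- length(letters)
  mat <- matrix("", length(idx0), k)
  rem <- idx0
  for (pos in k:1) {
    mat[, pos] <- letters[rem %% sigma + 1L]
    rem <- rem %/% sigma
  }
  apply(mat, 1L, paste, collapse = "")
}

#' Sample a random antidictionary of length-k patterns
#'
#' Two sampling modes: `"space"` draws patterns uniformly without
#' replacement from the whole space of length-`k` strings over the alphabet
#' (`round(rate * sigma^k)` of them, or `count`); `"occurring"` draws
#' uniformly without replacement from the distinct k-grams that actually
#' occur in the supplied collection.
#'
#' @param k Pattern length.
#' @param alphabet An [alphabet()].
#' @param mode `"space"` or `"occurring"`.
#' @param rate Fraction of the length-k space to forbid (`space` mode).
#' @param count Number of patterns (alternative to `rate`; required in
#'   `occurring` mode).
#' @param data Collection (character vector or tibble with `sequence`)
#'   whose k-grams form the pool in `occurring` mode.
#' @param seed Integer RNG seed.
#' @return A [pattern_set()] of uniform length `k`.
#' @export
sample_patterns <- function(k, alphabet, mode = c("space", "occurring"),
                            rate = NULL, count = NULL, data = NULL,
                            seed = NULL) {
  mode <- match.arg(mode)
  ab <- as_alphabet(alphabet)
  letters <- unclass(ab)
  with_seed(seed, {
    if (mode == "space") {
      pool_size <- length(letters)^k
      if (pool_size >= 2^31) {
        ss_abort("bad_k", "the pattern space sigma^k is too large to sample from")
      }
      m <- if (!is.null(count)) count else round(rate * pool_size)
      if (m > pool_size) {
        ss_abort("not_enough_patterns",
                 "requested %d patterns but the space has only %d", m, pool_size)
      }
      pats <- index_to_string(sample.int(pool_size, m) - 1L, letters, k)
    } else {
      if (is.null(data) || is.null(count)) {
        ss_abort("not_enough_patterns",
                 "occurring mode needs the dataset and a pattern count")
      }
      seqs <- if (is.data.frame(data)) data$sequence else as.character(data)
      pool <- unique(unlist(lapply(seqs, kgrams, k = k)))
      if (count > length(pool)) {
        ss_abort("not_enough_patterns",
                 "requested %d patterns but only %d distinct k-grams occur",
                 count, length(pool))
      }
      pats <- sample(pool, count)
    }
    pattern_set(pats, ab)
  })
}
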