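# Independent oracles used across the test files.  All are deliberately
# naive (direct definitions, quadratic DP, exhaustive enumeration) and share
# no code with the implementation paths they check.

# direct window-scan substring search
oracle_contains <- function(x, patterns) {
  any(vapply(as.character(patterns), function(p) {
    n <- nchar(x); m <- nchar(p)
    if (m > n || m == 0L) return(FALSE)
    any(substring(x, 1:(n - m + 1L), m:n) == p)
  }, logical(1)))
}

# O(h^2) dynamic program for the longest strictly increasing subsequence
oracle_lis <- function(v) {
  h <- length(v)
  if (h == 0L) return(0L)
  best <- rep(1L, h)
  for (i in seq_len(h)) {
    for (j in seq_len(i - 1L)) {
      if (v[j] < v[i] && best[j] + 1L > best[i]) best[i] <- best[j] + 1L
    }
  }
  max(best)
}

# is `a` a subsequence of `b`?
is_subsequence <- function(a, b) {
  i <- 1L
  for (x in b) {
    if (i <= length(a) && identical(a[i], x)) i <- i + 1L
  }
  i > length(a)
}

random_string <- function(letters, n) {
  if (n == 0L) return("")
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# all strings over `letters` of exactly length m, lexicographic order
enumerate_strings <- function(letters, m) {
  out <- ""
  for (i in seq_len(m)) out <- paste0(rep(out, each = length(letters)), letters)
  out
}

proper_prefixes <- function(p) substring(p, 1L, 0:(nchar(p) - 1L))

# random anti-factorial pattern set over `letters` (brute-force filtered)
random_pattern_set <- function(letters, n_pat, max_len = 4L) {
  raw <- unique(vapply(seq_len(n_pat), function(i) {
    random_string(letters, sample.int(max_len, 1L))
  }, character(1)))
  keep <- vapply(seq_along(raw), function(i) {
    !any(vapply(raw[-i], function(q) {
      nchar(q) < nchar(raw[i]) && grepl(q, raw[i], fixed = TRUE)
    }, logical(1)))
  }, logical(1))
  raw[keep]
}

# mutual information via the entropy identity I = H(A) + H(B) - H(A,B),
# an algebraically different route than the package's direct formula
oracle_nmi <- function(a, b) {
  ent <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log(p))
  }
  Ha <- ent(table(a)); Hb <- ent(table(b))
  Hab <- ent(table(paste(a, b, sep = "\r")))
  if (Ha == 0 && Hb == 0) return(1)
  if (Ha == 0 || Hb == 0) return(0)
  (Ha + Hb - Hab) / max(Ha, Hb)
}

# pair-by-pair counting of the four agreement classes between partitions
oracle_pair_counts <- function(a, b) {
  n <- length(a)
  N <- c(N00 = 0, N01 = 0, N10 = 0, N11 = 0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      key <- paste0("N", as.integer(sa), as.integer(sb))
      N[key] <- N[key] + 1
    }
  }
  N
}

# non-forbidden k-gram sequence over the original alphabet, computed by
# direct scanning (windows containing '#' are not k-grams over the alphabet)
oracle_gram_seq <- function(w, k, patterns) {
  n <- nchar(w)
  if (n < k) return(character(0))
  g <- substring(w, 1:(n - k + 1L), k:n)
  g[!g %in% as.character(patterns) & !grepl("#", g, fixed = TRUE)]
}

# exhaustive optimum for full sanitization: the shortest string over
# `letters` (ties: none needed, only the length is compared) that avoids all
# patterns and keeps the non-forbidden k-gram sequence of w as a
# subsequence; searches lengths 0..max_len, returns NA if none
oracle_sfss_optimum_length <- function(w, k, patterns, letters, max_len) {
  target <- oracle_gram_seq(w, k, patterns)
  for (m in 0:max_len) {
    cands <- enumerate_strings(letters, m)
    for (x in cands) {
      if (oracle_contains(x, patterns)) next
      if (is_subsequence(target, oracle_gram_seq(x, k, patterns))) return(m)
    }
  }
  NA_integer_
}
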