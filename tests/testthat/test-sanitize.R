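ex_set <- pattern_set(c("bbbb", "aaba", "abba"))
abAC <- alphabet("AC")

test_that("partial sanitization reproduces the worked example", {
  x <- tfs("abbbbaaabaa", 4, ex_set)
  expect_identical(x$text, "abbbaaab#abaa")
  expect_identical(x$segments, c("abbbaaab", "abaa"))
  expect_identical(x$d, 1L)

  expect_identical(tfs("ababab", 4, ex_set)$text, "ababab")  # pattern-free
  expect_identical(tfs("bbbb", 4, pattern_set("bbbb"))$text, "")
  expect_warning(x <- tfs("ab", 4, ex_set), "shorter than k")
  expect_identical(x$text, "")
})

test_that("tfs validates k against the pattern lengths", {
  expect_error(tfs("ab", 1, pattern_set("a")), class = "stringsan_error_bad_k")
  expect_error(tfs("abab", 3, ex_set), class = "stringsan_error_bad_k")
  expect_error(gfss("abab", 3, ex_set), class = "stringsan_error_bad_k")
})

test_that("full sanitization reproduces the worked example", {
  expect_identical(sfss("abbbbaaabaa", 4, ex_set), "abbbaaabbbabaa")
  expect_identical(sfss("ababab", 4, ex_set), "ababab")
})

test_that("full sanitization merges segments when the gap contexts overlap", {
  # the two kept 3-grams CAA and AAC chain through their 2-letter overlap,
  # so the optimal fully-sanitized string drops all three A's of the run;
  # exhaustive search confirms no shorter feasible string exists
  y <- sfss("CAAAAAC", 3, pattern_set("AAA", abAC))
  expect_identical(y, "CAAC")
  expect_false(oracle_contains(y, "AAA"))
  expect_true(is_subsequence(oracle_gram_seq("CAAAAAC", 3, "AAA"),
                             oracle_gram_seq(y, 3, "AAA")))
  expect_identical(
    oracle_sfss_optimum_length("CAAAAAC", 3, "AAA", c("A", "C"), 6L),
    nchar(y))
})

test_that("full sanitization FAILs with the failing gap index", {
  S <- pattern_set(c("ab", "ba"), alphabet("ab"))
  y <- sfss("aabb", 2, S)
  expect_true(is.na(y))
  expect_identical(attr(y, "failed_gap"), 1L)
})

test_that("per-gap antidictionaries are supported", {
  S <- ex_set
  x <- tfs("abbbbaaabaa", 4, S)
  expect_error(sfss("abbbbaaabaa", 4, S, gap_patterns = list(S, S)),
               class = "stringsan_error_bad_k")
  # with the single gap unconstrained, the contexts merge via their overlap
  # (aab/aba overlap by 2), giving a shorter replacement than under ex_set
  y <- sfss("abbbbaaabaa", 4, S,
            gap_patterns = list(pattern_set(character(0), alphabet("ab"))))
  expect_identical(y, "abbbaaabaa")
})

test_that("greedy sanitization deletes letters and can cascade", {
  expect_identical(gfss("CAAAAAC", 3, pattern_set("AAA", abAC)), "CAAC")
  expect_identical(gfss("abbbbaaabaa", 4, ex_set), "abbbaaab")
  expect_identical(gfss("ababab", 4, ex_set), "ababab")
  expect_identical(gfss("ab", 4, ex_set), "ab")  # too short to form a k-gram
})

test_that("the sanitization verifier reports every violation", {
  expect_true(verify_sanitized("abbbaaabbbabaa", ex_set)$ok)
  rep1 <- verify_sanitized("abbbb", pattern_set("bbbb"))
  expect_false(rep1$ok)
  expect_equal(rep1$violations$pattern, "bbbb")
  expect_equal(rep1$violations$position, 2L)
  rep2 <- verify_sanitized("ab#a", pattern_set("bbbb"))
  expect_false(rep2$ok)
  expect_true("#" %in% rep2$violations$pattern)
})

test_that("sanitizer invariants hold on random instances", {
  set.seed(49)
  for (rep in 1:40) {
    letters <- strsplit(c("ab", "abc", "abcd")[sample(3, 1)], "")[[1]]
    k <- sample(2:3, 1)
    pool <- enumerate_strings(letters, k)
    Sk <- pattern_set(sample(pool, min(length(pool) - 1L, sample(1:4, 1))),
                      letters)
    w <- random_string(letters, sample(k:60, 1))
    x <- tfs(w, k, Sk)
    target <- oracle_gram_seq(w, k, Sk)

    # partial output: exact gram sequence, segment lengths, length bound
    expect_identical(oracle_gram_seq(x$text, k, Sk), target)
    expect_true(all(nchar(x$segments) >= k))
    expect_false(any(vapply(x$segments, oracle_contains, logical(1),
                            patterns = Sk)))
    expect_lte(nchar(x$text), nchar(w) + x$d * k)
    occ <- sum(vapply(seq_len(max(0, nchar(w) - k + 1)), function(i) {
      substr(w, i, i + k - 1L) %in% as.character(Sk)
    }, logical(1)))
    expect_lte(x$d, occ)

    # full output: sanitized and supersequence of the gram sequence
    y <- sfss(w, k, Sk)
    if (!is.na(y)) {
      expect_false(oracle_contains(y, Sk))
      expect_false(grepl("#", y, fixed = TRUE))
      expect_true(is_subsequence(target, oracle_gram_seq(y, k, Sk)))
    }

    # greedy output: always sanitized, never longer than the input
    g <- gfss(w, k, Sk)
    expect_true(verify_sanitized(g, Sk)$ok)
    expect_lte(nchar(g), nchar(w))
  }
})

test_that("collections are sanitized with a shared automaton", {
  dat <- tibble::tibble(id = c("r1", "r2"),
                        sequence = c("abbbbaaabaa", "ababab"))
  out <- sanitize_strings(dat, 4, ex_set, method = "sfss")
  expect_identical(out$sanitized, c("abbbaaabbbabaa", "ababab"))
  expect_identical(out$status, c("ok", "ok"))
  out_tfs <- sanitize_strings(dat, 4, ex_set, method = "tfs")
  expect_identical(out_tfs$sanitized[1], "abbbaaab#abaa")
})
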