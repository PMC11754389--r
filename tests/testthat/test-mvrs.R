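ab2 <- alphabet("ab")

test_that("suffix/prefix overlap lengths are found in decreasing order", {
  expect_equal(suffix_prefix_overlaps("aab", "aba"), 2L)
  expect_equal(suffix_prefix_overlaps("abab", "abab"), c(4L, 2L))
  expect_equal(suffix_prefix_overlaps("ab", "cd"), integer(0))
  expect_equal(suffix_prefix_overlaps("", "ab"), integer(0))
})

test_that("solve_mvrs reproduces the worked replacement instance", {
  res <- solve_mvrs("aab", "aba", c("bbbb", "abba", "aaba"))
  expect_identical(res$status, "SOLVED")
  expect_identical(res$x, "aabbbaba")
  expect_identical(res$middle, "bb")

  # a shorter antidictionary admits the overlap solution
  res2 <- solve_mvrs("aab", "aba", pattern_set("bbbb", ab2))
  expect_identical(res2$x, "aaba")
  expect_identical(res2$overlap_used, 2L)
})

test_that("solve_mvrs handles degenerate contexts and infeasibility", {
  expect_identical(solve_mvrs("a", "a", character(0), ab2)$x, "a")
  expect_identical(solve_mvrs("", "", character(0), ab2)$x, "")
  expect_identical(solve_mvrs("a", "", character(0), ab2)$x, "a")
  expect_identical(solve_mvrs("", "ba", pattern_set("bb", ab2))$x, "ba")

  res <- solve_mvrs("a", "b", c("aa", "ab"), ab2)
  expect_identical(res$status, "FAIL")
  expect_identical(res$reason, "NO_PATH")

  res2 <- solve_mvrs("aa", "b", c("aa", "ab"), ab2)
  expect_identical(res2$reason, "PATTERN_IN_CONTEXT")

  expect_error(solve_mvrs("ax", "b", c("aa"), ab2),
               class = "stringsan_error_alphabet_violation")
})

test_that("the exhaustive oracle agrees with itself on the worked examples", {
  expect_identical(
    mvrs_brute_force("aab", "aba", c("bbbb", "abba", "aaba"), max_len = 10)$x,
    "aabbbaba")
  expect_identical(mvrs_brute_force("", "", character(0), ab2)$x, "")
  expect_identical(
    mvrs_brute_force("a", "b", c("aa", "ab"), ab2, max_len = 8)$status, "FAIL")
  expect_error(
    mvrs_brute_force("a", "b", c("aa", "ab"), ab2, max_len = 14, budget = 10),
    class = "stringsan_error_oracle_budget")
})

test_that("solver and exhaustive oracle agree on random instances", {
  set.seed(46)
  n_checked <- 0
  for (rep in 1:150) {
    letters <- strsplit(c("ab", "abc")[sample(2, 1)], "")[[1]]
    pats <- random_pattern_set(letters, sample(1:6, 1))
    if (sum(nchar(pats)) > 24) next
    u <- random_string(letters, sample(0:5, 1))
    v <- random_string(letters, sample(0:5, 1))
    S <- pattern_set(pats, letters)
    got <- solve_mvrs(u, v, S)
    want <- mvrs_brute_force(u, v, S, max_len = nchar(u) + nchar(v) + 6L)
    if (got$status == "SOLVED" && nchar(got$x) > nchar(u) + nchar(v) + 6L) next
    expect_identical(got$status, want$status)
    if (got$status == "SOLVED") {
      expect_identical(nchar(got$x), nchar(want$x))
      # feasibility of the solver's witness
      expect_true(startsWith(got$x, u))
      expect_true(endsWith(got$x, v))
      expect_false(oracle_contains(got$x, pats))
      # overlap solutions are preferred whenever one exists
      if (nchar(want$x) < nchar(u) + nchar(v)) {
        expect_lte(nchar(got$x), nchar(u) + nchar(v) - 1L)
      }
    }
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 100)
})

test_that("adding a forbidden pattern never shortens the optimum", {
  set.seed(47)
  for (rep in 1:40) {
    letters <- c("a", "b")
    pats <- random_pattern_set(letters, sample(1:3, 1))
    extra <- random_string(letters, sample(2:4, 1))
    u <- random_string(letters, sample(0:4, 1))
    v <- random_string(letters, sample(0:4, 1))
    r1 <- solve_mvrs(u, v, pattern_set(pats, letters))
    r2 <- solve_mvrs(u, v, pattern_set(unique(c(pats, extra)), letters))
    if (r1$status == "FAIL") {
      expect_identical(r2$status, "FAIL")
    } else if (r2$status == "SOLVED") {
      expect_gte(nchar(r2$x), nchar(r1$x))
    }
  }
})

test_that("fixed-length instances match shortest paths in the de Bruijn graph", {
  skip_if_not_installed("igraph")
  set.seed(48)
  for (k in 3:4) {
    letters <- c("a", "b")
    nodes <- enumerate_strings(letters, k - 1L)
    all_edges_str <- enumerate_strings(letters, k)
    for (rep in 1:10) {
      Sk <- sample(all_edges_str, sample(2:(length(all_edges_str) - 2L), 1))
      keep <- setdiff(all_edges_str, Sk)
      # edge s corresponds to prefix(s) -> suffix(s)
      el <- cbind(substr(keep, 1L, k - 1L), substring(keep, 2L))
      g <- igraph::graph_from_edgelist(el, directed = TRUE)
      g <- igraph::add_vertices(g, length(setdiff(nodes, igraph::V(g)$name)),
                                name = setdiff(nodes, igraph::V(g)$name))
      u <- sample(nodes, 1); v <- sample(nodes, 1)
      d <- igraph::distances(g, u, v, mode = "out")[1, 1]
      res <- solve_mvrs(u, v, pattern_set(Sk, letters))
      if (is.infinite(d)) {
        expect_identical(res$status, "FAIL")
      } else {
        expect_identical(res$status, "SOLVED")
        expect_equal(nchar(res$x), (k - 1L) + d)
      }
    }
  }
})
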