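# planted two-blob distance matrix: items 1-5 and 6-10, within-block
# distance 1 (0 on the diagonal), between-block distance 10
two_blob <- function() {
  D <- matrix(10, 10, 10)
  D[1:5, 1:5] <- 1
  D[6:10, 6:10] <- 1
  diag(D) <- 0
  D
}

test_that("K-medoids recovers planted structure and degenerate cases", {
  D <- two_blob()
  fit <- pam_cluster(D, 2, seed = 7)
  expect_identical(fit$labels[1:5], rep(fit$labels[1], 5))
  expect_identical(fit$labels[6:10], rep(fit$labels[6], 5))
  expect_false(fit$labels[1] == fit$labels[6])
  expect_equal(fit$cost, 8)  # eight non-medoids at distance 1

  # K = n: every item its own medoid, zero cost
  fit_n <- pam_cluster(D, 10, seed = 7)
  expect_equal(fit_n$cost, 0)
  expect_identical(sort(fit_n$medoids), 1:10)

  # K = 1: the medoid minimizes the row sums
  set.seed(53)
  M <- matrix(runif(64, 1, 5), 8, 8)
  M <- M + t(M); diag(M) <- 0
  fit_1 <- pam_cluster(M, 1, seed = 7)
  expect_identical(fit_1$medoids, which.min(rowSums(M)))

  expect_error(pam_cluster(D, 0, seed = 1), class = "stringsan_error_bad_k")
  expect_error(pam_cluster(D, 11, seed = 1), class = "stringsan_error_bad_k")
})

test_that("K-medoids is deterministic, 1-swap optimal, and matches the
          exhaustive optimum on small instances", {
  set.seed(54)
  for (rep in 1:5) {
    n <- 8
    M <- matrix(runif(n * n, 1, 5), n, n)
    M <- M + t(M); diag(M) <- 0
    fit <- pam_cluster(M, 2, seed = 100 + rep)
    fit2 <- pam_cluster(M, 2, seed = 100 + rep)
    expect_identical(fit$medoids, fit2$medoids)
    expect_equal(fit$cost, clustering_cost(M, fit))

    # no single (medoid, non-medoid) swap improves the final cost
    for (mi in 1:2) {
      for (h in setdiff(1:n, fit$medoids)) {
        cand <- sort(c(fit$medoids[-mi], h))
        alt_cost <- sum(apply(M[, cand], 1, min))
        expect_gte(alt_cost, fit$cost - 1e-9)
      }
    }

    # exhaustive optimum over all medoid pairs
    best <- min(apply(utils::combn(n, 2), 2, function(m) {
      sum(apply(M[, m], 1, min))
    }))
    expect_equal(fit$cost, best)
  }
})

test_that("K-medoids agrees with an established PAM on separated data", {
  skip_if_not_installed("cluster")
  D <- two_blob()
  ours <- pam_cluster(D, 2, seed = 3)
  ref <- cluster::pam(stats::as.dist(D), 2)
  expect_equal(ours$cost, unname(ref$objective["swap"]) * 10)
})

test_that("clustering cost follows the K-median objective", {
  D <- two_blob()
  expect_equal(clustering_cost(D, list(medoids = 1:10, labels = 1:10)), 0)
  expect_equal(clustering_cost(D, list(medoids = c(1L, 6L),
                                       labels = rep(1:2, each = 5))), 8)
  Z <- matrix(0, 3, 3)
  expect_equal(clustering_cost(Z, list(medoids = 1L, labels = rep(1L, 3))), 0)
})

test_that("NMI matches its definition and handles trivial partitions", {
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(nmi(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)   # relabel-invariant
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)   # independent
  expect_equal(nmi(c(1, 1, 1), c(1, 1, 1)), 1)         # both trivial
  expect_equal(nmi(c(1, 1, 1), c(1, 2, 3)), 0)         # one trivial
  expect_error(nmi(1:3, 1:4), class = "stringsan_error_length_mismatch")

  set.seed(55)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    a <- sample.int(4, n, replace = TRUE)
    b <- sample.int(3, n, replace = TRUE)
    got <- nmi(a, b)
    expect_equal(got, oracle_nmi(a, b), tolerance = 1e-12)
    expect_gte(got, 0); expect_lte(got, 1)
    perm <- sample(4)
    expect_equal(nmi(perm[a], b), got)
  }
})

test_that("the pair-counting adjusted Rand index matches brute-force counts", {
  expect_equal(ari(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(ari(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(ari(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)

  set.seed(56)
  for (rep in 1:15) {
    n <- sample(5:25, 1)
    a <- sample.int(3, n, replace = TRUE)
    b <- sample.int(3, n, replace = TRUE)
    N <- oracle_pair_counts(a, b)
    num <- 2 * (N["N00"] * N["N11"] - N["N01"] * N["N10"])
    den <- (N["N00"] + N["N01"]) * (N["N01"] + N["N11"]) +
      (N["N00"] + N["N10"]) * (N["N10"] + N["N11"])
    if (den > 0) expect_equal(ari(a, b), unname(num / den))
  }
})

test_that("the conventional adjusted Rand variant matches mclust", {
  skip_if_not_installed("mclust")
  set.seed(57)
  for (rep in 1:10) {
    n <- sample(6:30, 1)
    a <- sample.int(3, n, replace = TRUE)
    b <- sample.int(4, n, replace = TRUE)
    expect_equal(ari(a, b, variant = "adjusted"),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("the within-cluster LIS score follows its definition", {
  expect_equal(lis_quality("abbbbaaabaa", "abbbbaaabaa", 4), 2 * (11 - 4 + 1))
  expect_equal(lis_quality("abbbbaaabaa", "abbbaaabbbabaa", 4), 12)
  expect_equal(lis_quality(character(0), "abc", 2), 0L)
  expect_error(lis_quality("ab", "abcd", 3), class = "stringsan_error_bad_k")
})
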