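# K-medoids (PAM) clustering on a precomputed LIS k-gram distance matrix,
# and partition-agreement measures.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

assign_to_medoids <- function(D, medoids) {
  sub <- D[, medoids, drop = FALSE]
  nearest <- apply(sub, 1L, which.min)     # ties -> lowest medoid index
  nearest[medoids] <- seq_along(medoids)   # a medoid represents itself
  list(labels = nearest,
       cost = sum(sub[cbind(seq_len(nrow(D)), nearest)]))
}

#' K-medoids clustering of a distance matrix (PAM)
#'
#' Partitioning Around Medoids on a precomputed distance matrix: the
#' objective is the K-median cost, the sum over all items of the distance to
#' the nearest medoid.  Because the LIS k-gram distance is symmetric and
#' zero on identical strings but not a metric, a medoid-based heuristic is
#' used: `K` initial medoids are drawn uniformly without replacement with
#' the seeded generator, then (medoid, non-medoid) swaps are scanned in
#' index order and the first cost-decreasing swap is accepted, restarting
#' the scan, until a full pass yields no improvement; the whole procedure is
#' repeated `restarts` times and the best run kept.  The result is
#' deterministic given `(D, K, seed)` and 1-swap-optimal.
#'
#' @param D Symmetric numeric distance matrix with zero diagonal (e.g. from
#'   [lk_dist_matrix()]).
#' @param K Number of clusters, `1 <= K <= nrow(D)`.
#' @param seed Integer seed for the random initializations (`NULL` to use
#'   the current RNG state).
#' @param restarts Number of random restarts (default 5).
#' @return An object of class `pam_clustering`: list with `medoids`
#'   (ascending item indices), `labels` (cluster index in `1..K` per item;
#'   each item is assigned to its nearest medoid, ties broken toward the
#'   lowest medoid index, and each medoid to itself), `cost`, `K`, `n`,
#'   `ids`.
#' @export
pam_cluster <- function(D, K, seed = NULL, restarts = 5L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (!is.numeric(K) || length(K) != 1L || K < 1L || K > n || K != as.integer(K)) {
    ss_abort("bad_k", "K must be an integer in [1, %d]", n)
  }
  K <- as.integer(K)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(max(1L, restarts))) {
      medoids <- sort(sample.int(n, K))
      fit <- assign_to_medoids(D, medoids)
      repeat {
        improved <- FALSE
        for (mi in seq_len(K)) {
          for (h in setdiff(seq_len(n), medoids)) {
            cand <- sort(c(medoids[-mi], h))
            cfit <- assign_to_medoids(D, cand)
            if (cfit$cost < fit$cost - 1e-9) {
              medoids <- cand
              fit <- cfit
              improved <- TRUE
              break
            }
          }
          if (improved) break
        }
        if (!improved) break
      }
      if (is.null(best) || fit$cost < best$cost - 1e-9) {
        best <- list(medoids = medoids, labels = fit$labels, cost = fit$cost)
      }
    }
  })
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  structure(list(medoids = best$medoids, labels = unname(best$labels),
                 cost = best$cost, K = K, n = n, ids = ids,
                 restarts = restarts, seed = seed),
            class = "pam_clustering")
}

#' @export
print.pam_clustering <- function(x, ...) {
  cat(sprintf("<pam_clustering> K = %d, n = %d, cost = %g\n  medoids: %s\n",
              x$K, x$n, x$cost, paste(x$ids[x$medoids], collapse = ", ")))
  invisible(x)
}

#' K-median cost of a clustering
#'
#' The sum, over every item, of its distance to the medoid of its cluster.
#'
#' @param D Distance matrix.
#' @param clustering A `pam_clustering`, or a list with elements `medoids`
#'   and `labels`.
#' @return Numeric cost.
#' @export
clustering_cost <- function(D, clustering) {
  D <- as.matrix(D)
  m <- clustering$medoids
  l <- clustering$labels
  stopifnot(length(l) == nrow(D), all(l >= 1L), all(l <= length(m)))
  sum(D[cbind(m[l], seq_len(nrow(D)))])
}

contingency <- function(a, b) {
  if (length(a) != length(b)) {
    ss_abort("length_mismatch", "partitions must label the same items")
  }
  table(factor(a), factor(b))
}

#' Normalized mutual information between two partitions
#'
#' `NMI(C, C') = I(C, C') / max(H(C), H(C'))`, where `H` is the entropy of
#' the cluster-size distribution and `I` the mutual information of the
#' contingency counts (natural logarithm; the ratio is base-invariant).
#' When both partitions are trivial (single cluster: both entropies zero)
#' the partitions are identical and the value is defined as 1; when exactly
#' one is trivial it is defined as 0.
#'
#' @param a,b Cluster label vectors of equal length (any label coding).
#' @return Numeric in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  tab <- contingency(a, b)
  N <- sum(tab)
  pa <- rowSums(tab) / N
  pb <- colSums(tab) / N
  Ha <- -sum(ifelse(pa > 0, pa * log(pa), 0))
  Hb <- -sum(ifelse(pb > 0, pb * log(pb), 0))
  if (Ha == 0 && Hb == 0) return(1)
  if (Ha == 0 || Hb == 0) return(0)
  pij <- tab / N
  expected <- outer(pa, pb)
  pos <- pij > 0
  I <- sum(pij[pos] * log(pij[pos] / expected[pos]))
  min(max(I / max(Ha, Hb), 0), 1)
}

#' Adjusted Rand index between two partitions
#'
#' Counts every unordered pair of items into `N11` (same cluster in both
#' partitions), `N00` (different in both), `N10` (same in the first only)
#' and `N01` (same in the second only).  The default `"pair"` variant is
#' `2 (N00 N11 - N01 N10) / ((N00 + N01)(N01 + N11) + (N00 + N10)(N10 + N11))`;
#' the `"adjusted"` variant is the conventional hypergeometric-expectation
#' (Hubert-Arabie) adjusted Rand index, provided for comparison with other
#' tools.
#'
#' @inheritParams nmi
#' @param variant `"pair"` (default) or `"adjusted"`.
#' @return Numeric; 1 for identical partitions.
#' @export
ari <- function(a, b, variant = c("pair", "adjusted")) {
  variant <- match.arg(variant)
  tab <- contingency(a, b)
  N <- sum(tab)
  N11 <- sum(choose(tab, 2))
  sameA <- sum(choose(rowSums(tab), 2))
  sameB <- sum(choose(colSums(tab), 2))
  total <- choose(N, 2)
  N10 <- sameA - N11
  N01 <- sameB - N11
  N00 <- total - N11 - N10 - N01
  if (variant == "pair") {
    num <- 2 * (N00 * N11 - N01 * N10)
    den <- (N00 + N01) * (N01 + N11) + (N00 + N10) * (N10 + N11)
    if (abs(den) < .Machine$double.eps) {
      return(if (N01 + N10 == 0) 1 else NaN)
    }
    num / den
  } else {
    exp_idx <- sameA * sameB / total
    num <- N11 - exp_idx
    den <- (sameA + sameB) / 2 - exp_idx
    if (abs(den) < .Machine$double.eps) {
      return(if (abs(num) < .Machine$double.eps) 1 else 0)
    }
    num / den
  }
}

#' Within-cluster LIS similarity of a clustering
#'
#' The sum over every string of the largest bidirectional LIS similarity
#' `lis_k(y, m) + lis_k(m, y)` to any medoid.  Larger values indicate more
#' compact clusters; unlike [lk_dist()], this score is comparable across
#' sanitizers that output strings of different lengths.
#'
#' @param data Strings (character vector, or tibble with a `sequence`
#'   column).
#' @param medoids Medoid strings (same formats).
#' @param k Window length.
#' @return Integer score (`0` for an empty collection).
#' @export
lis_quality <- function(data, medoids, k) {
  seqs <- if (is.data.frame(data)) data$sequence else as.character(data)
  meds <- if (is.data.frame(medoids)) medoids$sequence else as.character(medoids)
  if (length(seqs) == 0L) return(0L)
  if (any(nchar(c(seqs, meds)) < k)) {
    ss_abort("bad_k", "all strings must have length at least k = %d", k)
  }
  sum(vapply(seqs, function(y) {
    max(vapply(meds, function(m) lis_k(y, m, k) + lis_k(m, y, k), numeric(1)))
  }, numeric(1)))
}
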