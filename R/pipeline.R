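# Three-phase pipeline: sanitize a collection, compute the LIS k-gram
# distance matrix, cluster with K-medoids, and score the agreement between
# the clusterings of the original and the sanitized collection.

#' Sanitize and cluster a string collection
#'
#' Runs the full methodology: Phase I sanitizes every string ([sfss()] by
#' default, or the greedy [gfss()] baseline); Phase II computes the pairwise
#' LIS k-gram distance matrices of the original and the sanitized
#' collection ([lk_dist_matrix()]); Phase III clusters both matrices with
#' seeded K-medoids ([pam_cluster()]).  The clustering `C` of the original
#' collection is compared with the clustering `C'` of the sanitized
#' collection via [nmi()] and [ari()]; if true labels are available (a
#' `cluster` column, or `truth`) both clusterings are also scored against
#' them.  Strings whose sanitization fails or becomes shorter than `k` are
#' excluded from Phases II-III and reported in `failures`.
#'
#' @param data Tibble with `id` and `sequence` (a `cluster` column, if
#'   present, is used as the true labels), or a character vector.
#' @param k Pattern length / distance window.
#' @param K Number of clusters.
#' @param patterns Forbidden patterns of length `k`.
#' @param method `"sfss"` or `"gfss"`.
#' @param seed Integer seed for the clustering initializations.
#' @param truth Optional vector of true labels (overrides a `cluster`
#'   column).
#' @param restarts PAM restarts.
#' @param alphabet Optional [alphabet()].
#' @return An object of class `sanitize_cluster`: list with `data` (per-
#'   string tibble: sanitized sequence, status, original/sanitized cluster,
#'   truth), `D_original`, `D_sanitized`, `clustering_original`,
#'   `clustering_sanitized`, `metrics` (named list: `nmi`, `ari`,
#'   `lis_quality`, and `*_truth_*` entries when truth is known), `failures`
#'   and `params`.
#' @export
sanitize_cluster <- function(data, k, K, patterns,
                             method = c("sfss", "gfss"), seed = 1L,
                             truth = NULL, restarts = 5L, alphabet = NULL) {
  method <- match.arg(method)
  if (is.character(data)) {
    data <- tibble::tibble(id = as.character(seq_along(data)), sequence = data)
  }
  data <- tibble::as_tibble(data)
  if (is.null(truth) && "cluster" %in% names(data)) truth <- data$cluster

  san <- sanitize_strings(data[c("id", "sequence")], k, patterns,
                          method = method, alphabet = alphabet)
  san$status[san$status == "ok" & nchar(san$sanitized) < k] <- "short"
  ok <- san$status == "ok"
  if (sum(ok) < K) {
    ss_abort("bad_k", "only %d usable sanitized strings for K = %d clusters",
             sum(ok), K)
  }

  D_orig <- lk_dist_matrix(san[ok, c("id", "sequence")], k)
  D_san <- lk_dist_matrix(
    tibble::tibble(id = san$id[ok], sequence = san$sanitized[ok]), k)
  C_orig <- pam_cluster(D_orig, K, seed = seed, restarts = restarts)
  C_san <- pam_cluster(D_san, K, seed = seed, restarts = restarts)

  res <- san
  res$cluster_original <- NA_integer_
  res$cluster_sanitized <- NA_integer_
  res$cluster_original[ok] <- C_orig$labels
  res$cluster_sanitized[ok] <- C_san$labels
  if (!is.null(truth)) res$truth <- truth

  metrics <- list(
    nmi = nmi(C_orig$labels, C_san$labels),
    ari = ari(C_orig$labels, C_san$labels),
    lis_quality = lis_quality(san$sanitized[ok],
                              san$sanitized[ok][C_san$medoids], k)
  )
  if (!is.null(truth)) {
    metrics$nmi_truth_original <- nmi(truth[ok], C_orig$labels)
    metrics$nmi_truth_sanitized <- nmi(truth[ok], C_san$labels)
    metrics$ari_truth_sanitized <- ari(truth[ok], C_san$labels)
  }

  structure(list(
    data = res,
    D_original = D_orig, D_sanitized = D_san,
    clustering_original = C_orig, clustering_sanitized = C_san,
    metrics = metrics,
    failures = res[!ok, c("id", "status")],
    params = list(k = k, K = K, method = method, seed = seed,
                  n_patterns = length(as_pattern_set(patterns)))
  ), class = "sanitize_cluster")
}

#' @export
print.sanitize_cluster <- function(x, ...) {
  cat(sprintf(
    "<sanitize_cluster> %s, k = %d, K = %d, %d string(s), %d failure(s)\n",
    x$params$method, x$params$k, x$params$K, nrow(x$data), nrow(x$failures)))
  cat(sprintf("  NMI(C, C') = %.4f, ARI(C, C') = %.4f\n",
              x$metrics$nmi, x$metrics$ari))
  if (!is.null(x$metrics$nmi_truth_sanitized)) {
    cat(sprintf("  NMI(truth, C') = %.4f\n", x$metrics$nmi_truth_sanitized))
  }
  invisible(x)
}

#' Write a machine-readable pipeline report
#'
#' @param x A `sanitize_cluster` result.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  stopifnot(inherits(x, "sanitize_cluster"))
  report <- list(params = x$params, metrics = x$metrics,
                 medoids_original =
                   x$clustering_original$ids[x$clustering_original$medoids],
                 medoids_sanitized =
                   x$clustering_sanitized$ids[x$clustering_sanitized$medoids],
                 failures = x$failures)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
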