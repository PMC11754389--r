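# broom-style accessors and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a K-medoids clustering
#'
#' @param x A `pam_clustering` from [pam_cluster()].
#' @param ... Unused.
#' @return A tibble with one row per item: `id`, `cluster`, `medoid_id`,
#'   `is_medoid`.
#' @method tidy pam_clustering
#' @export
tidy.pam_clustering <- function(x, ...) {
  tibble::tibble(
    id = x$ids,
    cluster = x$labels,
    medoid_id = x$ids[x$medoids[x$labels]],
    is_medoid = seq_len(x$n) %in% x$medoids
  )
}

#' @rdname tidy.pam_clustering
#' @return `glance()` returns a one-row tibble: `K`, `n`, `cost`,
#'   `restarts`.
#' @method glance pam_clustering
#' @export
glance.pam_clustering <- function(x, ...) {
  tibble::tibble(K = x$K, n = x$n, cost = x$cost, restarts = x$restarts)
}

#' Plot a K-medoids clustering by classical MDS of its distance matrix
#'
#' Projects the items onto two dimensions with classical multidimensional
#' scaling of the distance matrix (the LIS k-gram distance is not
#' Euclidean, so the projection is approximate) and colours them by
#' cluster; medoids are drawn larger.
#'
#' @param object A `pam_clustering`.
#' @param D The distance matrix the clustering was fitted to.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pam_clustering
#' @export
autoplot.pam_clustering <- function(object, D, ...) {
  xy <- suppressWarnings(stats::cmdscale(as.matrix(D), k = 2))
  df <- tidy.pam_clustering(object)
  df$mds1 <- xy[, 1]
  df$mds2 <- xy[, 2]
  ggplot2::ggplot(df, ggplot2::aes(.data$mds1, .data$mds2,
                                   colour = factor(.data$cluster))) +
    ggplot2::geom_point(ggplot2::aes(size = .data$is_medoid,
                                     shape = .data$is_medoid)) +
    ggplot2::scale_size_manual(values = c(`FALSE` = 2, `TRUE` = 4),
                               guide = "none") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                                guide = "none") +
    ggplot2::labs(colour = "cluster", x = "MDS 1", y = "MDS 2") +
    ggplot2::theme_minimal()
}

#' Tidy a sanitize-and-cluster result
#'
#' @param x A `sanitize_cluster` from [sanitize_cluster()].
#' @param ... Unused.
#' @return The per-string tibble (`id`, `sequence`, `sanitized`, `status`,
#'   `cluster_original`, `cluster_sanitized`, and `truth` when known).
#' @method tidy sanitize_cluster
#' @export
tidy.sanitize_cluster <- function(x, ...) {
  x$data
}

#' @rdname tidy.sanitize_cluster
#' @return `glance()` returns a one-row tibble with the run parameters and
#'   all agreement metrics.
#' @method glance sanitize_cluster
#' @export
glance.sanitize_cluster <- function(x, ...) {
  dplyr::bind_cols(
    tibble::as_tibble(x$params[c("method", "k", "K", "n_patterns")]),
    tibble::as_tibble(x$metrics)
  )
}

#' @rdname autoplot.pam_clustering
#' @details For a `sanitize_cluster` object the sanitized-collection
#'   distance matrix and clustering are plotted.
#' @method autoplot sanitize_cluster
#' @export
autoplot.sanitize_cluster <- function(object, ...) {
  autoplot.pam_clustering(object$clustering_sanitized, object$D_sanitized)
}
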