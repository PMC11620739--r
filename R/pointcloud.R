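#' Point cloud with an attached metric
#'
#' A finite metric space for topological analysis: the points plus the full
#' matrix of pairwise distances under the chosen metric.
#'
#' * `euclidean` — ambient Euclidean distance;
#' * `knn_geodesic` — shortest-path length along the symmetrized
#'   k-nearest-neighbour graph (edge weights = Euclidean lengths), the
#'   standard estimator of intrinsic geodesic distance;
#' * `correlation` — Pearson correlation distance `1 - r` between rows.
#'
#' @param points numeric matrix, one point per row.
#' @param metric metric name (see above).
#' @param k neighbourhood size for `knn_geodesic` (default 10).
#' @param provenance free-text tag (`"population"`, `"neurons"`,
#'   `"fixture"`, ...).
#' @return object of class `point_cloud`: `points`, `dist`, `metric`, `k`,
#'   `provenance`.
#' @export
point_cloud <- function(points, metric = c("euclidean", "knn_geodesic",
                                           "correlation"),
                        k = 10, provenance = "fixture") {
  metric <- match.arg(metric)
  points <- as.matrix(points)
  if (!all(is.finite(points))) stop("points must be finite")
  D <- switch(metric,
              euclidean = as.matrix(dist(points)),
              knn_geodesic = knn_geodesic_distance(points, k),
              correlation = correlation_distance(points))
  structure(list(points = points, dist = D, metric = metric,
                 k = if (metric == "knn_geodesic") k else NA_integer_,
                 provenance = provenance),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points in R^%d, metric %s%s (%s)\n",
              nrow(x$points), ncol(x$points), x$metric,
              if (!is.na(x$k)) sprintf("(k=%d)", x$k) else "",
              x$provenance))
  invisible(x)
}

#' k-nearest-neighbour geodesic distance matrix
#'
#' Builds the graph joining every point to its k nearest Euclidean
#' neighbours (undirected union of the directed edges), weights each edge
#' by its Euclidean length and returns all-pairs shortest-path distances.
#' Errors when the graph is disconnected, reporting the component sizes.
#'
#' @param points numeric matrix (one point per row), or a precomputed
#'   Euclidean distance matrix.
#' @param k number of neighbours (default 10).
#' @return symmetric matrix of geodesic distances.
#' @export
knn_geodesic_distance <- function(points, k = 10) {
  D <- if (is.matrix(points) && nrow(points) == ncol(points) &&
           isTRUE(all.equal(points, t(points), tolerance = 1e-8)) &&
           all(diag(points) == 0)) points else as.matrix(dist(points))
  n <- nrow(D)
  if (n < k + 1) stop("need at least k + 1 points")
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ], seq_len(n))[2:(k + 1)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj * D, mode = "undirected",
                                           weighted = TRUE)
  comp <- igraph::components(g)
  if (comp$no > 1)
    stop(sprintf(
      "kNN graph (k=%d) is disconnected: component sizes %s; increase k",
      k, paste(sort(comp$csize, decreasing = TRUE), collapse = ", ")))
  G <- igraph::distances(g)
  (G + t(G)) / 2
}

#' Pearson correlation distance matrix between rows
#' @param points matrix; rows are compared.
#' @return matrix of `1 - cor` values (0 for identical, 2 for
#'   anti-correlated rows).
#' @export
correlation_distance <- function(points) {
  if (any(apply(points, 1, sd) == 0))
    stop("correlation distance undefined for constant rows")
  D <- 1 - cor(t(points))
  D[D < 0] <- 0
  diag(D) <- 0
  D
}
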