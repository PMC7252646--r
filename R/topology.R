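as_graph <- function(adjacency) {
  adjacency <- as.matrix(adjacency)
  if (!all(adjacency == t(adjacency)))
    stop("adjacency matrix must be symmetric")
  # edge-list constructor: much cheaper than the dense-matrix route for
  # the many small graphs handled per series
  idx <- which(adjacency != 0 & upper.tri(adjacency), arr.ind = TRUE)
  igraph::make_graph(t(idx), n = nrow(adjacency), directed = FALSE)
}

#' Network density
#'
#' Fraction of the `n(n-1)/2` possible edges that are present.
#'
#' @param adjacency Symmetric 0/1 matrix with zero diagonal.
#' @return Density in `[0, 1]`.
#' @export
network_density <- function(adjacency) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (n < 2L) stop("density is undefined for fewer than 2 nodes")
  if (!all(adjacency == t(adjacency)))
    stop("adjacency matrix must be symmetric")
  sum(adjacency != 0) / (n * (n - 1))
}

#' Mean network efficiency
#'
#' Mean over unordered node pairs of the reciprocal shortest-path length,
#' with disconnected pairs contributing 0. Unlike the mean path length,
#' this is well defined on the sparse, partly disconnected networks typical
#' of thresholded functional connectivity.
#'
#' @param adjacency Symmetric 0/1 matrix with zero diagonal.
#' @return Mean efficiency in `[0, 1]`.
#' @export
mean_efficiency <- function(adjacency) {
  n <- nrow(as.matrix(adjacency))
  if (n < 2L) stop("efficiency is undefined for fewer than 2 nodes")
  D <- igraph::distances(as_graph(adjacency))
  inv <- 1 / D[upper.tri(D)]
  mean(inv)
}

#' Global clustering coefficient
#'
#' `type = "average"` (default) is the mean of local clustering
#' coefficients, with nodes of degree below 2 contributing 0.
#' `type = "transitivity"` is the ratio of closed triads to all triads.
#'
#' @param adjacency Symmetric 0/1 matrix with zero diagonal.
#' @param type `"average"` or `"transitivity"`.
#' @return Clustering coefficient in `[0, 1]`.
#' @export
global_clustering <- function(adjacency, type = c("average", "transitivity")) {
  type <- match.arg(type)
  n <- nrow(as.matrix(adjacency))
  if (n < 1L) stop("clustering is undefined for an empty node set")
  g <- as_graph(adjacency)
  if (type == "average") {
    igraph::transitivity(g, type = "localaverage", isolates = "zero")
  } else {
    v <- igraph::transitivity(g, type = "global")
    if (is.nan(v)) 0 else v
  }
}

#' Per-window topology of a binary network series
#'
#' @param networks A `binary_network_series`.
#' @param clustering_type Passed to [global_clustering()].
#' @return Object of class `topology_record`: data frame with one row per
#'   window (`window_index`, `window_start`, `density`, `efficiency`,
#'   `clustering`).
#' @export
topology_series <- function(networks, clustering_type = "average") {
  stopifnot(inherits(networks, "binary_network_series"))
  W <- dim(networks$adj)[3]
  out <- data.frame(window_index = seq_len(W),
                    window_start = networks$window_start,
                    density = numeric(W), efficiency = numeric(W),
                    clustering = numeric(W))
  for (w in seq_len(W)) {
    A <- networks$adj[, , w]
    out$density[w] <- network_density(A)
    out$efficiency[w] <- mean_efficiency(A)
    out$clustering[w] <- global_clustering(A, clustering_type)
  }
  class(out) <- c("topology_record", class(out))
  out
}

#' Time-averaged topology
#'
#' Arithmetic mean of each per-window metric over all windows.
#'
#' @param records A `topology_record` (data frame from [topology_series()]),
#'   or any data frame with `density`, `efficiency` and `clustering`
#'   columns.
#' @return Named numeric vector with `density`, `efficiency`, `clustering`.
#' @export
time_average <- function(records) {
  if (nrow(records) < 1L) stop("need at least one window to average")
  c(density = mean(records$density),
    efficiency = mean(records$efficiency),
    clustering = mean(records$clustering))
}

#' Matched-density random-network null distribution
#'
#' Samples uniform random graphs with exactly `m` edges on `n` nodes (the
#' G(n, m) ensemble, matching the observed network density exactly) and
#' returns the per-replicate mean efficiency and clustering coefficient.
#'
#' @param n Number of nodes.
#' @param m Number of edges, `0 <= m <= n(n-1)/2`.
#' @param reps Number of replicates.
#' @param seed Integer seed.
#' @param clustering_type Passed to [global_clustering()].
#' @return Data frame with `efficiency` and `clustering`, one row per
#'   replicate.
#' @export
random_network_null <- function(n, m, reps = 1000, seed = 1L,
                                clustering_type = "average") {
  if (m < 0 || m > n * (n - 1) / 2)
    stop("edge count m out of range for ", n, " nodes")
  set.seed(seed)
  eff <- numeric(reps)
  clu <- numeric(reps)
  for (r in seq_len(reps)) {
    g <- igraph::sample_gnm(n, m)
    D <- igraph::distances(g)
    eff[r] <- mean(1 / D[upper.tri(D)])
    clu[r] <- if (clustering_type == "average")
      igraph::transitivity(g, type = "localaverage", isolates = "zero")
    else {
      v <- igraph::transitivity(g, type = "global")
      if (is.nan(v)) 0 else v
    }
  }
  data.frame(efficiency = eff, clustering = clu)
}

#' Recurrence-probability network across trials
#'
#' For each channel pair, the fraction of windows in which the edge is
#' present is computed within each trial; the per-trial probabilities are
#' then averaged across trials with equal weight, giving a single
#' representative weighted network for a condition. An optional display
#' threshold binarizes the result.
#'
#' @param trials List of `binary_network_series` sharing channel labels.
#' @param display_threshold Optional probability threshold; edges at or
#'   above it are kept in the `thresholded` matrix.
#' @return List of class `edge_probability_network` with `probability`
#'   (symmetric matrix in `[0, 1]`, zero diagonal), `labels`, and
#'   `thresholded` (0/1 matrix, or `NULL`).
#' @export
recurrence_probability_network <- function(trials, display_threshold = NULL) {
  stopifnot(length(trials) >= 1L)
  labels <- trials[[1L]]$labels
  for (tr in trials) {
    stopifnot(inherits(tr, "binary_network_series"))
    if (!identical(tr$labels, labels))
      stop("all trials must share the same channel labels")
  }
  acc <- 0
  for (tr in trials) acc <- acc + apply(tr$adj, c(1, 2), mean)
  P <- acc / length(trials)
  diag(P) <- 0
  thr <- NULL
  if (!is.null(display_threshold)) {
    thr <- (P >= display_threshold) * 1L
    diag(thr) <- 0L
  }
  structure(list(probability = P, labels = labels, thresholded = thr),
            class = "edge_probability_network")
}

#' @export
print.edge_probability_network <- function(x, ...) {
  cat("Recurrence-probability network:", nrow(x$probability), "channels,",
      "mean edge probability", format(mean(x$probability[upper.tri(x$probability)]), digits = 3), "\n")
  invisible(x)
}
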