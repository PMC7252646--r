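#' Hierarchical partition of a distance matrix at a depth threshold
#'
#' Cuts the single-linkage dendrogram of the pairwise phase-locking
#' distances at `depth_threshold`. For single linkage this cut equals the
#' connected components of the graph joining pairs with distance strictly
#' below the threshold — the same edge rule as the eigenvector pipeline —
#' which is how it is computed here.
#'
#' @param distances Symmetric nonnegative distance matrix, zero diagonal.
#' @param depth_threshold Positive branch-depth threshold (the canonical
#'   value equals the binarization threshold, `4e-4`).
#' @return Integer vector of cluster labels (numbered by first occurrence).
#' @export
hierarchical_partition <- function(distances, depth_threshold = 4e-4) {
  distances <- as.matrix(distances)
  if (!all(distances == t(distances)))
    stop("distance matrix must be symmetric")
  adj <- (distances < depth_threshold) * 1L
  diag(adj) <- 0L
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  match(comp, unique(comp))
}

#' Modularity partition of a connectivity matrix
#'
#' Greedy agglomerative (fast-greedy) modularity maximization. In
#' `"thresholded"` mode the input is a binary adjacency matrix and is used
#' as is. In `"weighted"` mode the input is a distance matrix, converted
#' to similarities by `s = 1 / (eps + d)` (small distance = strong edge)
#' with the diagonal removed.
#'
#' @param matrix Symmetric nonnegative matrix: binary adjacency
#'   (`"thresholded"`) or distances (`"weighted"`).
#' @param mode `"thresholded"` or `"weighted"`.
#' @param eps Regularizer of the similarity transform.
#' @return Integer vector of cluster labels (numbered by first occurrence).
#' @export
modularity_partition <- function(matrix, mode = c("thresholded", "weighted"),
                                 eps = 1e-6) {
  mode <- match.arg(mode)
  matrix <- as.matrix(matrix)
  if (!all(matrix == t(matrix)))
    stop("input matrix must be symmetric")
  if (any(matrix < 0)) stop("negative weights are not supported")
  n <- nrow(matrix)
  if (mode == "weighted") {
    matrix <- 1 / (eps + matrix)
    diag(matrix) <- 0
    g <- igraph::graph_from_adjacency_matrix(matrix, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
  } else {
    g <- igraph::graph_from_adjacency_matrix((matrix != 0) * 1,
                                             mode = "undirected", diag = FALSE)
  }
  if (igraph::ecount(g) == 0L) return(seq_len(n))
  comm <- igraph::cluster_fast_greedy(g)
  # choose the dendrogram cut with maximal modularity; on ties prefer the
  # coarsest partition (deterministic, and a complete graph then yields a
  # single community)
  w <- if (mode == "weighted") igraph::E(g)$weight else NULL
  n_min <- n - nrow(comm$merges)
  best <- NULL
  best_q <- -Inf
  for (no in n_min:n) {
    memb <- igraph::cut_at(comm, no = no)
    q <- igraph::modularity(g, memb, weights = w)
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- memb
    }
  }
  match(best, unique(best))
}

#' Track cluster labels across windows by overlap
#'
#' Propagates cluster labels through a sequence of per-window partitions:
#' each window's clusters are matched to the previous window's by maximal
#' Jaccard overlap (greedy, largest overlap first; ties go to the lower
#' previous label), and unmatched clusters receive fresh labels. Clusters
#' with zero overlap to any previous cluster always get fresh labels.
#'
#' @param partitions Integer matrix, windows x oscillators (each row a
#'   partition), or a list of per-window label vectors.
#' @return Object of class `cluster_timeline`: integer matrix, windows x
#'   oscillators, with temporally consistent labels.
#' @export
track_clusters <- function(partitions) {
  if (is.list(partitions)) partitions <- do.call(rbind, partitions)
  partitions <- as.matrix(partitions)
  W <- nrow(partitions)
  n <- ncol(partitions)
  if (W == 0L) stop("no partitions to track")
  out <- matrix(NA_integer_, W, n)
  next_label <- 1L
  relabel_first <- match(partitions[1L, ], unique(partitions[1L, ]))
  out[1L, ] <- relabel_first
  next_label <- max(relabel_first) + 1L
  if (W == 1L) return(structure(out, class = c("cluster_timeline", "matrix")))
  for (w in 2L:W) {
    prev_labels <- out[w - 1L, ]
    cur <- partitions[w, ]
    cur_ids <- unique(cur)
    prev_ids <- sort(unique(prev_labels))
    # Jaccard overlap of every (current, previous) cluster pair
    cand <- expand.grid(cur = cur_ids, prev = prev_ids)
    cand$jac <- mapply(function(ci, pi) {
      a <- cur == ci; b <- prev_labels == pi
      sum(a & b) / sum(a | b)
    }, cand$cur, cand$prev)
    cand <- cand[cand$jac > 0, , drop = FALSE]
    cand <- cand[order(-cand$jac, cand$prev), , drop = FALSE]
    assigned <- stats::setNames(rep(NA_integer_, length(cur_ids)), cur_ids)
    used_prev <- integer()
    for (r in seq_len(nrow(cand))) {
      ci <- as.character(cand$cur[r])
      if (!is.na(assigned[ci]) || cand$prev[r] %in% used_prev) next
      assigned[ci] <- cand$prev[r]
      used_prev <- c(used_prev, cand$prev[r])
    }
    for (ci in names(assigned)) {
      if (is.na(assigned[ci])) {
        assigned[ci] <- next_label
        next_label <- next_label + 1L
      }
    }
    out[w, ] <- assigned[as.character(cur)]
  }
  structure(out, class = c("cluster_timeline", "matrix"))
}

#' @export
print.cluster_timeline <- function(x, ...) {
  cat("Cluster timeline:", nrow(x), "windows x", ncol(x), "oscillators,",
      length(unique(as.vector(x))), "distinct labels\n")
  invisible(x)
}

#' Cluster timeline of a network or distance series
#'
#' Convenience wrapper: partitions every window with the chosen baseline
#' method and tracks labels across windows with [track_clusters()].
#'
#' @param x A `plv_distance_series` (for `"hierarchical"` and
#'   `"modularity_weighted"`) or `binary_network_series` (for
#'   `"modularity_thresholded"`).
#' @param method Partitioning method.
#' @param depth_threshold Threshold for the hierarchical cut.
#' @return A `cluster_timeline` matrix, windows x oscillators.
#' @export
cluster_timeline <- function(x, method = c("hierarchical",
                                           "modularity_weighted",
                                           "modularity_thresholded"),
                             depth_threshold = 4e-4) {
  method <- match.arg(method)
  if (method == "modularity_thresholded") {
    stopifnot(inherits(x, "binary_network_series"))
    mats <- x$adj
    fun <- function(A) modularity_partition(A, "thresholded")
  } else {
    stopifnot(inherits(x, "plv_distance_series"))
    mats <- x$d
    fun <- if (method == "hierarchical")
      function(A) hierarchical_partition(A, depth_threshold)
    else
      function(A) modularity_partition(A, "weighted")
  }
  W <- dim(mats)[3]
  parts <- matrix(NA_integer_, W, dim(mats)[1])
  for (w in seq_len(W)) parts[w, ] <- fun(mats[, , w])
  track_clusters(parts)
}
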