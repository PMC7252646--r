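# Independent oracles used to cross-check the implementation. These stay
# deliberately naive (enumeration, brute force, power iteration) and never
# call the code paths they verify.

# Top eigenvalue/eigenvector by shifted power iteration. The shift by n
# makes the dominant eigenvalue of A + nI the (unique) largest in magnitude
# whenever A's top eigenvalue is simple.
oracle_power_top <- function(A, iters = 3000, resid_tol = 1e-6) {
  n <- nrow(A)
  B <- A + diag(n, n)
  v <- rep(1 / sqrt(n), n)
  lam <- n
  for (i in seq_len(iters)) {
    w <- B %*% v
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(list(value = 0, vector = v))
    v <- as.vector(w) / nw
    lam <- sum(v * (B %*% v))
    # for symmetric B the eigenvalue error is bounded by the residual norm
    if (sqrt(sum((B %*% v - lam * v)^2)) < resid_tol) break
  }
  list(value = lam - n, vector = v)
}

# All-pairs shortest-path lengths by breadth-first expansion of the
# neighborhood indicator (no igraph).
oracle_bfs_dist <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(TRUE, n)
  Alog <- A != 0
  for (k in seq_len(n)) {
    new_reach <- reach | (reach %*% Alog) > 0
    newly <- new_reach & !reach
    D[newly] <- k
    if (all(new_reach == reach)) break
    reach <- new_reach
  }
  D
}

oracle_mean_efficiency <- function(A) {
  D <- oracle_bfs_dist(A)
  mean(1 / D[upper.tri(D)])
}

# Mean local clustering by explicit triad enumeration; degree < 2 nodes
# contribute 0.
oracle_mean_clustering <- function(A) {
  n <- nrow(A)
  local <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] != 0)
    k <- length(nb)
    if (k < 2) next
    links <- sum(A[nb, nb] != 0) / 2
    local[v] <- links / (k * (k - 1) / 2)
  }
  mean(local)
}

# Exact two-sided signed-rank p-value by enumerating all sign assignments
# of the nonzero differences (requires no ties in |d|).
oracle_wilcoxon_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  total <- 2^n
  stats_all <- numeric(total)
  for (mask in 0:(total - 1)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    stats_all[mask + 1] <- sum(r[signs])
  }
  mu <- n * (n + 1) / 4
  p <- sum(abs(stats_all - mu) >= abs(v_obs - mu)) / total
  min(1, p)
}

# Closed-form windowed phasor distance for a constant speed gap.
oracle_const_gap_distance <- function(delta, width) 2 * abs(sin(delta / 2)) * sqrt(width)

# All simple graphs on n nodes as adjacency matrices (n <= 6 is feasible).
all_graphs <- function(n) {
  npairs <- n * (n - 1) / 2
  ut <- which(upper.tri(matrix(0, n, n)))
  lapply(0:(2^npairs - 1), function(mask) {
    A <- matrix(0L, n, n)
    bits <- bitwAnd(bitwShiftR(mask, 0:(npairs - 1)), 1L)
    A[ut] <- bits
    A + t(A)
  })
}

rand_graph <- function(n, p = 0.3) {
  A <- matrix(0L, n, n)
  ut <- upper.tri(A)
  A[ut] <- stats::rbinom(sum(ut), 1, p)
  A + t(A)
}

# Adjacency of a disjoint union of cliques given by a membership list.
clique_union <- function(n, cliques) {
  A <- matrix(0L, n, n)
  for (cl in cliques) for (i in cl) for (j in cl) if (i != j) A[i, j] <- 1L
  A
}

# Uniform Perron vector supported on one clique.
uniform_on <- function(n, members) {
  v <- numeric(n)
  v[members] <- 1 / sqrt(length(members))
  v
}

# Wrap a plain speed matrix and window into the distance -> network ->
# eigenvector chain used by scenario-level tests.
speeds_to_ips <- function(speed, width = 40L, step = 1L, threshold = 4e-4) {
  d <- windowed_plv_distance(speed, window_spec(width, step, 1000))
  es <- eigenvector_series(binarize(d, threshold))
  list(distances = d, eigen = es, ips = successive_inner_products(es))
}
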