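#' Prime eigenvector of a binary network
#'
#' Returns the eigenvector associated with the largest eigenvalue of a
#' symmetric 0/1 adjacency matrix, unit-normalized and oriented so that all
#' entries are nonnegative (the Perron orientation). For a disjoint union
#' of cliques this is the uniform vector `1/sqrt(k)` on the members of the
#' largest clique, so its support identifies the largest phase-locked
#' cluster.
#'
#' When the top eigenvalue is degenerate (relative gap below `tol`, e.g.
#' two synchronized clusters of equal size), the returned vector is the
#' normalized projection of `previous` onto the top eigenspace, which keeps
#' the series continuous: identical consecutive networks always give an
#' inner product of exactly 1. Without a `previous` vector the projection
#' of the first coordinate axis with a nonzero component in the eigenspace
#' is used. An edgeless network has no meaningful leading direction and is
#' flagged invalid.
#'
#' @param adjacency Symmetric numeric 0/1 matrix with zero diagonal.
#' @param previous Optional unit vector from the preceding window, used for
#'   degeneracy tie-breaking.
#' @param tol Relative eigenvalue-gap tolerance for degeneracy.
#' @param check Verify symmetry of the input (disable only when the caller
#'   guarantees it, e.g. a validated series).
#' @return List with `vector` (unit norm, entries >= 0, or `NA` if
#'   invalid), `value` (largest eigenvalue) and `valid`.
#' @export
prime_eigenvector <- function(adjacency, previous = NULL, tol = 1e-8,
                              check = TRUE) {
  adjacency <- as.matrix(adjacency)
  if (check && !all(adjacency == t(adjacency)))
    stop("adjacency matrix must be symmetric")
  n <- nrow(adjacency)
  if (all(adjacency == 0))
    return(list(vector = rep(NA_real_, n), value = 0, valid = FALSE))
  e <- eigen(adjacency, symmetric = TRUE)
  lam <- e$values[1L]
  top <- which(e$values >= lam - tol * max(1, abs(lam)))
  if (length(top) == 1L) {
    v <- e$vectors[, 1L]
  } else {
    V <- e$vectors[, top, drop = FALSE]
    v <- NULL
    if (!is.null(previous) && all(is.finite(previous))) {
      p <- V %*% crossprod(V, previous)
      if (sqrt(sum(p^2)) > tol) v <- drop(p)
    }
    if (is.null(v)) {
      for (j in seq_len(n)) {
        p <- V %*% t(V[j, , drop = FALSE])
        if (sqrt(sum(p^2)) > tol) { v <- drop(p); break }
      }
    }
  }
  v <- v / sqrt(sum(v^2))
  if (sum(v) < 0) v <- -v
  v[abs(v) < 1e-12] <- 0
  v <- v / sqrt(sum(v^2))
  list(vector = v, value = lam, valid = TRUE)
}

#' Prime-eigenvector series of a binary network series
#'
#' Applies [prime_eigenvector()] to every window, threading each window's
#' vector into the next call as the degeneracy tie-breaker. Edgeless
#' windows are flagged invalid (their vector columns are `NA`), not
#' fabricated.
#'
#' @param networks A `binary_network_series` (see [binarize()]).
#' @param tol Degeneracy tolerance passed to [prime_eigenvector()].
#' @return An object of class `eigenvector_series`: list with `vectors`
#'   (channels x windows matrix), `values`, `valid`, `labels`,
#'   `window_start`, `window`.
#' @export
eigenvector_series <- function(networks, tol = 1e-8) {
  stopifnot(inherits(networks, "binary_network_series"))
  n <- dim(networks$adj)[1]
  W <- dim(networks$adj)[3]
  vectors <- matrix(NA_real_, n, W)
  values <- numeric(W)
  valid <- logical(W)
  prev <- NULL
  for (w in seq_len(W)) {
    # the series constructor guarantees symmetry; skip per-window checks
    pe <- prime_eigenvector(networks$adj[, , w], previous = prev, tol = tol,
                            check = w == 1L)
    values[w] <- pe$value
    valid[w] <- pe$valid
    if (pe$valid) {
      vectors[, w] <- pe$vector
      prev <- pe$vector
    }
  }
  rownames(vectors) <- networks$labels
  structure(list(vectors = vectors, values = values, valid = valid,
                 labels = networks$labels,
                 window_start = networks$window_start,
                 window = networks$window),
            class = "eigenvector_series")
}

#' @export
print.eigenvector_series <- function(x, ...) {
  cat("Prime eigenvector series:", nrow(x$vectors), "channels,",
      ncol(x$vectors), "windows (", sum(x$valid), "valid )\n")
  invisible(x)
}

#' Inner products of successive prime eigenvectors
#'
#' The dot product of the prime eigenvectors of consecutive windows. Both
#' vectors are unit-norm and entrywise nonnegative, so values lie in
#' `[0, 1]`: values near 1 mean the largest cluster persisted, values near
#' 0 mean it was replaced by a (nearly) disjoint one. Pairs involving an
#' invalid window are flagged invalid and carry `NA`.
#'
#' @param series An `eigenvector_series`.
#' @return An object of class `inner_product_series`: list with `values`
#'   (length `windows - 1`), `valid`, `window_start` (start sample of the
#'   later window of each pair), `window`.
#' @export
successive_inner_products <- function(series) {
  stopifnot(inherits(series, "eigenvector_series"))
  W <- ncol(series$vectors)
  if (W < 2L) stop("need at least 2 windows")
  ip <- colSums(series$vectors[, -W, drop = FALSE] *
                series$vectors[, -1L, drop = FALSE])
  valid <- series$valid[-W] & series$valid[-1L]
  ip[!valid] <- NA_real_
  ip[valid] <- pmin(pmax(ip[valid], 0), 1)
  structure(list(values = ip, valid = valid,
                 window_start = series$window_start[-1L],
                 window = series$window),
            class = "inner_product_series")
}

#' @export
print.inner_product_series <- function(x, ...) {
  cat("Successive inner-product series:", length(x$values), "pairs (",
      sum(x$valid), "valid )\n")
  invisible(x)
}

#' Count transition and persistence events
#'
#' Counts Event 0 (inner product `< lo`, a transition of the prime
#' eigenvector between states) and Event 1 (inner product `> hi`, the
#' eigenvector staying in the same state) over valid pairs, and their
#' frequencies normalized by the number of valid pairs.
#'
#' @param series An `inner_product_series`.
#' @param lo,hi Event thresholds, `0 <= lo < hi <= 1` (defaults 0.01 and
#'   0.99).
#' @return List with `n_event0`, `n_event1`, `n_valid`, `freq_event0`,
#'   `freq_event1`.
#' @export
count_events <- function(series, lo = 0.01, hi = 0.99) {
  stopifnot(inherits(series, "inner_product_series"))
  if (!(lo >= 0 && lo < hi && hi <= 1))
    stop("event thresholds must satisfy 0 <= lo < hi <= 1")
  v <- series$values[series$valid]
  n <- length(v)
  n0 <- sum(v < lo)
  n1 <- sum(v > hi)
  list(n_event0 = n0, n_event1 = n1, n_valid = n,
       freq_event0 = if (n > 0) n0 / n else NA_real_,
       freq_event1 = if (n > 0) n1 / n else NA_real_)
}

#' Detect transition spikes in an inner-product series
#'
#' A spike is a maximal run of consecutive valid values below
#' `plateau_level` that contains at least one value at or below
#' `spike_level`; it is reported at its minimum, with depth `1 - minimum`.
#' Two spikes are distinct iff separated by at least one value at or above
#' `plateau_level`. Invalid pairs are skipped and do not interrupt a run.
#'
#' The default `spike_level = 0.95` lies above every cross-plateau overlap
#' produced by the scripted scenarios (the largest is
#' `sqrt(14/17) ~ 0.907`, the shallow separation spike of the benchmark
#' scenario) and below the numerically noisy plateau band near 1.
#'
#' @param series An `inner_product_series`.
#' @param plateau_level Values at or above this belong to a plateau
#'   (default 0.99).
#' @param spike_level Maximum run minimum for the run to count as a spike.
#' @return Data frame with one row per spike: `pair_index` (index of the
#'   minimum in the series), `window_start` (start sample of the later
#'   window of the minimum pair), `minimum` and `depth`.
#' @export
detect_spikes <- function(series, plateau_level = 0.99, spike_level = 0.95) {
  stopifnot(inherits(series, "inner_product_series"))
  if (!(plateau_level > spike_level && spike_level >= 0))
    stop("need plateau_level > spike_level >= 0")
  idx <- which(series$valid)
  v <- series$values[idx]
  out <- data.frame(pair_index = integer(), window_start = integer(),
                    minimum = numeric(), depth = numeric())
  in_run <- FALSE
  run_min <- Inf
  run_at <- NA_integer_
  flush <- function() {
    if (in_run && run_min <= spike_level)
      out[nrow(out) + 1L, ] <<- list(run_at, series$window_start[run_at],
                                     run_min, 1 - run_min)
  }
  for (k in seq_along(v)) {
    if (v[k] < plateau_level) {
      if (!in_run) { in_run <- TRUE; run_min <- Inf }
      if (v[k] < run_min) { run_min <- v[k]; run_at <- idx[k] }
    } else {
      flush()
      in_run <- FALSE
    }
  }
  flush()
  out
}

#' All-pairs recurrence matrix of prime eigenvectors
#'
#' Entry `(i, j)` is the inner product of the prime eigenvectors of windows
#' `i` and `j` within `range`; the diagonal is 1 for valid windows. Blocks
#' of high values along the diagonal are meta-stable states (temporal
#' clusters of similar network structure); off-diagonal blocks show states
#' recurring later in the trial.
#'
#' @param series An `eigenvector_series`.
#' @param range Integer vector of window indices (default: all windows).
#' @return Symmetric numeric matrix in `[0, 1]` with `NA` rows/columns for
#'   invalid windows.
#' @export
recurrence_matrix <- function(series, range = NULL) {
  stopifnot(inherits(series, "eigenvector_series"))
  W <- ncol(series$vectors)
  if (is.null(range)) range <- seq_len(W)
  if (length(range) == 0L) stop("empty window range")
  if (any(range < 1L) || any(range > W)) stop("window range out of bounds")
  V <- series$vectors[, range, drop = FALSE]
  R <- crossprod(V)
  ok <- series$valid[range]
  R[ok, ok] <- pmin(pmax(R[ok, ok], 0), 1)
  diag(R)[ok] <- 1
  R
}

#' Segment an eigenvector series into meta-stable states
#'
#' Greedy segmentation: a state is extended while the inner product of the
#' current window's eigenvector with the state centroid (the renormalized
#' running mean of the state's vectors) stays at or above `similarity`.
#' When a window breaks away, it starts a new state if it matches its own
#' successor at `similarity`; otherwise it is marked a transition window.
#' Invalid windows are transition windows. Durations are reported in
#' windows and in seconds (windows are `step / fs` seconds apart).
#'
#' @param series An `eigenvector_series`.
#' @param similarity Similarity threshold (default 0.99).
#' @return List of class `state_segmentation` with `states` (data frame:
#'   `start`, `end`, `duration_windows`, `duration_s`), `centroids`
#'   (channels x states matrix, unit columns) and `transition_windows`
#'   (indices belonging to no state).
#' @export
segment_states <- function(series, similarity = 0.99) {
  stopifnot(inherits(series, "eigenvector_series"))
  W <- ncol(series$vectors)
  step_s <- series$window$step / series$window$fs
  states <- data.frame(start = integer(), end = integer(),
                       duration_windows = integer(), duration_s = numeric())
  centroids <- list()
  transition <- integer()
  cur_sum <- NULL
  cur_start <- NA_integer_
  cur_n <- 0L
  close_state <- function(last) {
    if (cur_n > 0L) {
      c0 <- cur_sum / sqrt(sum(cur_sum^2))
      states[nrow(states) + 1L, ] <<- list(cur_start, last, cur_n, cur_n * step_s)
      centroids[[length(centroids) + 1L]] <<- c0
    }
  }
  w <- 1L
  while (w <= W) {
    if (!series$valid[w]) {
      close_state(w - 1L); cur_n <- 0L; cur_sum <- NULL
      transition <- c(transition, w)
      w <- w + 1L
      next
    }
    v <- series$vectors[, w]
    if (cur_n > 0L) {
      cen <- cur_sum / sqrt(sum(cur_sum^2))
      if (sum(v * cen) >= similarity) {
        cur_sum <- cur_sum + v
        cur_n <- cur_n + 1L
        w <- w + 1L
        next
      }
      close_state(w - 1L); cur_n <- 0L; cur_sum <- NULL
    }
    # try to open a state at w: needs a valid, similar successor or to be
    # the final window
    nxt <- w + 1L
    open_ok <- (nxt > W) || (series$valid[nxt] &&
                             sum(v * series$vectors[, nxt]) >= similarity)
    if (open_ok) {
      cur_sum <- v
      cur_start <- w
      cur_n <- 1L
    } else {
      transition <- c(transition, w)
    }
    w <- w + 1L
  }
  close_state(W)
  cen <- if (length(centroids)) do.call(cbind, centroids) else
    matrix(numeric(), nrow(series$vectors), 0)
  rownames(cen) <- series$labels
  structure(list(states = states, centroids = cen,
                 transition_windows = transition),
            class = "state_segmentation")
}

#' @export
print.state_segmentation <- function(x, ...) {
  cat("State segmentation:", nrow(x$states), "meta-stable states,",
      length(x$transition_windows), "transition windows\n")
  invisible(x)
}

#' Accumulated event frequencies
#'
#' Running counts of Event 0 and Event 1 divided by the running number of
#' valid pairs, evaluated after each successive pair. The final values
#' equal the frequencies from [count_events()]. Suitable for online
#' monitoring of a growing network series.
#'
#' @inheritParams count_events
#' @return Data frame with `pair_index`, `accum_event0`, `accum_event1`
#'   (`NA` until the first valid pair).
#' @export
accumulated_event_frequency <- function(series, lo = 0.01, hi = 0.99) {
  stopifnot(inherits(series, "inner_product_series"))
  if (!(lo >= 0 && lo < hi && hi <= 1))
    stop("event thresholds must satisfy 0 <= lo < hi <= 1")
  v <- series$values
  ok <- series$valid
  nv <- cumsum(ok)
  e0 <- cumsum(ok & !is.na(v) & v < lo)
  e1 <- cumsum(ok & !is.na(v) & v > hi)
  data.frame(pair_index = seq_along(v),
             accum_event0 = ifelse(nv > 0, e0 / nv, NA_real_),
             accum_event1 = ifelse(nv > 0, e1 / nv, NA_real_))
}
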