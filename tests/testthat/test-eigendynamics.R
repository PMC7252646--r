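test_that("the prime eigenvector of a clique union is uniform on the largest clique", {
  A <- clique_union(8, list(4:8))
  pe <- prime_eigenvector(A)
  expect_true(pe$valid)
  expect_equal(pe$value, 4)
  expect_equal(pe$vector, uniform_on(8, 4:8), tolerance = 1e-12)

  B <- clique_union(8, list(1:3, 4:8))
  pb <- prime_eigenvector(B)
  expect_equal(pb$vector, uniform_on(8, 4:8), tolerance = 1e-12)

  empty <- matrix(0, 5, 5)
  expect_false(prime_eigenvector(empty)$valid)
  expect_error(prime_eigenvector(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("degenerate top eigenvalues are resolved continuously", {
  # two equal cliques: the top eigenvalue is twofold degenerate
  A <- clique_union(8, list(1:4, 5:8))
  prev <- uniform_on(8, 5:8)
  pe <- prime_eigenvector(A, previous = prev)
  expect_equal(pe$vector, prev, tolerance = 1e-10)
  # identical consecutive adjacency gives an inner product of exactly 1
  pe2 <- prime_eigenvector(A, previous = pe$vector)
  expect_equal(sum(pe$vector * pe2$vector), 1, tolerance = 1e-12)
  # without a previous vector, the support containing the lowest index wins
  pe0 <- prime_eigenvector(A)
  expect_equal(pe0$vector, uniform_on(8, 1:4), tolerance = 1e-10)
})

test_that("successive inner products reflect largest-cluster overlap", {
  n <- 15
  mk <- function(members) {
    pe <- prime_eigenvector(clique_union(n, list(members)))
    pe$vector
  }
  v12 <- mk(4:15)
  v7 <- mk(9:15)
  v8 <- mk(1:8)
  expect_equal(sum(v12 * v12), 1)
  expect_equal(sum(v12 * v7), sqrt(7 / 12), tolerance = 1e-12)
  expect_equal(sum(v7 * v8), 0)
})

test_that("eigenvector series flags edgeless windows and pairs around them", {
  adj <- array(0L, c(4, 4, 3))
  adj[, , 1] <- clique_union(4, list(1:3))
  adj[, , 3] <- clique_union(4, list(2:4))
  nets <- structure(list(adj = adj, threshold = 1, labels = letters[1:4],
                         window_start = 1:3,
                         window = window_spec(2, 1, 1000)),
                    class = "binary_network_series")
  es <- eigenvector_series(nets)
  expect_equal(es$valid, c(TRUE, FALSE, TRUE))
  expect_true(all(is.na(es$vectors[, 2])))
  ips <- successive_inner_products(es)
  expect_equal(ips$valid, c(FALSE, FALSE))
  expect_true(all(is.na(ips$values)))
})

test_that("event counting and accumulation follow the definitions", {
  mk_ips <- function(values) structure(
    list(values = values, valid = !is.na(values),
         window_start = seq_along(values),
         window = window_spec(2, 1, 1000)),
    class = "inner_product_series")

  ev <- count_events(mk_ips(c(1, 1, 1, 0)))
  expect_equal(ev$freq_event1, 0.75)
  expect_equal(ev$freq_event0, 0.25)
  ev_mid <- count_events(mk_ips(rep(0.5, 10)))
  expect_equal(ev_mid$freq_event0, 0)
  expect_equal(ev_mid$freq_event1, 0)
  expect_error(count_events(mk_ips(c(1, 0)), lo = 0.5, hi = 0.5), "lo < hi")

  acc <- accumulated_event_frequency(mk_ips(c(1, 1, 0, 1)))
  expect_equal(acc$accum_event1, c(1, 1, 2 / 3, 3 / 4))
  expect_equal(acc$accum_event0, c(0, 0, 1 / 3, 1 / 4))
  # the final accumulated values equal the overall frequencies
  ev2 <- count_events(mk_ips(c(1, 1, 0, 1)))
  expect_equal(acc$accum_event1[4], ev2$freq_event1)
  expect_equal(acc$accum_event0[4], ev2$freq_event0)
  # saturated series stays at 1
  expect_equal(accumulated_event_frequency(mk_ips(rep(1, 5)))$accum_event1,
               rep(1, 5))
  # counts never exceed the valid denominator
  expect_lte(ev$n_event0 + ev$n_event1, ev$n_valid)
})

test_that("spike detection separates runs by plateaus and reports minima", {
  mk_ips <- function(values) structure(
    list(values = values, valid = !is.na(values),
         window_start = seq_along(values),
         window = window_spec(2, 1, 1000)),
    class = "inner_product_series")

  expect_equal(nrow(detect_spikes(mk_ips(rep(1, 20)))), 0)
  # one dip: a single spike at its minimum
  v <- c(rep(1, 5), 0.98, 0.6, 0.7, rep(1, 5))
  sp <- detect_spikes(mk_ips(v))
  expect_equal(nrow(sp), 1)
  expect_equal(sp$pair_index, 7)
  expect_equal(sp$minimum, 0.6)
  expect_equal(sp$depth, 0.4)
  # two dips separated by a plateau value count as two spikes
  v2 <- c(rep(1, 3), 0.5, rep(1, 3), 0.4, rep(1, 3))
  expect_equal(nrow(detect_spikes(mk_ips(v2))), 2)
  # two dips not separated by a plateau are one spike
  v3 <- c(rep(1, 3), 0.5, 0.97, 0.4, rep(1, 3))
  sp3 <- detect_spikes(mk_ips(v3))
  expect_equal(nrow(sp3), 1)
  expect_equal(sp3$minimum, 0.4)
  # a shallow excursion above spike_level is not a spike
  v4 <- c(rep(1, 3), 0.97, rep(1, 3))
  expect_equal(nrow(detect_spikes(mk_ips(v4))), 0)
  expect_error(detect_spikes(mk_ips(v), plateau_level = 0.5, spike_level = 0.9))
})

test_that("the recurrence matrix has unit diagonal and block structure", {
  vecs <- cbind(uniform_on(6, 1:3), uniform_on(6, 1:3),
                uniform_on(6, 4:6), uniform_on(6, 4:6))
  es <- structure(list(vectors = vecs, values = rep(2, 4),
                       valid = rep(TRUE, 4), labels = letters[1:6],
                       window_start = 1:4,
                       window = window_spec(2, 1, 1000)),
                  class = "eigenvector_series")
  R <- recurrence_matrix(es)
  expect_equal(diag(R), rep(1, 4))
  expect_equal(R, rbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
                        c(0, 0, 1, 1), c(0, 0, 1, 1)))
  expect_error(recurrence_matrix(es, integer()), "empty")
  expect_error(recurrence_matrix(es, 9), "bounds")
})

test_that("state segmentation covers valid windows and finds constant states", {
  vecs <- cbind(uniform_on(6, 1:3), uniform_on(6, 1:3), uniform_on(6, 1:3))
  es <- structure(list(vectors = vecs, values = rep(2, 3),
                       valid = rep(TRUE, 3), labels = letters[1:6],
                       window_start = 1:3,
                       window = window_spec(40, 5, 1000)),
                  class = "eigenvector_series")
  seg <- segment_states(es)
  expect_equal(nrow(seg$states), 1)
  expect_equal(seg$states$start, 1)
  expect_equal(seg$states$end, 3)
  expect_equal(seg$states$duration_s, 3 * 5 / 1000)
  expect_equal(unname(seg$centroids[, 1]), uniform_on(6, 1:3))

  # two states with an orthogonal transition window between them
  vecs2 <- cbind(uniform_on(6, 1:3), uniform_on(6, 1:3),
                 uniform_on(6, c(1, 4, 5)),
                 uniform_on(6, 4:6), uniform_on(6, 4:6))
  es2 <- structure(list(vectors = vecs2, values = rep(2, 5),
                        valid = rep(TRUE, 5), labels = letters[1:6],
                        window_start = 1:5,
                        window = window_spec(40, 5, 1000)),
                   class = "eigenvector_series")
  seg2 <- segment_states(es2)
  expect_equal(nrow(seg2$states), 2)
  expect_equal(seg2$transition_windows, 3L)
  # partition conservation: state durations + transitions = valid windows
  expect_equal(sum(seg2$states$duration_windows) +
                 length(seg2$transition_windows), sum(es2$valid))
})

test_that("scenario 1 dynamics: plateaus dominate and events count correctly", {
  traj <- simulate_phase_network(build_scenario("scenario1"), seed = 2)
  res <- speeds_to_ips(traj$speed)
  ev <- count_events(res$ips)
  expect_gt(ev$freq_event1, 0.9)
  expect_lt(ev$freq_event0, 0.01)
  expect_gt(ev$freq_event1, ev$freq_event0)
  seg <- segment_states(res$eigen)
  expect_equal(nrow(seg$states), 3)
  # segmentation boundaries sit at the scripted changes (window pairs near
  # steps 500 and 1500)
  expect_lt(abs(seg$states$end[1] - 500), 45)
  expect_lt(abs(seg$states$end[2] - 1461), 45)
})
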