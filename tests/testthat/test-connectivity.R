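tone <- function(freq, fs = 1000, n = 6000, phase = 0)
  cos(2 * pi * freq * seq_len(n) / fs + phase)

interior <- function(y) {
  e <- attr(y, "edge_samples")
  y[(e + 1):(nrow(y) - e), , drop = FALSE]
}

test_that("band-pass filter passes in-band tones and rejects out-of-band ones", {
  x <- cbind(in_band = tone(10), out_band = tone(30), dc = rep(1, 6000))
  y <- bandpass_filter(x, c(8, 12), fs = 1000)
  yi <- interior(y)
  amp <- apply(yi, 2, function(ch) (max(ch) - min(ch)) / 2)
  expect_gt(amp["in_band"], 0.95)
  expect_lt(amp["in_band"], 1.05)
  expect_lt(amp["out_band"], 0.01)
  expect_lt(max(abs(yi[, "dc"])), 0.01)
})

test_that("filter configuration errors are caught", {
  x <- matrix(tone(10), ncol = 1)
  expect_error(bandpass_filter(x, c(8, 600), fs = 1000), "Nyquist")
  expect_error(bandpass_filter(x[1:100, , drop = FALSE], c(8, 12), 1000),
               "too short")
})

test_that("analytic-signal phase recovers tone frequency and quadrature lag", {
  x <- cbind(c = tone(10), s = sin(2 * pi * 10 * seq_len(6000) / 1000))
  ph <- instantaneous_phase(x)
  mid <- 1000:5000
  slopes <- apply(ph[mid, ], 2, function(p) mean(diff(p)))
  expect_equal(unname(slopes), rep(2 * pi * 10 / 1000, 2), tolerance = 1e-6)
  # sin lags cos by pi/2
  lag <- ph[mid, "c"] - ph[mid, "s"]
  expect_equal(mean(lag), pi / 2, tolerance = 1e-3)
  # unwrapped phase of a positive-frequency tone is monotone increasing
  expect_true(all(diff(ph[mid, "c"]) > 0))
  expect_warning(instantaneous_phase(cbind(rep(1, 100))), "constant")
})

test_that("angular speed is the first difference and flags unwrapped input", {
  ramp <- cbind(seq(0, by = 0.05, length.out = 100))
  expect_equal(as.vector(angular_speed(ramp)), rep(0.05, 99))
  expect_equal(as.vector(angular_speed(cbind(c(0, 0.1, 0.3)))), c(0.1, 0.2))
  expect_error(angular_speed(cbind(1)), "at least 2")
  wrapped <- cbind(c(0, 3, -3, 3)) # jumps of ~2pi magnitude
  expect_warning(angular_speed(wrapped), "unwrapped")
})

test_that("windowed phasor distance matches its closed forms", {
  width <- 40L
  win <- window_spec(width, 5L, 1000)
  # identical rows give zero distance
  s <- cbind(a = rep(0.05, 200), b = rep(0.05, 200))
  expect_true(all(windowed_plv_distance(s, win)$d == 0))
  # constant gap: d = 2 sin(delta/2) sqrt(width)
  delta <- 2 * pi * 2 / 1000
  s2 <- cbind(a = rep(0.05, 200), b = rep(0.05 + delta, 200))
  d2 <- windowed_plv_distance(s2, win)$d[1, 2, ]
  expect_equal(unique(round(d2, 12)),
               round(oracle_const_gap_distance(delta, width), 12))
  expect_equal(d2[1], 0.07947618, tolerance = 1e-6)
})

test_that("splitting a window splits the squared distance exactly", {
  set.seed(42)
  for (i in 1:50) {
    width <- sample(10:60, 1)
    sa <- stats::runif(width, -0.3, 0.3)
    sb <- stats::runif(width, -0.3, 0.3)
    cut <- sample(2:(width - 2), 1)
    d_full <- windowed_plv_distance(cbind(sa, sb),
                                    window_spec(width, width, 1000))$d[1, 2, 1]
    d_alpha <- windowed_plv_distance(cbind(sa[1:cut], sb[1:cut]),
                                     window_spec(cut, cut, 1000))$d[1, 2, 1]
    d_beta <- windowed_plv_distance(cbind(sa[-(1:cut)], sb[-(1:cut)]),
                                    window_spec(width - cut, width - cut,
                                                1000))$d[1, 2, 1]
    expect_equal(d_full^2, d_alpha^2 + d_beta^2, tolerance = 1e-12)
  }
})

test_that("the phasor distance is a metric on speed rows", {
  set.seed(7)
  win <- window_spec(30, 30, 1000)
  for (i in 1:25) {
    s <- matrix(stats::runif(90, -1, 1), 30, 3)
    d <- windowed_plv_distance(s, win)$d[, , 1]
    expect_true(isSymmetric(d))
    expect_true(all(d >= 0))
    expect_equal(unname(diag(d)), rep(0, 3))
    expect_lte(d[1, 3], d[1, 2] + d[2, 3] + 1e-12)
  }
})

test_that("phasor and raw-speed distances agree to first order for small gaps", {
  set.seed(8)
  s <- matrix(stats::runif(200, -0.025, 0.025), 100, 2)
  win <- window_spec(40, 5, 1000)
  dp <- windowed_plv_distance(s, win, variant = "phasor")$d[1, 2, ]
  dr <- windowed_plv_distance(s, win, variant = "raw")$d[1, 2, ]
  expect_true(all(abs(dp - dr) / pmax(dr, 1e-300) < 1e-3))
})

test_that("window counts follow the closed form for all geometries", {
  for (len in c(40, 55, 100, 997)) {
    for (width in c(2, 10, 40)) {
      for (step in c(1, 3, width)) {
        if (width > len || step > width) next
        expect_length(window_starts(len, window_spec(width, step, 1000)),
                      floor((len - width) / step) + 1)
      }
    }
  }
  expect_error(window_starts(10, window_spec(40, 5, 1000)), "shorter")
})

test_that("phase coherence is 1 for constant lag, ~0 for a full-cycle sweep", {
  win <- window_spec(40, 5, 1000)
  p1 <- cbind(a = seq(0, 10, length.out = 200),
              b = seq(0, 10, length.out = 200) + 1.3)
  expect_equal(unique(round(phase_coherence(p1, win)$coherence[1, 2, ], 12)), 1)
  # phase difference sweeping exactly one cycle across the window
  p2 <- cbind(a = cumsum(rep(0.1, 40)),
              b = cumsum(rep(0.1 + 2 * pi / 40, 40)))
  expect_lt(phase_coherence(p2, window_spec(40, 40, 1000))$coherence[1, 2, 1],
            1e-10)
  set.seed(9)
  pr <- matrix(cumsum(stats::runif(300)), 100, 3)
  expect_true(all(phase_coherence(pr, win)$coherence >= 0 &
                  phase_coherence(pr, win)$coherence <= 1 + 1e-12))
})

test_that("binarization applies a strict threshold with a zero diagonal", {
  s <- cbind(rep(0.05, 100), rep(0.05, 100), rep(0.08, 100))
  d <- windowed_plv_distance(s, window_spec(40, 5, 1000))
  nets <- binarize(d, 4e-4)
  A <- nets$adj[, , 1]
  expect_equal(A, matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3,
                         dimnames = dimnames(A)))
  # threshold below the minimum nonzero distance: only the identical pair
  tiny <- binarize(d, 1e-12)
  expect_equal(sum(tiny$adj), 2 * dim(d$d)[3])
  # ties at exactly the threshold are non-edges
  gap <- d$d[1, 3, 1]
  at_tie <- binarize(d, gap)
  expect_equal(at_tie$adj[1, 3, 1], 0L)
  expect_error(binarize(d, 0), "positive")
})

test_that("the zero-noise signal pipeline recovers planted cliques exactly", {
  sc <- scenario_script(8, 6000, segments = list(
    list(start = 0, end = 6000, oscillators = 1:3, speed = hz_to_rad(9)),
    list(start = 0, end = 6000, oscillators = 4:8, speed = hz_to_rad(11))))
  x <- synth_multichannel_signal(sc, c(8, 12), noise_sd = 0, seed = 3)
  res <- signal_to_networks(x, band = c(6.5, 14), fs = 1000,
                            window = window_spec(40, 5, 1000),
                            threshold = 4e-4, transition = 3)
  W <- dim(res$networks$adj)[3]
  A <- res$networks$adj[, , round(W / 2)]
  expected <- clique_union(8, list(1:3, 4:8))
  dimnames(expected) <- dimnames(A)
  expect_equal(A, expected)
})
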