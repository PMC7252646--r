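#' Zero-phase FIR band-pass filter
#'
#' Filters each channel with a linear-phase Hamming-window FIR band-pass
#' design (order at least `3.3 / (transition / fs)`, rounded up to an even
#' number), applied once by FFT convolution with the group delay removed, so
#' the interior of the output is exactly zero-phase. The first and last
#' `order/2 + ceiling(fs / band[1])` samples are contaminated by the filter
#' start-up transient; their count is returned in the `edge_samples`
#' attribute and downstream window builders exclude them by default.
#'
#' @param x Numeric matrix, samples x channels (a vector is treated as one
#'   channel).
#' @param band Length-2 numeric, pass-band edges in Hz, inside `(0, fs/2)`.
#' @param fs Sampling rate in Hz.
#' @param transition Transition width in Hz used to choose the filter order
#'   (default: half the pass-band width, capped at the lower band edge).
#' @return Filtered matrix of the same shape with attributes `fs`, `band`,
#'   `filter_order` and `edge_samples`.
#' @export
bandpass_filter <- function(x, band, fs, transition = NULL) {
  x <- as.matrix(x)
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
    stop("band must be an increasing pair of positive frequencies")
  if (band[2] >= fs / 2)
    stop("upper band edge must lie below the Nyquist frequency ", fs / 2)
  if (is.null(transition))
    transition <- min((band[2] - band[1]) / 2, band[1])
  order <- ceiling(3.3 * fs / transition)
  if (order %% 2L == 1L) order <- order + 1L
  if (nrow(x) < 3L * order)
    stop("signal length ", nrow(x), " is too short for filter order ", order,
         " (need at least 3x the order)")
  b <- signal::fir1(order, band / (fs / 2), type = "pass")
  delay <- order / 2L
  y <- apply(x, 2, function(ch) {
    out <- signal::fftfilt(b, c(ch, numeric(delay)))
    out[(delay + 1L):(delay + length(ch))]
  })
  dimnames(y) <- dimnames(x)
  attr(y, "fs") <- fs
  attr(y, "band") <- band
  attr(y, "filter_order") <- order
  attr(y, "edge_samples") <- as.integer(delay + ceiling(fs / band[1]))
  y
}

#' Instantaneous phase via the analytic signal
#'
#' Computes the analytic signal of each (narrow-band) channel by zeroing the
#' negative-frequency half of its discrete Fourier transform, and returns
#' the unwrapped phase angle. Attributes of the input (as set by
#' [bandpass_filter()]) are carried through.
#'
#' @param x Numeric matrix, samples x channels.
#' @return Matrix of unwrapped phases in radians, same shape as `x`.
#' @export
instantaneous_phase <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 samples")
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  ph <- apply(x, 2, function(ch) {
    if (stats::sd(ch) == 0)
      warning("constant channel: instantaneous phase is degenerate")
    z <- stats::fft(h * stats::fft(ch), inverse = TRUE) / n
    unwrap_phase(Arg(z))
  })
  dimnames(ph) <- dimnames(x)
  for (a in c("fs", "band", "filter_order", "edge_samples"))
    attr(ph, a) <- attr(x, a)
  ph
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1L], d))
}

#' Instantaneous angular speed
#'
#' First difference of the unwrapped phase along time; the output has one
#' row fewer than the input. Any speed of magnitude above pi indicates a
#' phase-unwrapping failure and triggers a warning.
#'
#' @param phase Matrix of unwrapped phases, samples x channels.
#' @return Matrix of angular speeds in rad/sample.
#' @export
angular_speed <- function(phase) {
  phase <- as.matrix(phase)
  if (nrow(phase) < 2L) stop("need at least 2 phase samples to differentiate")
  v <- diff(phase)
  if (any(abs(v) > pi, na.rm = TRUE))
    warning("angular speed exceeds pi rad/sample; was the phase unwrapped?")
  for (a in c("fs", "band", "filter_order", "edge_samples"))
    attr(v, a) <- attr(phase, a)
  v
}

#' Windowed phase-locking distance between channels
#'
#' For each sliding window and each channel pair, computes the Euclidean
#' (2-norm) distance between the complex unit-phasor row vectors of the two
#' channels' angular speeds,
#' \deqn{d_{mn} = \lVert (e^{i\dot\phi_{m,t}})_t - (e^{i\dot\phi_{n,t}})_t
#'   \rVert_2 = \sqrt{\sum_t 4 \sin^2((\dot\phi_{m,t}-\dot\phi_{n,t})/2)}.}
#' A small distance means the two channels kept nearly equal angular speeds
#' across the window, i.e. they are phase-locked. `variant = "raw"` uses
#' the plain speed difference instead of the phasor difference; the two
#' agree to first order for small speed gaps.
#'
#' @param speeds Matrix of angular speeds, samples x channels.
#' @param window A [window_spec()].
#' @param exclude_edges Drop windows overlapping filter edge transients
#'   (uses the `edge_samples` attribute when present). Default `TRUE`.
#' @param variant `"phasor"` (default) or `"raw"`.
#' @return An object of class `plv_distance_series`: list with `d`
#'   (channels x channels x windows array), `window_start` (1-based sample
#'   index of each window into the full speed series), `labels`, `window`.
#' @export
windowed_plv_distance <- function(speeds, window = window_spec(),
                                  exclude_edges = TRUE,
                                  variant = c("phasor", "raw")) {
  variant <- match.arg(variant)
  speeds <- as.matrix(speeds)
  if (any(!is.finite(speeds))) stop("angular speeds must be finite")
  n <- ncol(speeds)
  labels <- colnames(speeds)
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(n))

  margin <- 0L
  if (exclude_edges && !is.null(attr(speeds, "edge_samples")))
    margin <- attr(speeds, "edge_samples")
  keep <- if (margin > 0L) {
    if (nrow(speeds) <= 2L * margin)
      stop("series too short once filter edge transients are excluded")
    (margin + 1L):(nrow(speeds) - margin)
  } else seq_len(nrow(speeds))

  starts <- window_starts(length(keep), window)
  W <- length(starts)
  d <- array(0, dim = c(n, n, W), dimnames = list(labels, labels, NULL))
  s <- speeds[keep, , drop = FALSE]
  for (m in seq_len(n - 1L)) {
    for (k in (m + 1L):n) {
      gap <- s[, m] - s[, k]
      sq <- if (variant == "phasor") 4 * sin(gap / 2)^2 else gap^2
      cs <- c(0, cumsum(sq))
      w2 <- sqrt(pmax(cs[starts + window$width] - cs[starts], 0))
      d[m, k, ] <- w2
      d[k, m, ] <- w2
    }
  }
  structure(list(d = d, window_start = keep[1L] - 1L + starts,
                 labels = labels, window = window, variant = variant),
            class = "plv_distance_series")
}

#' @export
print.plv_distance_series <- function(x, ...) {
  cat("PLV distance series:", dim(x$d)[1], "channels,",
      dim(x$d)[3], "windows (", x$variant, "variant )\n")
  invisible(x)
}

#' Classical phase coherence per sliding window
#'
#' The modulus of the time-averaged complex phasor of the phase difference,
#' \eqn{\mathrm{PLV}_{mn} = \frac{1}{T}\left|\sum_t
#' e^{i(\phi_{m,t}-\phi_{n,t})}\right|}, in `[0, 1]`; 1 means a perfectly
#' constant phase difference across the window. Provided for comparison
#' with the angular-speed distance.
#'
#' @param phases Matrix of phases, samples x channels.
#' @param window A [window_spec()].
#' @param exclude_edges As in [windowed_plv_distance()].
#' @return List with `coherence` (channels x channels x windows, diagonal
#'   1), `window_start`, `labels`, `window`.
#' @export
phase_coherence <- function(phases, window = window_spec(),
                            exclude_edges = TRUE) {
  phases <- as.matrix(phases)
  n <- ncol(phases)
  labels <- colnames(phases)
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(n))
  margin <- 0L
  if (exclude_edges && !is.null(attr(phases, "edge_samples")))
    margin <- attr(phases, "edge_samples")
  keep <- if (margin > 0L) {
    if (nrow(phases) <= 2L * margin)
      stop("series too short once filter edge transients are excluded")
    (margin + 1L):(nrow(phases) - margin)
  } else seq_len(nrow(phases))
  starts <- window_starts(length(keep), window)
  W <- length(starts)
  coh <- array(1, dim = c(n, n, W), dimnames = list(labels, labels, NULL))
  p <- phases[keep, , drop = FALSE]
  for (m in seq_len(n - 1L)) {
    for (k in (m + 1L):n) {
      z <- exp(1i * (p[, m] - p[, k]))
      cs <- c(0, cumsum(z))
      v <- Mod(cs[starts + window$width] - cs[starts]) / window$width
      coh[m, k, ] <- v
      coh[k, m, ] <- v
    }
  }
  list(coherence = coh, window_start = keep[1L] - 1L + starts,
       labels = labels, window = window)
}

#' Binarize a distance series into phase-locking networks
#'
#' An edge joins channels `m` and `n` in a window iff their windowed
#' phase-locking distance is strictly below the threshold; ties at exactly
#' the threshold are non-edges. The canonical threshold for 1 kHz EEG
#' analysis with a 40-sample window is `4e-4`.
#'
#' @param distances A `plv_distance_series`.
#' @param threshold Positive distance threshold.
#' @return An object of class `binary_network_series`: list with `adj`
#'   (channels x channels x windows 0/1 array, zero diagonal), `threshold`,
#'   `labels`, `window_start`, `window`.
#' @export
binarize <- function(distances, threshold = 4e-4) {
  stopifnot(inherits(distances, "plv_distance_series"))
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be a positive number")
  adj <- (distances$d < threshold) * 1L
  n <- dim(adj)[1]
  for (w in seq_len(dim(adj)[3]))
    adj[cbind(seq_len(n), seq_len(n), w)] <- 0L
  structure(list(adj = adj, threshold = threshold,
                 labels = distances$labels,
                 window_start = distances$window_start,
                 window = distances$window),
            class = "binary_network_series")
}

#' @export
print.binary_network_series <- function(x, ...) {
  cat("Binary phase-locking network series:", dim(x$adj)[1], "channels,",
      dim(x$adj)[3], "windows, threshold", format(x$threshold), "\n")
  invisible(x)
}

#' Full connectivity pipeline: signal to binary network series
#'
#' Convenience wrapper chaining [bandpass_filter()],
#' [instantaneous_phase()], [angular_speed()], [windowed_plv_distance()]
#' and [binarize()]. Pass `band = NULL` to skip filtering (e.g. for
#' simulated speeds already available as narrow-band phases).
#'
#' @param x Signal matrix, samples x channels.
#' @param band Pass-band in Hz or `NULL`.
#' @param fs Sampling rate in Hz.
#' @param window A [window_spec()].
#' @param threshold Binarization threshold.
#' @param transition Filter transition width in Hz (see [bandpass_filter()]).
#' @param exclude_edges Drop filter-edge-contaminated windows.
#' @return A list with elements `distances` (`plv_distance_series`) and
#'   `networks` (`binary_network_series`).
#' @export
signal_to_networks <- function(x, band, fs, window = window_spec(fs = fs),
                               threshold = 4e-4, transition = NULL,
                               exclude_edges = TRUE) {
  y <- if (is.null(band)) as.matrix(x) else bandpass_filter(x, band, fs, transition)
  ph <- instantaneous_phase(y)
  sp <- angular_speed(ph)
  d <- windowed_plv_distance(sp, window, exclude_edges = exclude_edges)
  list(distances = d, networks = binarize(d, threshold))
}
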