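#' Sliding-window specification
#'
#' Window width and step are stored in samples; the convenience arguments
#' `width_ms`/`step_ms` convert from milliseconds using `fs`. The canonical
#' analysis window is 40 ms wide with a 5 ms step at 1 kHz (40 and 5
#' samples); the simulation scenarios use a step of 1 sample.
#'
#' @param width Window width in samples (>= 2).
#' @param step Step between window starts in samples (1 <= step <= width).
#' @param fs Sampling rate in Hz.
#' @param width_ms,step_ms Alternative specification in milliseconds;
#'   overrides `width`/`step` when given.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(width = 40L, step = 5L, fs = 1000,
                        width_ms = NULL, step_ms = NULL) {
  if (!is.null(width_ms)) width <- round(width_ms * fs / 1000)
  if (!is.null(step_ms)) step <- round(step_ms * fs / 1000)
  width <- as.integer(width); step <- as.integer(step)
  if (width < 2L) stop("window width must be at least 2 samples")
  if (step < 1L || step > width)
    stop("window step must satisfy 1 <= step <= width")
  structure(list(width = width, step = step, fs = fs), class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat("Sliding window: width", x$width, "samples, step", x$step,
      "samples at", x$fs, "Hz\n")
  invisible(x)
}

#' Start indices of sliding windows over a series of given length
#'
#' The number of windows is `floor((n - width) / step) + 1`.
#'
#' @param n Series length in samples.
#' @param window A [window_spec()].
#' @return Integer vector of 1-based start indices; errors if no window fits.
#' @export
window_starts <- function(n, window) {
  if (n < window$width)
    stop("series of length ", n, " is shorter than the window width ",
         window$width)
  seq.int(1L, n - window$width + 1L, by = window$step)
}
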