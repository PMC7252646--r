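#' Convert an oscillation frequency in Hz to an angular speed in rad/step
#'
#' @param hz Frequency in Hz.
#' @param fs Sampling rate in Hz (steps per second). Defaults to 1000, i.e.
#'   one step per millisecond.
#' @return Angular speed in radians per time step.
#' @export
hz_to_rad <- function(hz, fs = 1000) 2 * pi * hz / fs

#' Scripted angular-speed scenario for a phase-locking oscillator network
#'
#' A scenario script defines, for a set of phase oscillators, piecewise
#' constant angular-speed targets (segments) and, optionally, a pairwise
#' coupling schedule that applies wherever an oscillator is not covered by a
#' segment. Oscillators sharing the same target speed over an interval form a
#' phase-locked cluster; editing the segment layout scripts merges and splits
#' of clusters at exact time steps.
#'
#' @param n_oscillators Number of oscillators.
#' @param duration Number of time steps simulated.
#' @param segments List of segments, each a list with fields `start` and
#'   `end` (0-based step interval `[start, end)`), `oscillators` (integer
#'   indices) and `speed` (rad/step).
#' @param coupling Optional list of coupling records, each a list with
#'   `start`, `end`, `m`, `n` and `strength` (the dimensionless phase-locking
#'   strength between oscillators `m` and `n`).
#' @param step_s Duration of one step in seconds (default 1 ms, mimicking a
#'   1 kHz sampling rate).
#' @return An object of class `scenario_script`.
#' @export
scenario_script <- function(n_oscillators, duration, segments = list(),
                            coupling = list(), step_s = 0.001) {
  script <- structure(
    list(n_oscillators = as.integer(n_oscillators),
         duration = as.integer(duration),
         segments = segments,
         coupling = coupling,
         step_s = step_s),
    class = "scenario_script")
  validate_scenario_script(script)
  script
}

#' Validate a scenario script
#'
#' Checks that segments have finite speeds, lie inside `[0, duration)`, and
#' do not overlap for any oscillator. Gaps are allowed: steps not covered by
#' a segment evolve freely under the coupling schedule.
#'
#' @param script A `scenario_script`.
#' @return The script, invisibly; errors on an invalid script.
#' @export
validate_scenario_script <- function(script) {
  stopifnot(inherits(script, "scenario_script"))
  n <- script$n_oscillators
  if (n < 1L || script$duration < 1L)
    stop("scenario script needs at least one oscillator and one step")
  cover <- vector("list", n)
  for (seg in script$segments) {
    if (!all(c("start", "end", "oscillators", "speed") %in% names(seg)))
      stop("segment missing one of: start, end, oscillators, speed")
    if (!is.finite(seg$speed)) stop("segment angular speed must be finite")
    if (seg$start < 0 || seg$end > script$duration || seg$start >= seg$end)
      stop("segment interval [", seg$start, ", ", seg$end,
           ") outside [0, duration) or empty")
    if (any(seg$oscillators < 1L) || any(seg$oscillators > n))
      stop("segment oscillator index out of range")
    for (m in seg$oscillators) {
      for (iv in cover[[m]]) {
        if (seg$start < iv[2] && iv[1] < seg$end)
          stop("overlapping segments for oscillator ", m)
      }
      cover[[m]] <- c(cover[[m]], list(c(seg$start, seg$end)))
    }
  }
  for (cp in script$coupling) {
    if (!all(c("start", "end", "m", "n", "strength") %in% names(cp)))
      stop("coupling record missing one of: start, end, m, n, strength")
    if (cp$m == cp$n) stop("coupling requires two distinct oscillators")
    if (!is.finite(cp$strength)) stop("coupling strength must be finite")
  }
  invisible(script)
}

#' @export
print.scenario_script <- function(x, ...) {
  cat("Scenario script:", x$n_oscillators, "oscillators,",
      x$duration, "steps (", x$duration * x$step_s, "s )\n")
  cat("  ", length(x$segments), "scripted segments,",
      length(x$coupling), "coupling records\n")
  invisible(x)
}

#' Cluster labels implied by a script at a given step
#'
#' Oscillators covered by a segment at `step` and sharing the same target
#' speed are assigned the same cluster label; uncovered oscillators get
#' singleton labels.
#'
#' @param script A `scenario_script`.
#' @param step 0-based time step.
#' @return Integer vector of cluster labels, one per oscillator.
#' @export
cluster_labels <- function(script, step) {
  speeds <- rep(NA_real_, script$n_oscillators)
  for (seg in script$segments) {
    if (step >= seg$start && step < seg$end) speeds[seg$oscillators] <- seg$speed
  }
  # uncovered oscillators are singletons: tag them with unique keys
  keys <- ifelse(is.na(speeds), paste0("free", seq_along(speeds)),
                 format(speeds, digits = 15))
  match(keys, unique(keys))
}

seg <- function(start, end, oscillators, hz, fs = 1000)
  list(start = start, end = end, oscillators = oscillators,
       speed = hz_to_rad(hz, fs))

#' Build one of the validation scenarios
#'
#' Three scripted scenarios exercise the eigenvector-based pipeline:
#'
#' * `"scenario1"`: 8 oscillators in two clusters (3 at 3 Hz, 5 at 5 Hz)
#'   that merge at step 500 (joint speed 4 Hz) and separate again at step
#'   1500; 2000 steps.
#' * `"scenario2"`: 15 oscillators in three clusters of sizes 3 (3 Hz), 5
#'   and 7 (jointly 5 Hz). At step 1000 the 5-cluster leaves the 7-cluster
#'   and joins the 3-cluster; 2000 steps.
#' * `"benchmark"`: 27 oscillators in four clusters of sizes 3 (3 Hz), 5
#'   (4 Hz), 9 (5 Hz) and 10 (7 Hz). At step 500 clusters 1+2 and 3+4 merge
#'   pairwise; at step 1000 cluster 3 leaves cluster 4 and joins clusters
#'   1+2; at step 1500 clusters 2+3 leave cluster 1 and merge with cluster
#'   4; 2500 steps.
#'
#' Joint speeds after a merge are not uniquely determined by the cluster
#' layout (the analysis depends only on which oscillators share a speed);
#' this builder uses 4 Hz for the scenario-1 merge and 3.5 / 6 Hz for the
#' benchmark super-clusters. Cluster changes are instantaneous step changes
#' in target speed. Builders are pure: the same name always returns an
#' identical script.
#'
#' @param name One of `"scenario1"`, `"scenario2"`, `"benchmark"`.
#' @return A `scenario_script`.
#' @export
build_scenario <- function(name = c("scenario1", "scenario2", "benchmark")) {
  name <- match.arg(name)
  if (name == "scenario1") {
    c1 <- 1:3; c2 <- 4:8
    scenario_script(8L, 2000L, segments = list(
      seg(0, 500, c1, 3), seg(0, 500, c2, 5),
      seg(500, 1500, c(c1, c2), 4),
      seg(1500, 2000, c1, 3), seg(1500, 2000, c2, 5)))
  } else if (name == "scenario2") {
    c1 <- 1:3; c2 <- 4:8; c3 <- 9:15
    scenario_script(15L, 2000L, segments = list(
      seg(0, 2000, c1, 3),
      seg(0, 1000, c2, 5), seg(1000, 2000, c2, 3),
      seg(0, 2000, c3, 5)))
  } else {
    c1 <- 1:3; c2 <- 4:8; c3 <- 9:17; c4 <- 18:27
    scenario_script(27L, 2500L, segments = list(
      seg(0, 500, c1, 3), seg(0, 500, c2, 4),
      seg(0, 500, c3, 5), seg(0, 500, c4, 7),
      seg(500, 2500, c1, 3.5),
      seg(500, 1500, c2, 3.5), seg(1500, 2500, c2, 6),
      seg(500, 1000, c3, 6), seg(1000, 1500, c3, 3.5), seg(1500, 2500, c3, 6),
      seg(500, 2500, c4, 6)))
  }
}

#' Write a scenario script to a YAML config file
#'
#' @param script A `scenario_script`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_script <- function(script, path) {
  yaml::write_yaml(list(
    n_oscillators = script$n_oscillators,
    duration = script$duration,
    step_s = script$step_s,
    segments = lapply(script$segments, function(s)
      list(start = s$start, end = s$end,
           oscillators = as.integer(s$oscillators), speed = s$speed)),
    coupling = script$coupling), path, precision = 15)
  invisible(path)
}

#' Read a scenario script from a YAML config file
#'
#' @param path Path to a file written by [write_scenario_script()].
#' @return A `scenario_script`.
#' @export
read_scenario_script <- function(path) {
  cfg <- yaml::read_yaml(path)
  scenario_script(cfg$n_oscillators, cfg$duration,
                  segments = cfg$segments,
                  coupling = if (is.null(cfg$coupling)) list() else cfg$coupling,
                  step_s = if (is.null(cfg$step_s)) 0.001 else cfg$step_s)
}
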