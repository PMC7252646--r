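Package: eigendyn
Title: Eigenvector-Based Dynamical Analysis of Phase-Locking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the meta-stable state dynamics of
    phase-locking functional connectivity in multichannel oscillatory
    signals such as EEG. Signals are band-pass filtered, instantaneous
    phases are extracted with the analytic signal, and a sliding-window
    phase-locking value based on the Euclidean distance between angular
    speed phasor vectors is thresholded into a time series of binary
    networks. The prime (leading) eigenvector of each network tracks the
    largest synchronized cluster; inner products of successive
    eigenvectors segment the dynamics into meta-stable states separated
    by transition spikes. Includes a scripted phase-oscillator network
    simulator with validation scenarios, static topology metrics with
    matched-density random-network nulls, hierarchical and modularity
    clustering baselines with temporal cluster tracking, and paired
    Wilcoxon signed-rank comparisons of condition-level summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
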