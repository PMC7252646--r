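#' Read a multichannel signal from delimited text
#'
#' Expects one row per channel: the first column holds the channel label,
#' the remaining columns the samples (channels x samples on disk).
#'
#' @param path Input file.
#' @param sep Field separator (default tab).
#' @param fs Optional sampling rate stored in the `fs` attribute.
#' @return Numeric matrix, samples x channels, with channel names.
#' @export
read_signals <- function(path, sep = "\t", fs = NULL) {
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           stringsAsFactors = FALSE)
  labels <- as.character(raw[[1L]])
  x <- t(as.matrix(raw[, -1L, drop = FALSE]))
  dimnames(x) <- list(NULL, labels)
  if (!is.null(fs)) attr(x, "fs") <- fs
  x
}

#' Write a multichannel signal as delimited text
#'
#' Inverse of [read_signals()]: one row per channel, label first.
#'
#' @param x Matrix, samples x channels.
#' @param path Output file.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_signals <- function(x, path, sep = "\t") {
  labels <- colnames(x)
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(ncol(x)))
  utils::write.table(cbind(labels, t(x)), path, sep = sep,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write phase trajectories as delimited text
#'
#' Writes two files, `<stem>_phase.tsv` and `<stem>_speed.tsv`, one row per
#' step and one column per oscillator.
#'
#' @param traj A `phase_trajectories` object.
#' @param stem Output path stem.
#' @return Character vector of the two paths, invisibly.
#' @export
write_trajectories <- function(traj, stem) {
  paths <- paste0(stem, c("_phase.tsv", "_speed.tsv"))
  utils::write.table(traj$phase, paths[1], sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(traj$speed, paths[2], sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(paths)
}

edge_long_form <- function(arr, window_start, labels, value_name = NULL) {
  n <- dim(arr)[1]
  W <- dim(arr)[3]
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  rows <- lapply(seq_len(W), function(w) {
    vals <- arr[, , w][upper.tri(arr[, , w])]
    keep <- if (is.null(value_name)) vals != 0 else rep(TRUE, length(vals))
    if (!any(keep)) return(NULL)
    df <- data.frame(window_index = w, window_start = window_start[w],
                     channel_i = labels[ut[keep, 1]],
                     channel_j = labels[ut[keep, 2]])
    if (!is.null(value_name)) df[[value_name]] <- vals[keep]
    df
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Write a binary network series in long form
#'
#' One row per present edge: `window_index`, `window_start`, `channel_i`,
#' `channel_j`.
#'
#' @param networks A `binary_network_series`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_series <- function(networks, path) {
  df <- edge_long_form(networks$adj, networks$window_start, networks$labels)
  if (is.null(df))
    df <- data.frame(window_index = integer(), window_start = integer(),
                     channel_i = character(), channel_j = character())
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a distance series in long form
#'
#' One row per channel pair and window, with a `distance` column.
#'
#' @param distances A `plv_distance_series`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_distance_series <- function(distances, path) {
  df <- edge_long_form(distances$d, distances$window_start,
                       distances$labels, value_name = "distance")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an eigenvector series as delimited text
#'
#' One row per window: `window_index`, `window_start`, `valid`,
#' `eigenvalue`, then one column per channel entry.
#'
#' @param series An `eigenvector_series`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_eigenvector_series <- function(series, path) {
  df <- data.frame(window_index = seq_len(ncol(series$vectors)),
                   window_start = series$window_start,
                   valid = series$valid,
                   eigenvalue = series$values,
                   t(series$vectors))
  names(df)[-(1:4)] <- series$labels
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an inner-product series as delimited text
#'
#' @param series An `inner_product_series`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_inner_product_series <- function(series, path) {
  df <- data.frame(pair_index = seq_along(series$values),
                   window_start = series$window_start,
                   valid = series$valid,
                   inner_product = series$values)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a state segmentation as interval records
#'
#' @param segmentation A `state_segmentation`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(segmentation, path) {
  utils::write.table(segmentation$states, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cluster timeline as a dense integer grid
#'
#' One row per window, one column per oscillator.
#'
#' @param timeline A `cluster_timeline` matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_timeline <- function(timeline, path) {
  utils::write.table(unclass(timeline), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a recurrence-probability network as an edge list
#'
#' One row per channel pair: `channel_i`, `channel_j`, `probability`.
#'
#' @param network An `edge_probability_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edge_probabilities <- function(network, path) {
  n <- nrow(network$probability)
  ut <- which(upper.tri(network$probability), arr.ind = TRUE)
  df <- data.frame(channel_i = network$labels[ut[, 1]],
                   channel_j = network$labels[ut[, 2]],
                   probability = network$probability[ut])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
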