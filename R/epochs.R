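#' Epoch set container
#'
#' Fixed-length multichannel epochs from one subject: a 3-D array
#' `epochs x nodes x samples` (microvolts) together with the sampling rate and
#' node labels. All pipeline stages consume and return this container.
#'
#' @param data numeric array `epochs x nodes x samples`, or a `nodes x samples`
#'   matrix for a single epoch.
#' @param fs sampling rate in Hz.
#' @param node_labels character vector of node names; defaults to
#'   `node_001 ...`.
#' @param epoch_seconds epoch duration in seconds; inferred from `data` and
#'   `fs` when missing.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, node_labels = NULL, epoch_seconds = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(1L, nrow(data), ncol(data)))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive sampling rate in Hz")
  }
  n_nodes <- dim(data)[2L]
  n_samples <- dim(data)[3L]
  if (is.null(epoch_seconds)) epoch_seconds <- n_samples / fs
  if (abs(n_samples - fs * epoch_seconds) > 1e-8) {
    stop("samples per epoch must equal fs * epoch_seconds")
  }
  if (is.null(node_labels)) {
    node_labels <- sprintf("node_%03d", seq_len(n_nodes))
  }
  if (length(node_labels) != n_nodes) {
    stop("`node_labels` length must match the node dimension")
  }
  structure(
    list(data = data, fs = fs, node_labels = as.character(node_labels),
         epoch_seconds = epoch_seconds),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epoch(s) x %d node(s) x %d samples @ %g Hz (%g s)\n",
              d[1L], d[2L], d[3L], x$fs, x$epoch_seconds))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

n_epochs <- function(x) dim(x$data)[1L]

# subset epochs, preserving metadata
keep_epochs <- function(x, idx) {
  epoch_set(x$data[idx, , , drop = FALSE], fs = x$fs,
            node_labels = x$node_labels, epoch_seconds = x$epoch_seconds)
}

#' Segment a continuous recording into fixed-length epochs
#'
#' Cuts a continuous multichannel recording into non-overlapping epochs of
#' `epoch_seconds`, in temporal order; any trailing remainder shorter than one
#' epoch is discarded.
#'
#' @param continuous numeric matrix `nodes x samples` (microvolts).
#' @param fs sampling rate in Hz.
#' @param epoch_seconds epoch length in seconds (default 2).
#' @param node_labels optional node names.
#' @return an [epoch_set].
#' @export
segment_epochs <- function(continuous, fs, epoch_seconds = 2,
                           node_labels = NULL) {
  stopifnot(is.matrix(continuous), fs > 0, epoch_seconds > 0)
  len <- as.integer(round(fs * epoch_seconds))
  n_total <- ncol(continuous)
  n_ep <- n_total %/% len
  if (n_ep < 1L) {
    stop(sprintf("recording (%d samples) shorter than one epoch (%d samples)",
                 n_total, len))
  }
  n_nodes <- nrow(continuous)
  out <- array(0, dim = c(n_ep, n_nodes, len))
  for (e in seq_len(n_ep)) {
    out[e, , ] <- continuous[, ((e - 1L) * len + 1L):(e * len), drop = FALSE]
  }
  epoch_set(out, fs = fs, node_labels = node_labels %||% rownames(continuous),
            epoch_seconds = epoch_seconds)
}
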