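#' Canonical frequency-band table
#'
#' The eleven frequency bands used throughout the pipeline. Band-pass
#' decomposition, PLV connectivity and graph features are computed once per
#' band; the classification feature vector concatenates bands in this order.
#'
#' @return a data.frame with columns `name`, `low`, `high` (Hz); 11 rows.
#' @export
#' @examples
#' band_table()
band_table <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "alpha1", "alpha2",
             "beta", "beta1", "beta2", "beta3", "beta4", "gamma"),
    low  = c(1, 4, 8, 8, 10, 12, 12, 18, 22, 18, 30),
    high = c(4, 8, 12, 10, 12, 30, 18, 22, 30, 30, 55),
    stringsAsFactors = FALSE
  )
}

band_lookup <- function(band) {
  tab <- band_table()
  if (is.character(band)) {
    row <- tab[tab$name == band, , drop = FALSE]
    if (nrow(row) != 1L) stop(sprintf("unknown band '%s'", band))
    return(row)
  }
  stopifnot(is.list(band), !is.null(band$low), !is.null(band$high))
  if (!(band$low > 0 && band$low < band$high)) {
    stop("band must satisfy 0 < low < high")
  }
  data.frame(name = band$name %||% sprintf("%g-%gHz", band$low, band$high),
             low = band$low, high = band$high, stringsAsFactors = FALSE)
}

# Squared magnitude response of an analog 4th-order Butterworth band-pass at
# frequencies f (Hz). Forward-backward (zero-phase) filtering applies |H|^2.
butter_bp_mag2 <- function(f, low, high, order = 4L) {
  w <- 2 * pi * f
  w02 <- (2 * pi * low) * (2 * pi * high)
  bw <- 2 * pi * (high - low)
  # lowpass-prototype frequency of the bandpass transform; 0/0 at w = 0
  u <- ifelse(w == 0, Inf, (w^2 - w02) / (bw * w))
  1 / (1 + u^(2L * order))
}

#' Zero-phase band-pass decomposition
#'
#' Filters every node of every epoch with a zero-phase 4th-order Butterworth
#' band-pass: the squared Butterworth magnitude response (the net response of
#' one forward and one backward pass) is applied in the frequency domain after
#' mirror-padding each epoch, so the operation is linear, phase-free and
#' vectorised across nodes.
#'
#' @param epochs an [epoch_set].
#' @param band a band name from [band_table()] or a list with `low`/`high` Hz.
#' @return an [epoch_set] of the same shape, band-limited.
#' @export
bandpass <- function(epochs, band) {
  stopifnot(inherits(epochs, "epoch_set"))
  b <- band_lookup(band)
  if (b$high >= epochs$fs / 2) {
    stop(sprintf("band '%s' upper edge %g Hz is at or above Nyquist (%g Hz)",
                 b$name, b$high, epochs$fs / 2))
  }
  d <- dim(epochs$data)
  ns <- d[3L]
  # even (mirror) extension: [x, rev(x)] is circularly continuous, so the
  # periodic FFT filter sees no boundary jumps
  idx_pad <- c(seq_len(ns), rev(seq_len(ns)))
  np <- 2L * ns
  freqs <- c(seq(0, floor(np / 2)), -seq(ceiling(np / 2 - 1), 1)) *
    (epochs$fs / np)
  h2 <- butter_bp_mag2(abs(freqs), b$low, b$high)
  # all (epoch, node) series as columns of one matrix; FFT in memory chunks
  M <- matrix(aperm(epochs$data, c(3L, 2L, 1L)), nrow = ns)[idx_pad, ,
                                                            drop = FALSE]
  out <- matrix(0, ns, ncol(M))
  chunk <- max(1L, floor(8e6 / np))
  for (s in seq(1L, ncol(M), by = chunk)) {
    cols <- s:min(ncol(M), s + chunk - 1L)
    xf <- stats::mvfft(M[, cols, drop = FALSE]) * h2
    y <- Re(stats::mvfft(xf, inverse = TRUE)) / np
    out[, cols] <- y[seq_len(ns), , drop = FALSE]
  }
  res <- aperm(array(out, dim = c(ns, d[2L], d[1L])), c(3L, 2L, 1L))
  epoch_set(res, fs = epochs$fs, node_labels = epochs$node_labels,
            epoch_seconds = epochs$epoch_seconds)
}
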