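#' Reject epochs by peak amplitude
#'
#' Removes every epoch containing a sample whose absolute amplitude strictly
#' exceeds `limit` at any node. A sample exactly at the limit is kept: the
#' rule is "exceeding", not "reaching".
#'
#' @param epochs an [epoch_set].
#' @param limit rejection limit in microvolts (default 100).
#' @return the surviving [epoch_set], with attribute `kept` — a logical mask
#'   over the input epochs (TRUE = kept).
#' @export
reject_amplitude <- function(epochs, limit = 100) {
  stopifnot(inherits(epochs, "epoch_set"), limit > 0)
  d <- dim(epochs$data)
  peak <- apply(abs(epochs$data), 1L, max)
  kept <- peak <= limit
  if (!any(kept)) warning("amplitude rejection removed every epoch")
  out <- keep_epochs(epochs, which(kept))
  attr(out, "kept") <- kept
  out
}

#' One-sided periodogram power spectral density
#'
#' Raw (untapered) periodogram of one epoch, per node, on the one-sided DFT
#' frequency grid. Scaling is density per Hz: summing `power * df` over the
#' grid recovers the mean squared amplitude (Parseval).
#'
#' @param epoch numeric matrix `nodes x samples`, or a vector for one node.
#' @param fs sampling rate in Hz.
#' @return list with `freq` (Hz) and `power` (`nodes x n_freq` matrix, uV^2/Hz).
#' @export
psd_periodogram <- function(epoch, fs) {
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1L)
  stopifnot(is.matrix(epoch), ncol(epoch) >= 2L, fs > 0)
  n <- ncol(epoch)
  xf <- stats::mvfft(t(epoch))                    # n x nodes
  p2 <- (Mod(xf)^2) / (fs * n)                    # two-sided density
  n_keep <- floor(n / 2) + 1L
  p1 <- p2[seq_len(n_keep), , drop = FALSE]
  # fold negative frequencies onto positive ones (not DC; not Nyquist if even n)
  dbl <- seq_len(n_keep) > 1L & (n %% 2L == 1L | seq_len(n_keep) < n_keep)
  p1[dbl, ] <- 2 * p1[dbl, ]
  list(freq = (seq_len(n_keep) - 1L) * fs / n, power = t(p1))
}

# Integrated band power (rectangle rule over bins strictly inside the edges),
# averaged over nodes. Returns a scalar per epoch matrix.
band_power <- function(psd, low, high) {
  sel <- psd$freq > low & psd$freq < high
  df <- psd$freq[2L] - psd$freq[1L]
  mean(rowSums(psd$power[, sel, drop = FALSE]) * df)
}

#' Reject epochs by theta/alpha power ratio
#'
#' Computes, for each epoch, the ratio of theta-band (4-8 Hz) to alpha-band
#' (8-12 Hz) power — integrated from the periodogram and averaged over nodes —
#' and removes epochs whose ratio strictly exceeds `threshold`. Epochs with
#' zero alpha power have an undefined ratio and are removed with a warning.
#'
#' @param epochs an [epoch_set].
#' @param threshold ratio threshold (default 1).
#' @return surviving [epoch_set] with attribute `kept` (logical mask) and
#'   attribute `ratio` (the per-epoch ratios; NaN where alpha power was zero).
#' @export
reject_theta_alpha <- function(epochs, threshold = 1) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$fs / 2 <= 12) stop("sampling rate too low to resolve the alpha band")
  d <- dim(epochs$data)
  ns <- d[3L]
  # periodogram of every (epoch, node) series in one batched FFT
  M <- matrix(aperm(epochs$data, c(3L, 2L, 1L)), nrow = ns)
  freq <- (seq_len(ns) - 1L) * epochs$fs / ns
  in_band <- function(lo, hi) freq > lo & freq < hi & freq <= epochs$fs / 2
  th_sel <- in_band(4, 8); al_sel <- in_band(8, 12)
  pw_th <- numeric(ncol(M)); pw_al <- numeric(ncol(M))
  chunk <- max(1L, floor(8e6 / ns))
  for (s in seq(1L, ncol(M), by = chunk)) {
    cols <- s:min(ncol(M), s + chunk - 1L)
    p2 <- Mod(stats::mvfft(M[, cols, drop = FALSE]))^2 / (epochs$fs * ns)
    pw_th[cols] <- colSums(2 * p2[th_sel, , drop = FALSE])
    pw_al[cols] <- colSums(2 * p2[al_sel, , drop = FALSE])
  }
  grp <- rep(seq_len(d[1L]), each = d[2L])
  th <- as.numeric(tapply(pw_th, grp, mean))
  al <- as.numeric(tapply(pw_al, grp, mean))
  # with alpha power indistinguishable from zero (relative to the epoch's
  # total power) the ratio is infinite if theta power is present and
  # undefined if both bands are empty
  tot <- as.numeric(tapply(colMeans(M^2), grp, mean))
  tol <- 1e-12 * pmax(tot, .Machine$double.xmin)
  ratio <- ifelse(al > tol, th / al, ifelse(th > tol, Inf, NaN))
  undef <- is.nan(ratio)
  if (any(undef)) {
    warning(sprintf("%d epoch(s) with zero alpha power removed (undefined ratio)",
                    sum(undef)))
  }
  # strict ">" with float slack so a ratio numerically equal to the
  # threshold is kept
  kept <- !undef & ratio <= threshold * (1 + 1e-9)
  if (!any(kept)) warning("theta/alpha rejection removed every epoch")
  out <- keep_epochs(epochs, which(kept))
  attr(out, "kept") <- kept
  attr(out, "ratio") <- ratio
  out
}

#' Randomly select a fixed number of epochs
#'
#' Samples `k` epochs uniformly without replacement (temporal order preserved
#' among the selected), reproducibly under `seed`.
#'
#' @param epochs an [epoch_set].
#' @param k number of epochs to keep (default 30).
#' @param seed integer seed.
#' @param allow_fewer if TRUE and fewer than `k` epochs are available, keep all
#'   with a warning instead of erroring.
#' @return an [epoch_set] with `min(k, n)` epochs.
#' @export
select_epochs <- function(epochs, k = 30, seed = NULL, allow_fewer = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"), k >= 1)
  n <- n_epochs(epochs)
  if (n < k) {
    if (!allow_fewer) {
      stop(sprintf("only %d epochs available, %d requested (set allow_fewer = TRUE to keep all)",
                   n, k))
    }
    warning(sprintf("only %d epochs available; keeping all", n))
    return(epochs)
  }
  if (n == k) return(epochs)
  idx <- sort(with_seed(seed, sample.int(n, k)))
  keep_epochs(epochs, idx)
}

#' Full epoch-level preprocessing chain
#'
#' Amplitude rejection, theta/alpha-ratio rejection (in that order), then
#' random subsampling to `k` epochs.
#'
#' @inheritParams reject_amplitude
#' @inheritParams reject_theta_alpha
#' @inheritParams select_epochs
#' @return an [epoch_set].
#' @export
preprocess_epochs <- function(epochs, limit = 100, threshold = 1, k = 30,
                              seed = NULL, allow_fewer = FALSE) {
  epochs <- reject_amplitude(epochs, limit = limit)
  epochs <- reject_theta_alpha(epochs, threshold = threshold)
  select_epochs(epochs, k = k, seed = seed, allow_fewer = allow_fewer)
}
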