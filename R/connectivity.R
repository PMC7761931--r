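#' Instantaneous phase via the analytic signal
#'
#' Builds the analytic signal by zeroing negative frequencies in the DFT
#' (doubling positive ones) and returns its argument: the instantaneous phase
#' in (-pi, pi]. For a pure sinusoid at f Hz the unwrapped phase advances at
#' 2*pi*f rad/s.
#'
#' @param x numeric vector (one node, one epoch) or a `samples x nodes`
#'   matrix; must be non-constant per column.
#' @return phase series, same shape as `x` (radians).
#' @export
instantaneous_phase <- function(x) {
  vec <- is.vector(x)
  if (vec) x <- matrix(x, ncol = 1L)
  if (any(apply(x, 2L, function(v) max(v) == min(v)))) {
    stop("instantaneous phase undefined for a constant signal")
  }
  n <- nrow(x)
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2L == 0L) {
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[2L:((n + 1L) / 2L)] <- 2
  }
  a <- stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n
  ph <- Arg(a)
  if (vec) ph[, 1L] else ph
}

#' Phase-locking value of one pair of phase series
#'
#' The magnitude of the time-averaged unit phasor of the phase difference:
#' 1 means a constant lag, values near 0 mean independent phases (the
#' finite-sample floor is of order 1/sqrt(T)).
#'
#' @param phase_x,phase_y phase series in radians, equal length >= 2.
#' @return PLV in `[0, 1]`.
#' @export
plv_pair <- function(phase_x, phase_y) {
  if (length(phase_x) != length(phase_y)) stop("phase series length mismatch")
  if (length(phase_x) < 2L) stop("need at least 2 samples")
  Mod(mean(exp(1i * (phase_x - phase_y))))
}

#' Per-band PLV connectivity matrix
#'
#' Computes instantaneous phases per node, then the PLV for every unordered
#' node pair. By default the PLV is computed within each epoch over its
#' samples and averaged across epochs (epochs being the unit of artifact
#' control); `method = "concat"` instead concatenates the phase series of all
#' epochs and computes one PLV. A fraction of samples at each epoch edge is
#' discarded before the PLV to suppress filter edge effects.
#'
#' @param band_filtered an [epoch_set] that has already been band-limited.
#' @param band optional band identifier stored in the result.
#' @param method `"epochs"` (default: per-epoch PLV, averaged) or `"concat"`.
#' @param edge_trim fraction of samples trimmed from each epoch edge
#'   (default 0.1).
#' @return object of class `plv_matrix`: list with `values` (symmetric
#'   `nodes x nodes` matrix, unit diagonal), `band`, `n_epochs_used`.
#' @export
plv_matrix <- function(band_filtered, band = NULL,
                       method = c("epochs", "concat"), edge_trim = 0.1) {
  stopifnot(inherits(band_filtered, "epoch_set"))
  method <- match.arg(method)
  d <- dim(band_filtered$data)
  if (d[1L] < 1L) stop("empty epoch set")
  ns <- d[3L]
  trim <- floor(ns * edge_trim)
  keep <- (trim + 1L):(ns - trim)
  tl <- length(keep)
  nn <- d[2L]
  acc <- matrix(0, nn, nn)
  cs_all <- NULL; sn_all <- NULL
  # batched analytic-signal phase for every (epoch, node) series
  M <- matrix(aperm(band_filtered$data, c(3L, 2L, 1L)), nrow = ns)
  PH <- matrix(0, ns, ncol(M))
  chunk <- max(1L, floor(8e6 / ns))
  for (s in seq(1L, ncol(M), by = chunk)) {
    cols <- s:min(ncol(M), s + chunk - 1L)
    PH[, cols] <- instantaneous_phase(M[, cols, drop = FALSE])
  }
  for (e in seq_len(d[1L])) {
    ph <- t(PH[keep, ((e - 1L) * nn + 1L):(e * nn), drop = FALSE])
    cs <- cos(ph); sn <- sin(ph)
    if (method == "epochs") {
      re <- tcrossprod(cs) + tcrossprod(sn)
      im <- tcrossprod(sn, cs) - tcrossprod(cs, sn)
      acc <- acc + sqrt(re^2 + im^2) / tl
    } else {
      cs_all <- cbind(cs_all, cs); sn_all <- cbind(sn_all, sn)
    }
  }
  if (method == "epochs") {
    vals <- acc / d[1L]
  } else {
    tt <- ncol(cs_all)
    re <- tcrossprod(cs_all) + tcrossprod(sn_all)
    im <- tcrossprod(sn_all, cs_all) - tcrossprod(cs_all, sn_all)
    vals <- sqrt(re^2 + im^2) / tt
  }
  vals <- (vals + t(vals)) / 2
  vals[vals > 1] <- 1
  diag(vals) <- 1
  dimnames(vals) <- list(band_filtered$node_labels, band_filtered$node_labels)
  structure(list(values = vals, band = band, n_epochs_used = d[1L]),
            class = "plv_matrix")
}

#' @export
print.plv_matrix <- function(x, ...) {
  cat(sprintf("<plv_matrix> %d nodes, band %s, %d epoch(s)\n",
              nrow(x$values), x$band %||% "?", x$n_epochs_used))
  invisible(x)
}
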