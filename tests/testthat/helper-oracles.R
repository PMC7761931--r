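# Independent brute-force oracles used to cross-check the implementation.

# Weighted clustering coefficient by explicit triangle enumeration:
# geometric-mean formulation on weights normalised by the matrix maximum.
oracle_local_cc <- function(W) {
  diag(W) <- 0
  n <- nrow(W)
  mx <- max(W)
  if (mx == 0) return(numeric(n))
  Wh <- W / mx
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        j <- nb[a]; h <- nb[b]
        s <- s + (Wh[i, j] * Wh[i, h] * Wh[j, h])^(1 / 3)
      }
    }
    out[i] <- 2 * s / (k * (k - 1))
  }
  out
}

# All-pairs shortest paths by Floyd-Warshall on inverse-weight lengths.
oracle_cpl <- function(W, mode = "mean") {
  diag(W) <- 0
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[W > 0] <- 1 / W[W > 0]
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  up <- D[upper.tri(D)]
  up <- up[is.finite(up)]
  if (mode == "mean") mean(up) else sum(up)
}

# Inverse binomial CDF by explicit summation of the mass function.
# q = 1 is handled exactly: only the full support has CDF equal to 1
# (floating-point cumsum cannot distinguish 1 - dbinom tail from 1).
oracle_binom_inv <- function(q, n, p) {
  if (q >= 1) return(if (p > 0) as.integer(n) else 0L)
  cdf <- cumsum(dbinom(0:n, n, p))
  which(cdf >= q - 1e-12)[1] - 1L
}

# AUC via the Mann-Whitney statistic.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Random symmetric weighted graph with strictly positive off-diagonal weights.
random_plv_graph <- function(n, seed) {
  set.seed(seed)
  W <- matrix(runif(n * n, 0.05, 1), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 1
  structure(list(values = W, band = "test", n_epochs_used = 1),
            class = "plv_matrix")
}

as_plv <- function(W, band = "test") {
  structure(list(values = W, band = band, n_epochs_used = 1),
            class = "plv_matrix")
}

# Small epoch set holding given per-epoch node signals.
tiny_epochs <- function(..., fs = 1000) {
  eps <- list(...)
  nn <- nrow(eps[[1]])
  ns <- ncol(eps[[1]])
  a <- array(0, dim = c(length(eps), nn, ns))
  for (e in seq_along(eps)) a[e, , ] <- eps[[e]]
  epoch_set(a, fs = fs)
}

sine_epoch <- function(freq, n_nodes = 1, amp = 1, fs = 1000, seconds = 2) {
  tt <- (0:(fs * seconds - 1)) / fs
  matrix(rep(amp * sin(2 * pi * freq * tt), n_nodes),
         nrow = n_nodes, byrow = TRUE)
}
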