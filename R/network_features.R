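#' Weighted local clustering coefficient
#'
#' Triangle-based geometric-mean formulation on weights rescaled by the matrix
#' maximum: with W-hat = W / max(W) and zeroed diagonal,
#' C_i = sum_{j,h} (w-hat_ij w-hat_ih w-hat_jh)^(1/3) / (k_i (k_i - 1)),
#' where k_i counts node i's nonzero-weight neighbours. Values lie in [0, 1];
#' nodes of degree < 2 get 0.
#'
#' @param W a `plv_matrix` or a symmetric non-negative numeric matrix.
#' @return numeric vector of per-node clustering coefficients.
#' @export
local_clustering <- function(W) {
  W <- as_weight_matrix(W)
  diag(W) <- 0
  mx <- max(W)
  if (mx == 0) {
    warning("all-zero weight matrix: clustering coefficients are 0")
    return(stats::setNames(numeric(nrow(W)), rownames(W)))
  }
  Wh <- (W / mx)^(1 / 3)
  k <- rowSums(W > 0)
  num <- diag(Wh %*% Wh %*% Wh)
  cc <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  stats::setNames(cc, rownames(W))
}

#' Weighted global clustering coefficient
#'
#' Arithmetic mean of the local clustering coefficients over all nodes.
#' @inheritParams local_clustering
#' @return scalar in `[0, 1]`.
#' @export
global_clustering <- function(W) mean(local_clustering(W))

#' Characteristic path length of a weighted graph
#'
#' Edge lengths are the inverse connection weights (1/w); shortest-path
#' distances are computed over all node pairs and summarised as their mean
#' (`mode = "mean"`, the characteristic path length) or their sum over
#' unordered pairs (`mode = "sum"`). If the graph is disconnected the summary
#' is taken over reachable pairs with a warning.
#'
#' @inheritParams local_clustering
#' @param mode `"mean"` (default) or `"sum"`.
#' @return scalar path-length summary.
#' @export
char_path_length <- function(W, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  W <- as_weight_matrix(W)
  diag(W) <- 0
  n <- nrow(W)
  if (n < 2L) stop("path length undefined for fewer than 2 nodes")
  L <- ifelse(W > 0, 1 / W, 0)
  g <- igraph::graph_from_adjacency_matrix(L, mode = "undirected",
                                           weighted = TRUE)
  D <- igraph::distances(g, algorithm = "dijkstra")
  up <- D[upper.tri(D)]
  if (any(!is.finite(up))) {
    warning("disconnected graph: summarising over reachable pairs only")
    up <- up[is.finite(up)]
  }
  if (mode == "mean") mean(up) else sum(up)
}

as_weight_matrix <- function(W) {
  if (inherits(W, "plv_matrix")) W <- W$values
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (any(W < 0)) stop("weights must be non-negative")
  if (max(abs(W - t(W))) > 1e-8) stop("weight matrix must be symmetric")
  W
}

#' Assemble the per-subject network feature vector
#'
#' Concatenates, band by band, the per-node local clustering coefficients
#' (node order), the global clustering coefficient and the characteristic
#' path length, giving `n_nodes * n_bands + 2 * n_bands` features. Names
#' follow `{band}__{kind}__{node}` / `{band}__global_cc` /
#' `{band}__path_length`. With 148 nodes and the 11 canonical bands the
#' vector has 1650 entries.
#'
#' @param per_band_matrices list of `plv_matrix` objects, one per band, over
#'   the same node set.
#' @return named numeric vector with attribute `index`, a data.frame
#'   (`band`, `kind`, `node`) describing each position.
#' @export
assemble_features <- function(per_band_matrices) {
  stopifnot(is.list(per_band_matrices), length(per_band_matrices) >= 1L)
  n_nodes <- nrow(per_band_matrices[[1L]]$values)
  if (n_nodes < 2L) stop("graph metrics undefined for a single node")
  labels0 <- rownames(per_band_matrices[[1L]]$values) %||%
    sprintf("node_%03d", seq_len(n_nodes))
  vals <- c(); idx <- list()
  for (m in per_band_matrices) {
    stopifnot(inherits(m, "plv_matrix"))
    lab_m <- rownames(m$values) %||% sprintf("node_%03d", seq_len(nrow(m$values)))
    if (nrow(m$values) != n_nodes || !identical(lab_m, labels0)) {
      stop("all bands must share one node set")
    }
    band <- m$band %||% "band"
    cc <- local_clustering(m)
    v <- c(cc, mean(cc), char_path_length(m))
    names(v) <- c(sprintf("%s__local_cc__%s", band, labels0),
                  sprintf("%s__global_cc", band),
                  sprintf("%s__path_length", band))
    vals <- c(vals, v)
    idx[[length(idx) + 1L]] <- data.frame(
      band = band,
      kind = c(rep("local_cc", n_nodes), "global_cc", "path_length"),
      node = c(labels0, NA, NA), stringsAsFactors = FALSE)
  }
  attr(vals, "index") <- do.call(rbind, idx)
  vals
}
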