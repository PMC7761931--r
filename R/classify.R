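#' @title SFS-wrapped LDA classification under repeated stratified CV
#' @description Internal helpers plus the user-facing `cv_10x10`, `sfs_select`
#'   and `run_pair`. Fold construction is stratified: within each class,
#'   subject order is shuffled and folds assigned round-robin, so every fold
#'   holds both classes whenever class counts allow.
#' @name classify
NULL

# Stratified fold assignment; returns integer fold id per subject.
stratified_folds <- function(y, n_folds, seed = NULL) {
  y <- as.factor(y)
  counts <- table(y)
  if (min(counts) < n_folds) {
    n_folds <- max(2L, min(counts))
    warning(sprintf("smallest class has %d members; using %d folds",
                    min(counts), n_folds))
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (lev in levels(y)) {
      idx <- which(y == lev)
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))[sample.int(length(idx))]
    }
  })
  fold
}

fold_metrics <- function(truth, pred, positive) {
  pos <- truth == positive
  acc <- mean(pred == truth)
  sens <- if (any(pos)) mean(pred[pos] == truth[pos]) else NA_real_
  spec <- if (any(!pos)) mean(pred[!pos] == truth[!pos]) else NA_real_
  c(accuracy = acc, sensitivity = sens, specificity = spec,
    n_pos = sum(pos), n_neg = sum(!pos))
}

#' Repeated stratified k-fold cross-validation of an LDA
#'
#' Runs `repeats` independent repetitions of stratified `n_folds`-fold
#' cross-validation (default 10 x 10-fold) with distinct shuffles; accuracy,
#' sensitivity (recall of the positive class) and specificity are averaged
#' over all held-out folds. Per-fold decision scores are kept for ROC
#' averaging. Fully reproducible under `seed`.
#'
#' @param X feature matrix `subjects x features`.
#' @param y binary labels.
#' @param positive positive-class label (defaults to the second factor
#'   level).
#' @param n_folds folds per repetition (default 10).
#' @param repeats repetitions (default 10).
#' @param seed integer seed.
#' @return object of class `cv_report`; see [print.cv_report()].
#' @export
cv_10x10 <- function(X, y, positive = NULL, n_folds = 10, repeats = 10,
                     seed = 1L) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (length(levels(droplevels(y))) != 2L) stop("labels must be binary")
  if (is.null(positive)) positive <- levels(droplevels(y))[2L]
  per_fold <- list(); fold_scores <- list()
  k <- 0L
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, n_folds, seed = derive_seed(seed, r))
    for (f in sort(unique(fold))) {
      k <- k + 1L
      te <- fold == f
      fit <- lda_train(X[!te, , drop = FALSE], y[!te], positive = positive)
      pred <- predict(fit, X[te, , drop = FALSE])
      per_fold[[k]] <- c(repeat_ = r, fold = f,
                         fold_metrics(as.character(y[te]), pred, positive))
      fold_scores[[k]] <- list(
        scores = predict(fit, X[te, , drop = FALSE], type = "score"),
        labels = as.character(y[te]) == positive)
    }
  }
  tab <- as.data.frame(do.call(rbind, per_fold))
  roc <- roc_mean(fold_scores)
  structure(list(
    accuracy = 100 * mean(tab$accuracy),
    sensitivity = 100 * mean(tab$sensitivity, na.rm = TRUE),
    specificity = 100 * mean(tab$specificity, na.rm = TRUE),
    per_fold = tab, roc = roc, auc = roc$auc,
    positive = positive, n = length(y), n_folds = n_folds,
    repeats = repeats, seed = seed, mode = NULL,
    selected = NULL, trace = NULL, threshold_pct = NULL
  ), class = "cv_report")
}

#' Sequential forward feature selection with an LDA cost
#'
#' Greedy bottom-up wrapper: at each step the candidate feature whose
#' addition maximises the cost function — mean stratified k-fold CV accuracy
#' of the LDA on the candidate set, with fold assignment fixed across the
#' whole search — joins the set. Ties break to the lowest feature index. The
#' search stops when no candidate improves the cost or when `max_k` features
#' are selected; the returned set is the trace prefix with the best cost.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param max_k cap on the number of selected features (default 30).
#' @param n_folds folds for the inner cost CV (default 10).
#' @param seed seed for the inner fold assignment.
#' @param positive positive-class label.
#' @return list with `selected` (integer indices, best prefix), `trace`
#'   (data.frame `feature`, `accuracy` per step) and `best_cost`.
#' @export
sfs_select <- function(X, y, max_k = 30, n_folds = 10, seed = 1L,
                       positive = NULL) {
  X <- as.matrix(X)
  y <- as.factor(y)
  p <- ncol(X)
  max_k <- min(max_k, p)
  fold <- stratified_folds(y, n_folds, seed = derive_seed(seed, 7919L))
  cost <- function(cols) {
    acc <- 0
    for (f in sort(unique(fold))) {
      te <- fold == f
      fit <- lda_train(X[!te, cols, drop = FALSE], y[!te],
                       positive = positive)
      acc <- acc + mean(predict(fit, X[te, cols, drop = FALSE]) ==
                          as.character(y[te]))
    }
    acc / length(unique(fold))
  }
  sel <- integer(0)
  trace_feat <- integer(0); trace_acc <- numeric(0)
  best_so_far <- -Inf
  while (length(sel) < max_k) {
    cand <- setdiff(seq_len(p), sel)
    costs <- vapply(cand, function(j) cost(c(sel, j)), numeric(1))
    best <- which.max(costs)          # which.max takes the first (lowest index) tie
    if (costs[best] <= best_so_far) break
    best_so_far <- costs[best]
    sel <- c(sel, cand[best])
    trace_feat <- c(trace_feat, cand[best])
    trace_acc <- c(trace_acc, costs[best])
  }
  best_k <- which.max(trace_acc)
  list(selected = trace_feat[seq_len(best_k)],
       trace = data.frame(feature = trace_feat, accuracy = 100 * trace_acc),
       best_cost = 100 * max(trace_acc))
}

#' Classify one pair of groups from a feature table
#'
#' Full classification stage for one binary contrast. In `"paper"` mode
#' (default, replicating the study design) SFS runs once on the complete data
#' set and the selected features are then assessed by repeated stratified CV;
#' the resulting accuracy is optimistic because selection saw the evaluation
#' data. In `"nested"` mode SFS is re-run inside every training fold and the
#' held-out fold is scored with that fold's own selection, giving an unbiased
#' estimate. The binomial significance threshold for the sample size is
#' attached to the report.
#'
#' @param X feature matrix `subjects x features` (or data.frame).
#' @param y binary labels.
#' @param mode `"paper"` or `"nested"`.
#' @param max_k SFS cap (default 30).
#' @param n_folds,repeats CV geometry (default 10 x 10).
#' @param sfs_folds folds of the SFS inner cost CV (default 10).
#' @param alpha significance level for the decoding threshold (default 0.05).
#' @param positive positive-class label.
#' @param seed master seed.
#' @return a `cv_report` with `selected`, `trace` (paper mode) or selection
#'   frequencies (nested mode), `mode` and `threshold_pct` filled in.
#' @export
run_pair <- function(X, y, mode = c("paper", "nested"), max_k = 30,
                     n_folds = 10, repeats = 10, sfs_folds = 10,
                     alpha = 0.05, positive = NULL, seed = 1L) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nrow(X) != length(y)) stop("feature rows and labels differ in length")
  if (length(levels(droplevels(y))) != 2L) stop("labels must be binary")
  if (is.null(positive)) positive <- levels(droplevels(y))[2L]
  if (mode == "paper") {
    sfs <- sfs_select(X, y, max_k = max_k, n_folds = sfs_folds,
                      seed = derive_seed(seed, 1L), positive = positive)
    rep_ <- cv_10x10(X[, sfs$selected, drop = FALSE], y, positive = positive,
                     n_folds = n_folds, repeats = repeats,
                     seed = derive_seed(seed, 2L))
    rep_$selected <- sfs$selected
    rep_$trace <- sfs$trace
  } else {
    rep_ <- cv_nested(X, y, positive = positive, max_k = max_k,
                      n_folds = n_folds, repeats = repeats,
                      sfs_folds = sfs_folds, seed = derive_seed(seed, 2L))
  }
  rep_$mode <- mode
  rep_$feature_names <- colnames(X)
  rep_$threshold_pct <- significance_threshold(length(y), 2L, alpha)
  rep_$exceeds_threshold <- rep_$accuracy > rep_$threshold_pct
  rep_
}

# Nested variant: SFS inside every training fold.
cv_nested <- function(X, y, positive, max_k, n_folds, repeats, sfs_folds,
                      seed) {
  per_fold <- list(); fold_scores <- list(); sel_count <- integer(ncol(X))
  k <- 0L
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, n_folds, seed = derive_seed(seed, r))
    for (f in sort(unique(fold))) {
      k <- k + 1L
      te <- fold == f
      sfs <- sfs_select(X[!te, , drop = FALSE], y[!te], max_k = max_k,
                        n_folds = sfs_folds,
                        seed = derive_seed(seed, r, f), positive = positive)
      cols <- sfs$selected
      sel_count[cols] <- sel_count[cols] + 1L
      fit <- lda_train(X[!te, cols, drop = FALSE], y[!te],
                       positive = positive)
      pred <- predict(fit, X[te, cols, drop = FALSE])
      per_fold[[k]] <- c(repeat_ = r, fold = f,
                         fold_metrics(as.character(y[te]), pred, positive))
      fold_scores[[k]] <- list(
        scores = predict(fit, X[te, cols, drop = FALSE], type = "score"),
        labels = as.character(y[te]) == positive)
    }
  }
  tab <- as.data.frame(do.call(rbind, per_fold))
  roc <- roc_mean(fold_scores)
  structure(list(
    accuracy = 100 * mean(tab$accuracy),
    sensitivity = 100 * mean(tab$sensitivity, na.rm = TRUE),
    specificity = 100 * mean(tab$specificity, na.rm = TRUE),
    per_fold = tab, roc = roc, auc = roc$auc,
    positive = positive, n = length(y), n_folds = n_folds,
    repeats = repeats, seed = seed, mode = "nested",
    selected = which(sel_count > 0), selection_freq = sel_count,
    trace = NULL, threshold_pct = NULL
  ), class = "cv_report")
}

#' Vertically averaged ROC curve over CV folds
#'
#' Each fold's empirical ROC (true-positive rate as a function of
#' false-positive rate) is interpolated onto a fixed FPR grid and averaged
#' vertically; the AUC is the trapezoidal area under the mean curve. Folds
#' lacking either class are dropped with a warning.
#'
#' @param fold_scores list of per-fold lists with `scores` (numeric decision
#'   scores, larger = more positive) and `labels` (logical, TRUE = positive).
#' @param grid FPR grid (default 0 to 1 by 0.01).
#' @return list with `fpr`, `tpr` (mean curve) and `auc`.
#' @export
roc_mean <- function(fold_scores, grid = seq(0, 1, by = 0.01)) {
  ok <- vapply(fold_scores,
               function(f) any(f$labels) && any(!f$labels), logical(1))
  if (!any(ok)) stop("no fold contains both classes")
  if (!all(ok)) warning(sprintf("%d fold(s) lacked a class; dropped",
                                sum(!ok)))
  curves <- vapply(fold_scores[ok], function(f) {
    o <- order(f$scores, decreasing = TRUE)
    lab <- f$labels[o]
    tpr <- c(0, cumsum(lab) / sum(lab))
    fpr <- c(0, cumsum(!lab) / sum(!lab))
    # step interpolation onto the grid (largest tpr with fpr <= g)
    vapply(grid, function(g) max(tpr[fpr <= g]), numeric(1))
  }, numeric(length(grid)))
  tpr_mean <- rowMeans(curves)
  auc <- sum(diff(grid) * (head(tpr_mean, -1) + tail(tpr_mean, -1)) / 2)
  list(fpr = grid, tpr = tpr_mean, auc = auc)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s%d x %d-fold CV, n = %d\n",
              if (!is.null(x$mode)) paste0("mode=", x$mode, ", ") else "",
              x$repeats, x$n_folds, x$n))
  cat(sprintf("  accuracy    %6.2f %%\n", x$accuracy))
  cat(sprintf("  sensitivity %6.2f %%  (positive: %s)\n",
              x$sensitivity, x$positive))
  cat(sprintf("  specificity %6.2f %%\n", x$specificity))
  cat(sprintf("  AUC         %6.3f\n", x$auc))
  if (!is.null(x$threshold_pct)) {
    cat(sprintf("  significance threshold %5.2f %% -> %s\n", x$threshold_pct,
                if (isTRUE(x$exceeds_threshold)) "above" else "not above"))
  }
  if (!is.null(x$selected) && !is.null(x$trace)) {
    cat(sprintf("  selected %d feature(s): %s\n", length(x$selected),
                paste(x$selected, collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.cv_report <- function(object, ...) {
  out <- list(
    accuracy = object$accuracy, sensitivity = object$sensitivity,
    specificity = object$specificity, auc = object$auc,
    mode = object$mode, n = object$n,
    n_features_selected = length(object$selected),
    threshold_pct = object$threshold_pct,
    exceeds_threshold = object$exceeds_threshold)
  class(out) <- "summary.cv_report"
  out
}

#' @export
print.summary.cv_report <- function(x, ...) {
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.null(v)) cat(sprintf("%-20s %s\n", nm, format(v, digits = 4)))
  }
  invisible(x)
}

#' Plot the fold-averaged ROC curve of a CV report
#'
#' @param x a `cv_report`.
#' @param ... passed to [plot.default()].
#' @export
plot.cv_report <- function(x, ...) {
  plot(x$roc$fpr, x$roc$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate",
       main = sprintf("Mean ROC (AUC = %.3f)", x$auc), ...)
  abline(0, 1, lty = 3)
  invisible(x)
}
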