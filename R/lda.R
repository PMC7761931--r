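#' Train a two-class linear discriminant
#'
#' Classic LDA from class means and pooled within-class covariance, with a
#' small ridge (1e-6 times the covariance trace) added to the diagonal so
#' collinear or duplicated feature columns never make the fit fail. Class
#' priors are the empirical class frequencies. Deterministic.
#'
#' @param X numeric matrix `subjects x features`.
#' @param y binary labels (factor, character or numeric with 2 levels).
#' @param positive which label is the positive class (for scores and
#'   sensitivity); defaults to the second level.
#' @param ridge ridge multiplier on the covariance trace (default 1e-6).
#' @return object of class `lda_pooled` with elements `w` (weights),
#'   `threshold`, `levels`, `positive`, `means`.
#' @export
lda_train <- function(X, y, positive = NULL, ridge = 1e-6) {
  X <- as.matrix(X)
  y <- as.factor(y)
  lev <- levels(droplevels(y))
  if (length(lev) != 2L) stop("lda_train requires exactly two classes present")
  if (is.null(positive)) positive <- lev[2L]
  if (!positive %in% lev) stop("`positive` is not one of the class labels")
  neg <- setdiff(lev, positive)
  i1 <- which(y == positive); i0 <- which(y == neg)
  n1 <- length(i1); n0 <- length(i0)
  m1 <- colMeans(X[i1, , drop = FALSE])
  m0 <- colMeans(X[i0, , drop = FALSE])
  c1 <- if (n1 > 1) stats::cov(X[i1, , drop = FALSE]) else 0 * diag(ncol(X))
  c0 <- if (n0 > 1) stats::cov(X[i0, , drop = FALSE]) else 0 * diag(ncol(X))
  S <- ((n1 - 1) * c1 + (n0 - 1) * c0) / max(1L, n1 + n0 - 2L)
  lam <- ridge * sum(diag(S))
  if (lam <= 0) lam <- ridge
  S <- S + diag(lam, ncol(X))
  w <- solve(S, m1 - m0)
  # decide positive iff x'w > t;  t folds in the log prior ratio
  thr <- sum((m1 + m0) / 2 * w) - log(n1 / n0)
  structure(list(w = w, threshold = thr, levels = c(negative = neg,
                 positive = positive), positive = positive,
                 means = rbind(negative = m0, positive = m1)),
            class = "lda_pooled")
}

#' @export
coef.lda_pooled <- function(object, ...) object$w

#' Predict from a pooled-covariance LDA
#'
#' @param object an `lda_pooled` fit.
#' @param newdata matrix `subjects x features`.
#' @param type `"class"` (default) or `"score"` (signed discriminant score;
#'   positive means the positive class).
#' @param ... unused.
#' @export
predict.lda_pooled <- function(object, newdata,
                               type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  s <- drop(newdata %*% object$w) - object$threshold
  if (type == "score") return(s)
  ifelse(s > 0, object$levels[["positive"]], object$levels[["negative"]])
}

#' @export
print.lda_pooled <- function(x, ...) {
  cat(sprintf("<lda_pooled> %d feature(s); positive class '%s'\n",
              length(x$w), x$positive))
  invisible(x)
}
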