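sep_data <- function(n, d = 3, gap = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n * d), ncol = d)
  X[1:n, 1] <- X[1:n, 1] - gap / 2
  X[(n + 1):(2 * n), 1] <- X[(n + 1):(2 * n), 1] + gap / 2
  list(X = X, y = factor(rep(c("ctrl", "case"), each = n),
                         levels = c("ctrl", "case")))
}

test_that("LDA separates well-separated Gaussians and is chance on noise", {
  d <- sep_data(200, d = 1, gap = 10, seed = 2)
  tr <- c(1:150, 201:350); te <- setdiff(seq_len(400), tr)
  fit <- lda_train(d$X[tr, , drop = FALSE], d$y[tr])
  expect_gt(mean(predict(fit, d$X[te, , drop = FALSE]) ==
                   as.character(d$y[te])), 0.99)

  set.seed(3)
  Xn <- matrix(rnorm(400 * 3), ncol = 3)
  fit0 <- lda_train(Xn[tr, ], d$y[tr])
  acc0 <- mean(predict(fit0, Xn[te, ]) == as.character(d$y[te]))
  expect_gt(acc0, 0.35); expect_lt(acc0, 0.65)
})

test_that("duplicate feature columns do not break the ridge-stabilised fit", {
  d <- sep_data(50, d = 2, seed = 4)
  Xd <- cbind(d$X, d$X[, 1], d$X[, 1])
  expect_silent(fit <- lda_train(Xd, d$y))
  expect_gt(mean(predict(fit, Xd) == as.character(d$y)), 0.9)
})

test_that("the in-package LDA agrees with the reference implementation", {
  skip_if_not_installed("MASS")
  d <- sep_data(80, d = 4, gap = 2, seed = 5)
  fit <- lda_train(d$X, d$y)
  ref <- MASS::lda(d$X, grouping = d$y)
  agree <- mean(predict(fit, d$X) ==
                  as.character(predict(ref, d$X)$class))
  expect_gte(agree, 0.98)
})

test_that("single-class input errors", {
  expect_error(lda_train(matrix(rnorm(20), ncol = 2), rep("a", 10)),
               "two classes")
})

test_that("repeated stratified CV is reproducible and self-consistent", {
  d <- sep_data(15, gap = 3, seed = 6)
  r1 <- cv_10x10(d$X, d$y, positive = "case", n_folds = 5, repeats = 3,
                 seed = 11)
  r2 <- cv_10x10(d$X, d$y, positive = "case", n_folds = 5, repeats = 3,
                 seed = 11)
  expect_equal(r1$accuracy, r2$accuracy)
  expect_identical(r1$per_fold, r2$per_fold)
  r3 <- cv_10x10(d$X, d$y, positive = "case", n_folds = 5, repeats = 3,
                 seed = 12)
  expect_false(identical(r1$per_fold, r3$per_fold))

  # per-fold identity: acc = (sens*n_pos + spec*n_neg) / n
  pf <- r1$per_fold
  lhs <- pf$accuracy * (pf$n_pos + pf$n_neg)
  rhs <- pf$sensitivity * pf$n_pos + pf$specificity * pf$n_neg
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("separable data reaches ~100% CV accuracy; metrics bounded", {
  d <- sep_data(15, gap = 12, seed = 7)
  r <- cv_10x10(d$X, d$y, positive = "case", seed = 13)
  expect_gt(r$accuracy, 99)
  expect_true(all(c(r$accuracy, r$sensitivity, r$specificity) <= 100))
  expect_true(all(c(r$accuracy, r$sensitivity, r$specificity) >= 0))
  expect_gt(r$auc, 0.99)
})

test_that("SFS picks the informative feature first and respects the cap", {
  set.seed(8)
  X <- matrix(rnorm(60 * 10), ncol = 10)
  y <- factor(rep(c("a", "b"), each = 30))
  X[y == "b", 3] <- X[y == "b", 3] + 8   # only feature 3 separates
  s <- sfs_select(X, y, max_k = 5, seed = 21)
  expect_equal(s$selected[1], 3)
  expect_lte(nrow(s$trace), 5)
  expect_equal(s$best_cost, max(s$trace$accuracy))

  s1 <- sfs_select(X, y, max_k = 1, seed = 22)
  expect_equal(nrow(s1$trace), 1)
  expect_equal(s1$selected, 3)
})

test_that("run_pair reports mode, threshold and the selected set", {
  d <- sep_data(20, gap = 8, seed = 9)
  r <- run_pair(d$X, d$y, mode = "paper", n_folds = 5, repeats = 2,
                sfs_folds = 5, seed = 31)
  expect_equal(r$mode, "paper")
  expect_equal(r$threshold_pct, significance_threshold(40, 2, 0.05))
  expect_true(r$exceeds_threshold)
  expect_true(all(r$trace$accuracy <= 100))
  expect_lte(length(r$selected), 30)

  rn <- run_pair(d$X, d$y, mode = "nested", n_folds = 5, repeats = 1,
                 sfs_folds = 5, max_k = 3, seed = 31)
  expect_equal(rn$mode, "nested")
  expect_gt(rn$accuracy, 90)
})

test_that("nested CV stays near chance under permuted labels", {
  set.seed(10)
  X <- matrix(rnorm(40 * 8), ncol = 8)
  y <- factor(rep(c("a", "b"), each = 20))[sample(40)]
  r <- run_pair(X, y, mode = "nested", n_folds = 5, repeats = 2,
                sfs_folds = 5, max_k = 5, seed = 41)
  expect_lt(r$accuracy, 75)  # generous band around 50% for one small run
  expect_gt(r$accuracy, 25)
})

test_that("ROC averaging matches canonical cases and the reference AUC", {
  perfect <- list(list(scores = c(1, 2, 3, 4), labels = c(F, F, T, T)))
  expect_equal(roc_mean(perfect)$auc, 1)
  reversed <- list(list(scores = c(4, 3, 2, 1), labels = c(F, F, T, T)))
  expect_lt(roc_mean(reversed)$auc, 0.05)

  set.seed(12)
  rand <- list(list(scores = rnorm(4000), labels = rep(c(TRUE, FALSE), 2000)))
  expect_equal(roc_mean(rand)$auc, 0.5, tolerance = 0.05)

  skip_if_not_installed("pROC")
  set.seed(13)
  sc <- rnorm(300); lb <- runif(300) < plogis(2 * sc)
  ours <- roc_mean(list(list(scores = sc, labels = lb)))$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 0.02)

  expect_error(roc_mean(list(list(scores = 1:3, labels = rep(TRUE, 3)))),
               "both classes")
})
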