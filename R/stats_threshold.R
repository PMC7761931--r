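#' Inverse binomial CDF
#'
#' Smallest number of successes k in `[0, n]` whose binomial cumulative
#' probability reaches `q` — the convention used to turn chance-level
#' accuracy into a significance threshold for decoding.
#'
#' @param q target cumulative probability in `[0, 1]`.
#' @param n number of trials.
#' @param p success probability.
#' @return integer k.
#' @export
binom_inv <- function(q, n, p) {
  if (!is.numeric(q) || q < 0 || q > 1) stop("q must be in [0, 1]")
  if (!is.numeric(p) || p < 0 || p > 1) stop("p must be in [0, 1]")
  stopifnot(n >= 1, n == round(n))
  as.integer(stats::qbinom(q, n, p))
}

#' Binomial significance threshold for decoding accuracy
#'
#' The smallest accuracy (in percent) that a classifier of `c` classes on
#' `n` samples must exceed for its correct-classification count to be
#' significantly above chance at level `alpha`:
#' `binom_inv(1 - alpha, n, 1/c) * 100 / n`, rounded to 2 decimals.
#'
#' @param n sample size.
#' @param c number of classes.
#' @param alpha significance level in (0, 1) (default 0.05).
#' @return threshold accuracy in percent.
#' @export
#' @examples
#' significance_threshold(238, 2, 0.05) # 55.46
#' significance_threshold(119, 2, 0.05) # 57.14
significance_threshold <- function(n, c, alpha = 0.05) {
  stopifnot(n >= 1, c >= 1, alpha > 0, alpha < 1)
  round(binom_inv(1 - alpha, n, 1 / c) * 100 / n, 2)
}

#' Theoretical chance level for c balanced classes
#'
#' @param c number of classes (>= 1).
#' @return chance accuracy in percent (100 / c).
#' @export
chance_level <- function(c) {
  stopifnot(c >= 1)
  100 / c
}
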