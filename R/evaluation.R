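# The three evaluation measures of prediction quality: coefficient of
# determination r^2, Kendall's tau-b rank correlation, and the top-f%
# recognition rate.

#' Coefficient of determination
#'
#' \eqn{r^2 = 1 - \sum_i (y_i - \hat y_i)^2 / \sum_i (y_i - \bar y)^2}.
#'
#' @param y Ground-truth values.
#' @param yhat Predicted values (same length).
#' @return A real number, at most 1 (negative when the predictor is worse
#'   than the constant mean).
#' @export
r_squared <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2L)
  if (anyNA(y) || anyNA(yhat)) stop("missing values are not allowed")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("r_squared is undefined when y has zero variance")
  1 - sum((y - yhat)^2) / ss_tot
}

#' Kendall's tau-b rank correlation
#'
#' Pair-counting with tie correction:
#' \eqn{\tau = (n_c - n_d) / \sqrt{(n_c + n_d + T)(n_c + n_d + U)}},
#' where \eqn{n_c} and \eqn{n_d} count concordant and discordant pairs, and
#' T (resp. U) counts pairs tied in one argument only. Pairs tied in both
#' arguments enter no term.
#'
#' @param a,b Numeric vectors of equal length (>= 2).
#' @return A real number in \eqn{[-1, 1]}; errors if either argument is
#'   entirely tied (the coefficient is undefined).
#' @export
kendall_tau <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  if (anyNA(a) || anyNA(b)) stop("missing values are not allowed")
  tau <- kendall_tau_b_cpp(as.numeric(a), as.numeric(b))
  if (is.na(tau)) {
    stop("Kendall's tau-b is undefined when either ranking is entirely tied")
  }
  tau
}

#' Recognition rate of the top-f% nodes
#'
#' Fraction of the true top-f% nodes (by `s`) recovered in the predicted
#' top-f% (by `s_hat`), both lists of identical length
#' \eqn{m = \lceil f/100 \cdot n \rceil}. Ties at the list boundary are
#' broken by node position (ascending) after sorting by value descending,
#' which makes the measure deterministic.
#'
#' @param s_hat Predicted influence on the test set.
#' @param s True influence on the test set (same length).
#' @param f_percent Top fraction in percent, in (0, 100); default 10.
#' @return A real number in \eqn{[0, 1]}.
#' @export
recognition_rate <- function(s_hat, s, f_percent = 10) {
  n <- length(s)
  stopifnot(n == length(s_hat), n >= 1L, f_percent > 0, f_percent < 100)
  if (anyNA(s) || anyNA(s_hat)) stop("missing values are not allowed")
  m <- ceiling(f_percent / 100 * n)
  top <- function(x) order(-x, seq_along(x))[seq_len(m)]
  length(intersect(top(s_hat), top(s))) / m
}
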