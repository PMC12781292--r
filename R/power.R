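#' Minimum sample size for a multiple-regression power analysis
#'
#' Power of the overall regression F-test with `n_predictors` tested
#' predictors at effect size f² is
#' `P(F'(p, n - p - 1, λ = f² n) > F_crit(α; p, n - p - 1))`,
#' using the noncentral F distribution. The minimum n is found by scanning
#' upward from `p + 2` until the target power is reached — the same
#' calculation a G*Power a-priori analysis performs.
#'
#' @param f2 Cohen's f² effect size (> 0).
#' @param alpha Type-I error rate.
#' @param power Target power in (0, 1).
#' @param n_predictors Number of tested predictors p.
#' @param n_max Search cap; exceeded means the target is unattainable.
#' @return A tibble with `n` (minimum sample size), `power` (achieved at
#'   n), `lambda` (noncentrality at n).
#' @examples
#' required_sample_size_f2(f2 = 0.10, alpha = 0.05, power = 0.95, n_predictors = 10)
#' @export
required_sample_size_f2 <- function(f2, alpha = 0.05, power = 0.95,
                                    n_predictors = 10, n_max = 1e6) {
  if (f2 <= 0) abort("f2 must be > 0")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (power <= 0 || power >= 1) abort("power must be in (0, 1)")
  p <- as.integer(n_predictors)
  if (p < 1) abort("n_predictors must be >= 1")
  n <- p + 2L
  repeat {
    pw <- regression_power(n, f2, alpha, p)
    if (pw >= power) {
      return(tibble(n = n, power = pw, lambda = f2 * n))
    }
    n <- n + 1L
    if (n > n_max) abort("target power unattainable within n_max")
  }
}

#' Achieved power of the overall regression F-test at a given n
#'
#' @param n Sample size (> p + 1).
#' @inheritParams required_sample_size_f2
#' @return Power in (0, 1).
#' @export
regression_power <- function(n, f2, alpha = 0.05, n_predictors = 10) {
  p <- as.integer(n_predictors)
  df2 <- n - p - 1
  if (any(df2 < 1)) abort("n must exceed n_predictors + 1")
  crit <- qf(1 - alpha, p, df2)
  pf(crit, p, df2, ncp = f2 * n, lower.tail = FALSE)
}

#' Participants-per-node heuristic for network sample size
#'
#' The common rule of 10 participants per network node, inflated for an
#' anticipated share of invalid responses:
#' `minimum = n_nodes * per_node`, `target = ceiling(minimum / (1 - attrition))`.
#'
#' @param n_nodes Number of network nodes.
#' @param per_node Participants required per node; default 10.
#' @param attrition Anticipated invalid-response fraction in `[0, 1)`;
#'   default 0.10.
#' @return A tibble with `minimum` and `target`.
#' @examples
#' heuristic_network_n(52) # minimum 520, target 578
#' @export
heuristic_network_n <- function(n_nodes, per_node = 10, attrition = 0.10) {
  if (n_nodes < 1) abort("n_nodes must be >= 1")
  if (attrition < 0 || attrition >= 1) abort("attrition must be in [0, 1)")
  minimum <- as.integer(n_nodes * per_node)
  tibble(minimum = minimum, target = as.integer(ceiling(minimum / (1 - attrition))))
}
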