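# Summary statistics and randomization (permutation) tests.

#' Summarize a sample as mean, SD and SEM
#'
#' @param values Numeric vector, length >= 1.
#' @return A `summary_stats` list: `n`, `mean`, `sd` (`NA` with
#'   `sd_defined = FALSE` for n = 1), `sem = sd / sqrt(n)`.
#' @examples
#' summarize_values(c(1, 2, 3))  # mean 2, sd 1, sem 1/sqrt(3)
#' @export
summarize_values <- function(values) {
  if (length(values) < 1) stop("empty input")
  n <- length(values)
  s <- if (n >= 2) stats::sd(values) else NA_real_
  structure(list(n = n, mean = mean(values), sd = s,
                 sem = s / sqrt(n), sd_defined = n >= 2),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("n = %d, mean = %.4g, sd = %.4g, sem = %.4g\n",
              x$n, x$mean, x$sd, x$sem))
  invisible(x)
}

#' Two-sided randomization test for a difference between groups
#'
#' Tests the difference of group means (or medians) by permuting group
#' labels. If the number of distinct assignments of group-a labels,
#' `choose(n_a + n_b, n_a)`, is at most `exhaustive_limit`, all
#' assignments are enumerated and the p-value is exact: the proportion of
#' assignments whose absolute statistic is at least the observed one.
#' Otherwise `n_permutations` random label shuffles are drawn and
#' `p = (#{perm >= obs} + 1) / (n_permutations + 1)`, which cannot be
#' zero.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param n_permutations Monte-Carlo permutations (default 10,000).
#' @param seed Optional seed for the Monte-Carlo draw.
#' @param statistic `"mean"` (default) or `"median"`.
#' @param exhaustive_limit Maximum number of assignments to enumerate.
#' @return A `permutation_result`: `observed_diff` (signed
#'   `stat(a) - stat(b)`), `p_value`, `n_permutations` (assignments
#'   evaluated), `exhaustive` flag, `seed`.
#' @examples
#' permutation_test(c(1, 2), c(3, 4))$p_value  # exact: 1/3
#' @export
permutation_test <- function(a, b, n_permutations = 10000, seed = NULL,
                             statistic = c("mean", "median"),
                             exhaustive_limit = 20000) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  statistic <- match.arg(statistic)
  stat_fun <- if (statistic == "mean") mean else stats::median
  pooled <- c(a, b)
  na <- length(a); N <- length(pooled)
  observed <- stat_fun(a) - stat_fun(b)
  obs_abs <- abs(observed)
  tol <- 1e-12 * max(1, obs_abs)

  n_assign <- choose(N, na)
  if (n_assign <= exhaustive_limit) {
    idx <- utils::combn(N, na)
    stats_abs <- apply(idx, 2, function(ii)
      abs(stat_fun(pooled[ii]) - stat_fun(pooled[-ii])))
    p <- mean(stats_abs >= obs_abs - tol)
    res <- list(observed_diff = observed, p_value = p,
                n_permutations = ncol(idx), exhaustive = TRUE, seed = seed)
  } else {
    if (!is.null(seed)) set.seed(seed)
    count <- 0L
    if (statistic == "mean") {
      # |mean_a - mean_b| is monotone in the group-a sum given the pooled
      # total, so only subset sums are needed.
      total <- sum(pooled)
      coef <- 1 / na + 1 / (N - na)
      for (i in seq_len(n_permutations)) {
        sa <- sum(pooled[sample.int(N, na)])
        d <- abs(sa * coef - total / (N - na))
        if (d >= obs_abs - tol) count <- count + 1L
      }
    } else {
      for (i in seq_len(n_permutations)) {
        ii <- sample.int(N, na)
        d <- abs(stat_fun(pooled[ii]) - stat_fun(pooled[-ii]))
        if (d >= obs_abs - tol) count <- count + 1L
      }
    }
    p <- (count + 1) / (n_permutations + 1)
    res <- list(observed_diff = observed, p_value = p,
                n_permutations = n_permutations, exhaustive = FALSE,
                seed = seed)
  }
  structure(res, class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Randomization test: observed diff = %.4g, p = %.4g (%s, %d permutations)\n",
    x$observed_diff, x$p_value,
    if (x$exhaustive) "exhaustive" else "Monte-Carlo", x$n_permutations))
  invisible(x)
}
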