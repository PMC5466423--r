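#' Fisher-Pitman two-sample permutation test on the difference of means
#'
#' Permutation test for a location difference between two independent
#' samples, using the difference of group means as the statistic. In exact
#' mode every assignment of the pooled values to groups of the observed
#' sizes is enumerated and the p-value is the proportion of assignments
#' whose statistic is as or more extreme than observed (two-sided: absolute
#' value; ties count as "as extreme", compared with a small relative
#' tolerance). Monte-Carlo mode samples random assignments and includes the
#' observed one in numerator and denominator.
#'
#' Exact enumeration is used when the number of assignments
#' \eqn{\binom{n}{n_a}} does not exceed `exact_cap`; above the cap the test
#' falls back to Monte-Carlo with a warning (mode `"auto"`).
#'
#' @param group_a,group_b Numeric vectors (each non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` (mean of
#'   `group_a` larger), or `"less"`.
#' @param mode `"auto"`, `"exact"`, or `"monte_carlo"`.
#' @param n_resamples Monte-Carlo resamples (default 1e4).
#' @param exact_cap Maximum number of assignments for exact enumeration
#'   (default 1e6).
#' @param seed Optional integer seed (Monte-Carlo mode).
#' @return List of class `"fp_test"`: `statistic` (observed mean
#'   difference), `p_value`, `alternative`, `method` (description
#'   including the number of assignments or resamples).
#' @examples
#' fisher_pitman_test(c(1, 2), c(3, 4))  # exact: p = 1/3
#' @export
fisher_pitman_test <- function(group_a, group_b,
                               alternative = c("two.sided", "greater", "less"),
                               mode = c("auto", "exact", "monte_carlo"),
                               n_resamples = 1e4,
                               exact_cap = 1e6,
                               seed = NULL) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  stopifnot(is.numeric(group_a), is.numeric(group_b))
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(group_a, group_b)
  n <- length(pooled)
  n_a <- length(group_a)
  obs <- mean(group_a) - mean(group_b)

  n_assign <- choose(n, n_a)
  if (mode == "exact" && n_assign > exact_cap) {
    warning(sprintf(
      "exact enumeration needs %.3g assignments (cap %.3g); falling back to Monte-Carlo",
      n_assign, exact_cap), call. = FALSE)
    mode <- "monte_carlo"
  }
  if (mode == "auto")
    mode <- if (n_assign <= exact_cap) "exact" else "monte_carlo"

  # difference of means is a monotone function of the group-a sum:
  # diff = sum_a / n_a - (total - sum_a) / n_b
  n_b <- n - n_a
  total <- sum(pooled)
  diff_from_sum <- function(sum_a) sum_a / n_a - (total - sum_a) / n_b
  tol <- 1e-8 * max(1, abs(obs), abs(diff(range(pooled))))

  if (mode == "exact") {
    sums <- utils::combn(pooled, n_a, sum)
    diffs <- diff_from_sum(sums)
    p <- switch(alternative,
      two.sided = mean(abs(diffs) >= abs(obs) - tol),
      greater   = mean(diffs >= obs - tol),
      less      = mean(diffs <= obs + tol))
    method <- sprintf("exact permutation (%d assignments)", length(diffs))
  } else {
    if (!is.null(seed)) set.seed(seed)
    sums <- vapply(seq_len(n_resamples),
                   function(i) sum(pooled[sample.int(n, n_a)]),
                   numeric(1))
    diffs <- diff_from_sum(sums)
    extreme <- switch(alternative,
      two.sided = sum(abs(diffs) >= abs(obs) - tol),
      greater   = sum(diffs >= obs - tol),
      less      = sum(diffs <= obs + tol))
    p <- (1 + extreme) / (1 + n_resamples)    # include the observed split
    method <- sprintf("Monte-Carlo permutation (%d resamples)", n_resamples)
  }

  structure(
    list(statistic = obs, p_value = p, alternative = alternative,
         method = method),
    class = "fp_test"
  )
}

#' @export
print.fp_test <- function(x, ...) {
  cat(sprintf("Fisher-Pitman permutation test (%s)\n", x$method))
  cat(sprintf("  mean difference = %.4g, %s p = %.4g\n",
              x$statistic, x$alternative, x$p_value))
  invisible(x)
}

#' Exact binomial test
#'
#' Exact test of an observed success count against a null success
#' probability `p0` (e.g. the probability that a substrate shows the same
#' four-strain convergence pattern by chance, \eqn{2 \times 0.5^4 =
#' 0.125}). One-sided p-values are binomial tail sums; the two-sided
#' p-value sums the probabilities of all outcomes no more likely than the
#' observed one (the small-p-values method of [stats::binom.test()], which
#' this wraps).
#'
#' @param k Observed successes (`0 <= k <= n`).
#' @param n Trials.
#' @param p0 Null success probability, in `(0, 1)`.
#' @param alternative `"two.sided"`, `"greater"`, or `"less"`.
#' @return List of class `"exact_binomial"`: `statistic` (= `k`), `n`,
#'   `p0`, `p_value`, `alternative`, `method`.
#' @examples
#' exact_binomial_test(k = 2, n = 4, p0 = 0.5, alternative = "greater")
#' @export
exact_binomial_test <- function(k, n, p0 = 0.5,
                                alternative = c("two.sided", "greater",
                                                "less")) {
  alternative <- match.arg(alternative)
  stopifnot(is.numeric(k), is.numeric(n), is.numeric(p0))
  if (n < 1 || n != floor(n)) stop("`n` must be a positive integer",
                                   call. = FALSE)
  if (k < 0 || k > n || k != floor(k))
    stop("`k` must be an integer in [0, n]", call. = FALSE)
  if (p0 <= 0 || p0 >= 1) stop("`p0` must lie in (0, 1)", call. = FALSE)
  ht <- stats::binom.test(k, n, p = p0, alternative = alternative)
  structure(
    list(statistic = k, n = n, p0 = p0, p_value = ht$p.value,
         alternative = alternative, method = "exact binomial test"),
    class = "exact_binomial"
  )
}

#' @export
print.exact_binomial <- function(x, ...) {
  cat(sprintf("Exact binomial test: %d/%d successes vs p0 = %.4g, %s p = %.4g\n",
              x$statistic, x$n, x$p0, x$alternative, x$p_value))
  invisible(x)
}
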