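#' Exact test on a 2x2 contingency table
#'
#' Hypergeometric exact test of association in a 2x2 table with rows as
#' groups and columns as outcome (yes/no). The two-sided p-value follows
#' the minimum-likelihood rule: it sums the probabilities of all tables
#' with the same margins whose point probability does not exceed that of
#' the observed table. The one-sided p-value is the exact tail in the
#' direction of the observed association.
#'
#' @param a,b,c,d Non-negative integer cell counts: `a`/`b` are the
#'   yes/no counts in group 1, `c`/`d` in group 2.
#' @param sidedness `"two"` (default) or `"one"`.
#' @return A `test_result` list with `statistic` (odds-ratio estimate),
#'   `pvalue`, `sidedness` and `method`.
#' @examples
#' fisher_exact(9, 51, 3, 126)$pvalue   # ~1.9e-3
#' @export
fisher_exact <- function(a, b, c, d, sidedness = c("two", "one")) {
  sidedness <- match.arg(sidedness)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("2x2 table has an empty margin; the exact test is undefined")
  }
  alternative <- "two.sided"
  if (sidedness == "one") {
    # tail of the observed direction (cross-product sign)
    alternative <- if (a * d >= b * c) "greater" else "less"
  }
  ft <- stats::fisher.test(tab, alternative = alternative)
  test_result(
    statistic = unname(ft$estimate),
    pvalue = ft$p.value,
    sidedness = sidedness,
    method = "Fisher exact test"
  )
}

#' Ratio of two proportions
#'
#' Fold ratio `(k1/n1) / (k2/n2)` used to report enrichment between two
#' groups (e.g. loci replicating in a second GWAS versus controls).
#'
#' @param k1,n1 Successes and size of the first group.
#' @param k2,n2 Successes and size of the second group.
#' @return The fold ratio; `NA` with a warning when `k2 = 0`.
#' @examples
#' fold_ratio(9, 60, 3, 129)  # 6.45
#' @export
fold_ratio <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
  if (k2 == 0) {
    warning("k2 = 0: fold ratio undefined")
    return(NA_real_)
  }
  (k1 / n1) / (k2 / n2)
}

#' Exact binomial test
#'
#' Exact binomial tail test of `k` successes in `n` trials against
#' success probability `p0`. The two-sided p-value uses the
#' minimum-likelihood rule (at `p0 = 0.5` this equals twice the smaller
#' tail, capped at 1).
#'
#' @param k,n Observed successes and number of trials.
#' @param p0 Null success probability, in (0, 1). Default 0.5.
#' @param sidedness `"two"` (default) or `"one"` (tail of the observed
#'   direction).
#' @return A `test_result` list.
#' @examples
#' binomial_exact(97, 397)$pvalue  # ~3.1e-25
#' @export
binomial_exact <- function(k, n, p0 = 0.5, sidedness = c("two", "one")) {
  sidedness <- match.arg(sidedness)
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  alternative <- "two.sided"
  if (sidedness == "one") {
    alternative <- if (k >= n * p0) "greater" else "less"
  }
  bt <- stats::binom.test(k, n, p = p0, alternative = alternative)
  test_result(
    statistic = k,
    pvalue = bt$p.value,
    sidedness = sidedness,
    method = "exact binomial test"
  )
}

#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Rank-sum comparison of two samples. The exact permutation null
#' distribution (computed over midranks with a shift-algorithm
#' recursion, so ties are handled) is used when the product of group
#' sizes is at most 400; otherwise a tie-corrected normal approximation
#' with continuity correction is used.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"` (default), `"greater"` (x tends
#'   larger) or `"less"`.
#' @return A `test_result` list; `statistic` is the Mann-Whitney U for
#'   `x` versus `y`.
#' @examples
#' rank_sum(c(3, 4), c(1, 2), alternative = "greater")$pvalue  # 1/6
#' @export
rank_sum <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) < 1 || length(y) < 1) stop("both groups must be non-empty")
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(pooled)) == 1L) {
    # all observations identical: no evidence either way
    return(test_result(
      statistic = u_stat, pvalue = 1,
      sidedness = if (alternative == "two.sided") "two" else "one",
      method = "Wilcoxon rank-sum (degenerate: all values tied)"
    ))
  }
  exact <- n1 * length(y) <= 400
  if (exact) {
    pvalue <- exact_rank_sum_p(x, y, alternative)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(
      x, y,
      alternative = alternative, exact = FALSE, correct = TRUE
    ))
    pvalue <- wt$p.value
  }
  test_result(
    statistic = u_stat,
    pvalue = min(1, pvalue),
    sidedness = if (alternative == "two.sided") "two" else "one",
    method = if (exact) "Wilcoxon rank-sum (exact permutation)" else
      "Wilcoxon rank-sum (normal approximation, tie-corrected)"
  )
}

# Exact permutation p-value of the rank-sum statistic under random
# group assignment, via the shift-algorithm recursion on doubled
# midranks (integers even with ties). Two-sided = doubled smaller
# tail, capped at 1.
exact_rank_sum_p <- function(x, y, alternative) {
  n1 <- length(x)
  n <- n1 + length(y)
  scores <- as.integer(round(2 * rank(c(x, y))))
  w_obs <- sum(scores[seq_len(n1)])
  max_s <- sum(sort(scores, decreasing = TRUE)[seq_len(n1)])
  # ways[k + 1, s + 1] = number of k-subsets of processed scores
  # summing to s
  ways <- matrix(0, nrow = n1 + 1, ncol = max_s + 1)
  ways[1, 1] <- 1
  for (v in scores) {
    for (k in n1:1) {
      cols <- (v + 1):(max_s + 1)
      ways[k + 1, cols] <- ways[k + 1, cols] +
        ways[k, seq_len(max_s + 1 - v)]
    }
  }
  dist <- ways[n1 + 1, ] / choose(n, n1)
  p_ge <- sum(dist[(w_obs + 1):(max_s + 1)])
  p_le <- sum(dist[seq_len(w_obs + 1)])
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

#' Cohort size required to reach a target power
#'
#' Projects the GWAS cohort size needed to detect an association at a
#' two-sided significance level `alpha` with power `power_target`, given
#' that a cohort of `n_current` individuals has power `power_current`.
#' The model is a two-sided normal test whose non-centrality parameter
#' (NCP, the mean of the association z-statistic) scales with the square
#' root of the sample size:
#' NCP_current = z_(alpha/2) - qnorm(1 - power_current),
#' NCP_target  = z_(alpha/2) + qnorm(power_target),
#' n_required  = n_current * (NCP_target / NCP_current)^2.
#'
#' @param alpha Two-sided significance level (default genome-wide 5e-8).
#' @param power_current Power of the current cohort, in (0, 1).
#' @param n_current Effective size of the current cohort.
#' @param power_target Desired power, in (0, 1).
#' @return A list with `n_required` (raw), `n_rounded` (nearest hundred),
#'   `ncp_current` and `ncp_target`.
#' @examples
#' required_n_for_power(5e-8, 0.1276, 68900, 0.80)$n_rounded
#' @export
required_n_for_power <- function(alpha = 5e-8, power_current, n_current,
                                 power_target) {
  stopifnot(
    alpha > 0, alpha < 1,
    power_current > 0, power_current < 1,
    power_target > 0, power_target < 1,
    n_current > 0
  )
  z_half <- stats::qnorm(1 - alpha / 2)
  ncp_current <- z_half - stats::qnorm(1 - power_current)
  if (ncp_current <= 0) {
    stop("power_current is at or below the level implied by alpha alone; ",
         "the NCP is non-positive and no projection is possible")
  }
  ncp_target <- z_half + stats::qnorm(power_target)
  n_required <- n_current * (ncp_target / ncp_current)^2
  list(
    n_required = n_required,
    n_rounded = round(n_required / 100) * 100,
    ncp_current = ncp_current,
    ncp_target = ncp_target
  )
}

#' Power of a two-sided normal test at a given NCP
#'
#' Detection probability of a z-statistic with mean `ncp` under a
#' two-sided test at level `alpha`.
#'
#' @param ncp Non-centrality parameter (mean of the z-statistic), >= 0.
#' @param alpha Two-sided significance level.
#' @return Detection probability.
#' @export
power_at_ncp <- function(ncp, alpha = 5e-8) {
  stopifnot(ncp >= 0, alpha > 0, alpha < 1)
  z_half <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(ncp - z_half) + stats::pnorm(-ncp - z_half)
}

#' Permutation empirical p-value
#'
#' Upper-tail empirical p-value with add-one correction:
#' `(1 + #\{null >= observed\}) / (1 + n_null)`. Never returns zero.
#'
#' @param observed Observed statistic.
#' @param null_values Numeric vector of null statistics.
#' @return Empirical p-value in (0, 1].
#' @export
empirical_p <- function(observed, null_values) {
  if (length(null_values) < 1) stop("need at least one null value")
  (1 + sum(null_values >= observed)) / (1 + length(null_values))
}

#' Equal-tailed Beta posterior interval for a proportion
#'
#' Posterior interval for a binomial proportion under a uniform
#' Beta(1, 1) prior: the equal-tailed `level` interval of
#' Beta(k + 1, n - k + 1). A convenience helper for summarizing
#' validation rates; interval conventions differ between analyses, so
#' results under other priors will differ.
#'
#' @param k,n Successes and trials.
#' @param level Interval mass (default 0.95).
#' @return Length-2 vector (lower, upper).
#' @export
beta_interval <- function(k, n, level = 0.95) {
  stopifnot(k >= 0, k <= n, level > 0, level < 1)
  tail <- (1 - level) / 2
  stats::qbeta(c(tail, 1 - tail), k + 1, n - k + 1)
}

test_result <- function(statistic, pvalue, sidedness, method) {
  structure(
    list(statistic = statistic, pvalue = pvalue, sidedness = sidedness,
         method = method),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, " (", x$sidedness, "-sided)\n", sep = "")
  cat("  statistic =", format(x$statistic), " p =", format(x$pvalue), "\n")
  invisible(x)
}
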