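# Nonparametric two-group comparison and box-plot summaries.
#
# The exact Mann-Whitney p-value is the null probability of a U statistic at
# least as far from its mean n1*n2/2 as the observed one, computed from the
# exact permutation distribution: an integer dynamic program over rank-sum
# counts when there are no ties, full enumeration of the C(N, n1) midrank
# assignments when there are. Counts stay below C(20,10) = 184756 on the
# exact path, so all arithmetic is exact in doubles.

#' Exact null distribution of the Mann-Whitney U statistic (no ties)
#'
#' Classical recurrence: the number of subsets of ranks summing to a given
#' rank sum, built by convolution. Returns counts over U = 0..n1*n2.
#'
#' @param n1,n2 group sizes.
#' @return numeric vector `counts` with `counts[u + 1]` the number of
#'   labelings giving U = u; sums to `choose(n1 + n2, n1)`.
#' @keywords internal
mw_null_counts <- function(n1, n2) {
  # c(a, b, u) = c(a-1, b, u-b) + c(a, b-1, u); built row by row in a.
  # All counts are integers < C(24,12), exact in doubles.
  prev <- rep(list(1), n2 + 1L)            # a = 0: point mass at u = 0
  for (a in seq_len(n1)) {
    cur <- vector("list", n2 + 1L)
    cur[[1L]] <- 1                          # b = 0
    for (b in seq_len(n2)) {
      v1 <- prev[[b + 1L]]                  # f(a-1, b), shifted by b
      v2 <- cur[[b]]                        # f(a, b-1)
      out <- numeric(a * b + 1L)
      out[b + seq_along(v1)] <- v1
      out[seq_along(v2)] <- out[seq_along(v2)] + v2
      cur[[b + 1L]] <- out
    }
    prev <- cur
  }
  prev[[n2 + 1L]]
}

# two-sided exact p from a null distribution of U given observed u; all
# quantities are exact binary fractions so comparisons are exact
two_sided_exact_p <- function(counts, u_obs, mu) {
  u <- seq_along(counts) - 1
  extreme <- abs(u - mu) >= abs(u_obs - mu)
  sum(counts[extreme]) / sum(counts)
}

# exact enumeration with ties: doubled midranks are integers, so U*2 is an
# integer and tail comparisons are exact
mw_exact_ties <- function(ranks2, n1, u_obs2, mu2) {
  N <- length(ranks2)
  combos <- utils::combn(N, n1)
  rs2 <- colSums(matrix(ranks2[combos], nrow = n1))
  u2 <- rs2 - n1 * (n1 + 1L)            # 2*U for each labeling
  mean(abs(u2 - mu2) >= abs(u_obs2 - mu2))
}

#' Mann-Whitney U test
#'
#' Rank-based two-sample test. U is computed from midranks. With
#' `method = "auto"`, the exact two-sided p-value (null probability of a U at
#' least as far from n1 n2 / 2 as observed, conditional on the tie pattern)
#' is used whenever \eqn{n_1 + n_2 \le 20}; larger samples use the normal
#' approximation with tie and continuity corrections. Stars follow the
#' convention * p < 0.05, ** p < 0.01 (strict inequalities).
#'
#' @param x,y numeric samples.
#' @param method `"auto"`, `"exact"` or `"normal_approx"`.
#' @return list with `n1`, `n2`, `U` (for `x`), `p_two_sided`, `method`
#'   (`"exact"` or `"normal_approx"`) and `stars`.
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact", "normal_approx")) {
  method <- match.arg(method)
  x <- as.double(x); y <- as.double(y)
  if (!length(x) || !length(y)) abort("empty sample")
  if (anyNA(x) || anyNA(y)) abort("NA values in sample")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  ranks <- rank(c(x, y))
  U <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- anyDuplicated(c(x, y)) > 0L

  use_exact <- switch(method,
    exact = TRUE,
    normal_approx = FALSE,
    auto = N <= 20L)
  if (use_exact && N > 24L)
    abort("exact enumeration infeasible for n1 + n2 > 24; use normal_approx")

  if (use_exact) {
    if (!ties) {
      counts <- mw_null_counts(n1, n2)
      p <- two_sided_exact_p(counts, U, mu)
    } else {
      ranks2 <- as.integer(round(2 * ranks))
      p <- mw_exact_ties(ranks2, n1, as.integer(round(2 * U)),
                         as.integer(round(2 * mu)))
    }
    used <- "exact"
  } else {
    tie_tab <- table(c(x, y))
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
    used <- "normal_approx"
  }
  list(n1 = n1, n2 = n2, U = U, p_two_sided = p, method = used,
       stars = stars(p))
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard W-statistic implementation with the
#' package's input contract (3 \eqn{\le} n \eqn{\le} 5000, non-degenerate).
#'
#' @param x numeric sample.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- as.double(x)
  if (length(x) < 3L || length(x) > 5000L)
    abort("shapiro_wilk needs 3 <= n <= 5000")
  if (stats::var(x) == 0) abort("constant sample: W undefined")
  ht <- stats::shapiro.test(x)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Box-plot summary statistics
#'
#' Median, quartiles by linear interpolation between order statistics
#' (quantile type 7 — the documented convention), min-max whiskers and n.
#'
#' @param x numeric sample.
#' @return list with `median`, `q1`, `q3`, `min`, `max`, `n`.
#' @export
box_summary <- function(x) {
  x <- as.double(x)
  if (!length(x) || anyNA(x)) abort("box_summary needs a complete, non-empty sample")
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  list(median = q[2], q1 = q[1], q3 = q[3], min = min(x), max = max(x),
       n = length(x))
}

#' Significance stars
#'
#' `"*"` for p < 0.05, `"**"` for p < 0.01, otherwise `""` (strict
#' inequalities: p = 0.05 exactly earns no star).
#'
#' @param p p-value.
#' @return string.
#' @export
stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}
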