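# Rank-based test statistics used by the polar-effect analyses.
#
# The two-sample rank-sum test is implemented directly so that the exact
# branch enumerates the permutation distribution even in the presence of
# ties (base wilcox.test falls back to the normal approximation there);
# the large-sample branch uses the standard normal approximation with tie
# and continuity corrections.

new_test_result <- function(statistic, p_value, n1, n2, method,
                            estimate = NA_real_, ...) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 n1 = n1, n2 = n2, method = method,
                 estimate = unname(estimate), ...),
            class = "polar_test")
}

#' @export
print.polar_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.na(x$estimate)) cat("  estimate  =", format(x$estimate), "\n")
  cat("  statistic =", format(x$statistic), "\n")
  cat("  p-value   =", format.pval(x$p_value), "  (unadjusted)\n")
  cat("  n         =", x$n1, if (!is.na(x$n2)) paste0("vs ", x$n2), "\n")
  invisible(x)
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Compares the locations of two samples by the Mann-Whitney U statistic
#' (number of pairs where `x` exceeds `y`, counting ties as 1/2). For
#' `n1 + n2 <= exact_limit` the p-value is exact, obtained by enumerating
#' every assignment of the pooled observations into two groups of the
#' observed sizes (valid with ties); otherwise the normal approximation
#' with tie correction and a 0.5 continuity correction is used.
#'
#' @param x,y Numeric vectors (the two samples).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (location of `x` relative to `y`).
#' @param exact_limit Largest pooled size for which the exact enumeration
#'   is used.
#' @return A `"polar_test"` result: `statistic` (U), `p_value`, group
#'   sizes `n1`/`n2`, and the method used.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6), alternative = "less")$p_value  # 0.05
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "less", "greater"),
                          exact_limit = 12L) {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("empty group in rank-sum test")
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  mu <- n1 * n2 / 2
  if (n <= exact_limit) {
    idx <- utils::combn(n, n1)
    rank_sums <- colSums(matrix(r[idx], nrow = n1))
    u_all <- rank_sums - n1 * (n1 + 1) / 2
    eps <- 1e-8
    p <- switch(alternative,
      two.sided = mean(abs(u_all - mu) >= abs(u - mu) - eps),
      greater   = mean(u_all >= u - eps),
      less      = mean(u_all <= u + eps))
    method <- "Wilcoxon rank sum test (exact enumeration)"
  } else {
    ties <- table(r)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {  # all values tied
      p <- 1
    } else {
      sigma <- sqrt(sigma2)
      z <- switch(alternative,
        two.sided = (u - mu - sign(u - mu) * 0.5) / sigma,
        greater   = (u - mu - 0.5) / sigma,
        less      = (u - mu + 0.5) / sigma)
      p <- switch(alternative,
        two.sided = 2 * stats::pnorm(-abs(z)),
        greater   = stats::pnorm(z, lower.tail = FALSE),
        less      = stats::pnorm(z))
    }
    p <- min(1, p)
    method <- "Wilcoxon rank sum test (normal approximation)"
  }
  new_test_result(u, p, n1, n2, method)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Ranks both variables (average ranks for ties), computes the Pearson
#' correlation of the ranks, and derives a two-sided p-value from the
#' t distribution with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length; pairs with missing values
#'   are dropped.
#' @return A `"polar_test"` with `estimate` = rho.
#' @export
spearman_test <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs for a correlation")
  rho <- stats::cor(rank(x), rank(y))
  p <- cor_t_pvalue(rho, n)
  new_test_result(rho, p, n, NA_integer_,
                  "Spearman rank correlation (t approximation)",
                  estimate = rho)
}

#' Pearson correlation test
#'
#' @param x,y Numeric vectors of equal length; pairs with missing values
#'   are dropped.
#' @return A `"polar_test"` with `estimate` = r.
#' @export
pearson_test <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs for a correlation")
  r <- stats::cor(x, y)
  p <- cor_t_pvalue(r, n)
  new_test_result(r, p, n, NA_integer_, "Pearson correlation", estimate = r)
}

cor_t_pvalue <- function(r, n) {
  if (is.na(r)) return(NA_real_)
  if (abs(r) >= 1) return(0)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}
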