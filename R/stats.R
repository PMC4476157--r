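#' Directional test-result container
#'
#' Light-weight record for the directional tests used throughout the
#' package; `tidy()` turns it into a one-row tibble.
#'
#' @param statistic Test statistic.
#' @param p_value P-value in \[0, 1\].
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @param method Label describing the test and whether an exact or
#'   approximate path was taken.
#' @param estimate Optional point estimate (e.g. a correlation).
#' @return An object of class `reg_test`.
#' @export
reg_test <- function(statistic, p_value, alternative, method,
                     estimate = NULL) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(list(statistic = unname(statistic),
                 p_value = min(unname(p_value), 1),
                 alternative = alternative, method = method,
                 estimate = estimate),
            class = "reg_test")
}

#' @export
print.reg_test <- function(x, ...) {
  cat("<reg_test> ", x$method, "\n", sep = "")
  if (!is.null(x$estimate)) {
    cat("  estimate = ", format(x$estimate, digits = 4), "\n", sep = "")
  }
  cat("  statistic = ", format(x$statistic, digits = 4),
      ", p = ", format(x$p_value, digits = 4),
      " (", x$alternative, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.reg_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic,
                 estimate = x$estimate %||% NA_real_,
                 p_value = x$p_value,
                 alternative = x$alternative,
                 method = x$method)
}

#' One-tailed exact binomial test
#'
#' Exact tail sum of Binomial(n, p0): `alternative = "greater"` gives
#' P(X >= k), `"less"` gives P(X <= k).
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param p0 Null success proportion, strictly inside (0, 1).
#' @param alternative `"greater"` or `"less"`.
#' @return A [reg_test()].
#' @examples
#' binom_test(10, 10, 0.5, "greater")$p_value  # (1/2)^10
#' @export
binom_test <- function(k, n, p0, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (p0 <= 0 || p0 >= 1) abort("`p0` must be strictly inside (0, 1).")
  if (k < 0 || k > n) abort("Need 0 <= k <= n.")
  p <- if (alternative == "greater") {
    sum(dbinom(k:n, n, p0))
  } else {
    sum(dbinom(0:k, n, p0))
  }
  reg_test(statistic = k, p_value = p, alternative = alternative,
           method = "exact binomial test")
}

#' One-tailed Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric tail on the (1,1) cell with margins fixed.
#' `alternative = "greater"` sums probabilities of tables with a (1,1) cell
#' at least as large as observed.
#'
#' @param table 2x2 matrix of nonnegative integers; all margins must be
#'   positive.
#' @param alternative `"greater"` or `"less"`.
#' @return A [reg_test()].
#' @export
fisher_exact <- function(table, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0)) {
    abort("`table` must be a nonnegative 2x2 matrix.")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("All margins of `table` must be positive.")
  }
  a <- table[1, 1]
  R1 <- sum(table[1, ]); R2 <- sum(table[2, ]); C1 <- sum(table[, 1])
  lo <- max(0, C1 - R2); hi <- min(R1, C1)
  support <- lo:hi
  probs <- dhyper(support, R1, R2, C1)
  p <- if (alternative == "greater") sum(probs[support >= a]) else
    sum(probs[support <= a])
  reg_test(statistic = a, p_value = p, alternative = alternative,
           method = "one-tailed Fisher's exact test")
}

#' Hypergeometric enrichment test
#'
#' Upper-tail hypergeometric probability P(X >= k) of drawing `k` or more
#' category members in `n` draws without replacement from a universe of
#' size `N` containing `K` category members — the classic over-representation
#' test.
#'
#' @param k Observed hits.
#' @param K Category size in the universe.
#' @param n Number of draws (e.g. size of the gene set).
#' @param N Universe size.
#' @return A [reg_test()].
#' @export
hypergeom_enrichment <- function(k, K, n, N) {
  if (K > N || n > N || k > min(K, n) || any(c(k, K, n, N) < 0)) {
    abort("Inconsistent hypergeometric arguments (need k <= min(K, n) <= N).")
  }
  lo <- max(0, n - (N - K)); hi <- min(K, n)
  support <- lo:hi
  p <- sum(dhyper(support[support >= k], K, N - K, n))
  reg_test(statistic = k, p_value = p, alternative = "greater",
           method = "hypergeometric enrichment test")
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact null distribution of the Mann-Whitney U statistic when the pooled
#' sample size is at most `exact_max` and there are no ties; with ties, an
#' exact permutation distribution conditional on the observed values is
#' enumerated when the pooled size is at most 12; otherwise a normal
#' approximation with tie correction and continuity correction is used. The
#' `method` field records which path was taken. `alternative = "greater"`
#' tests whether `x` tends to exceed `y`.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param alternative `"greater"` or `"less"` (direction of `x` vs `y`).
#' @param exact_max Largest pooled size for the tie-free exact path
#'   (default 20).
#' @return A [reg_test()]; `statistic` is the Mann-Whitney U of `x`.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("greater", "less"),
                              exact_max = 20) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) abort("Both samples must be non-empty.")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && nx + ny <= exact_max) {
    p <- if (alternative == "greater") {
      1 - pwilcox(u - 1, nx, ny)
    } else {
      pwilcox(u, nx, ny)
    }
    method <- "Wilcoxon rank-sum test (exact)"
  } else if (ties && nx + ny <= 12) {
    combs <- combn(nx + ny, nx)
    u_all <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
    p <- if (alternative == "greater") mean(u_all >= u - 1e-9) else
      mean(u_all <= u + 1e-9)
    method <- "Wilcoxon rank-sum test (exact permutation, ties)"
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(r)
    sigma2 <- nx * ny / 12 *
      ((nx + ny + 1) - sum(tie_tab^3 - tie_tab) /
         ((nx + ny) * (nx + ny - 1)))
    sigma <- sqrt(sigma2)
    z <- if (alternative == "greater") (u - mu - 0.5) / sigma else
      (u - mu + 0.5) / sigma
    p <- if (alternative == "greater") pnorm(z, lower.tail = FALSE) else
      pnorm(z)
    method <- "Wilcoxon rank-sum test (normal approximation)"
  }
  reg_test(statistic = u, p_value = p, alternative = alternative,
           method = method)
}

#' Spearman's rank correlation
#'
#' Rho is computed from (average-rank) ranked data. The p-value comes from
#' the exact permutation distribution when n <= `exact_max` and there are no
#' ties, otherwise from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y Paired numeric samples of equal length >= 3.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param exact_max Largest n for the exact permutation path (default 8).
#' @return A [reg_test()] with `estimate` = rho.
#' @export
spearman_cor <- function(x, y, alternative = c("two.sided", "greater", "less"),
                         exact_max = 8) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 3) abort("Need at least 3 pairs.")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  ties <- any(duplicated(x)) || any(duplicated(y))
  if (!ties && n <= exact_max) {
    perms <- all_permutations(n)
    # rho is monotone in the sum of rank products
    s_obs <- sum(rx * ry)
    s_perm <- as.vector(perms %*% ry[order(rx)])
    eps <- 1e-9
    p_ge <- mean(s_perm >= s_obs - eps)
    p_le <- mean(s_perm <= s_obs + eps)
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    method <- "Spearman's rank correlation (exact permutation)"
  } else {
    if (abs(rho) >= 1) {
      p_one <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p_one <- pt(tstat, df = n - 2, lower.tail = FALSE)
    }
    p <- switch(alternative,
                greater = if (rho >= 0) p_one else 1 - p_one,
                less = if (rho >= 0) 1 - p_one else p_one,
                two.sided = min(1, 2 * min(p_one, 1 - p_one)))
    if (abs(rho) >= 1) {
      p <- switch(alternative,
                  greater = if (rho > 0) 0 else 1,
                  less = if (rho < 0) 0 else 1,
                  two.sided = 0)
    }
    method <- "Spearman's rank correlation (t approximation)"
  }
  reg_test(statistic = rho, p_value = p, alternative = alternative,
           method = method, estimate = rho)
}

# All permutations of 1..n as a (n!) x n matrix; fine for n <= 8.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                   sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out[row:(row + nrow(sub) - 1), ] <- block
    row <- row + nrow(sub)
  }
  out
}
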