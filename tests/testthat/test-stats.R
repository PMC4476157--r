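test_that("binomial tail sums match hand values and base R", {
  expect_equal(binom_test(10, 10, 0.5, "greater")$p_value, 0.0009765625)
  expect_equal(binom_test(0, 10, 0.5, "greater")$p_value, 1)
  expect_equal(binom_test(7, 10, 0.5, "greater")$p_value, 176 / 1024)
  expect_error(binom_test(3, 10, 0), "p0")
  expect_error(binom_test(11, 10, 0.5), "k <= n")

  for (n in c(1, 4, 9, 12)) {
    for (k in 0:n) {
      for (p0 in c(0.2, 0.5, 0.8)) {
        expect_equal(
          binom_test(k, n, p0, "greater")$p_value,
          stats::binom.test(k, n, p0, alternative = "greater")$p.value
        )
        expect_equal(
          binom_test(k, n, p0, "less")$p_value,
          stats::binom.test(k, n, p0, alternative = "less")$p.value
        )
      }
    }
  }
})

test_that("Fisher's exact test matches enumeration and base R on all small tables", {
  expect_equal(fisher_exact(rbind(c(5, 0), c(0, 5)), "greater")$p_value,
               1 / 252)
  expect_equal(fisher_exact(rbind(c(1, 1), c(1, 1)), "greater")$p_value,
               5 / 6)
  expect_equal(fisher_exact(rbind(c(0, 5), c(5, 0)), "greater")$p_value, 1)
  expect_error(fisher_exact(rbind(c(1, 0), c(2, 0))), "margins")

  # every 2x2 table with N <= 12 and positive margins
  for (N in 2:12) {
    parts <- expand.grid(a = 0:N, b = 0:N, c = 0:N)
    parts$d <- N - parts$a - parts$b - parts$c
    parts <- parts[parts$d >= 0, ]
    for (r in seq_len(nrow(parts))) {
      tab <- rbind(c(parts$a[r], parts$b[r]), c(parts$c[r], parts$d[r]))
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(
        fisher_exact(tab, "greater")$p_value,
        stats::fisher.test(tab, alternative = "greater")$p.value,
        tolerance = 1e-12
      )
      expect_equal(
        fisher_exact(tab, "less")$p_value,
        stats::fisher.test(tab, alternative = "less")$p.value,
        tolerance = 1e-12
      )
    }
  }
})

test_that("hypergeometric enrichment equals the Fisher upper tail", {
  expect_equal(hypergeom_enrichment(5, 5, 5, 10)$p_value, 1 / 252)
  expect_equal(hypergeom_enrichment(0, 4, 5, 10)$p_value, 1)
  expect_equal(hypergeom_enrichment(2, 4, 5, 10)$p_value,
               fisher_exact(rbind(c(2, 3), c(2, 3)), "greater")$p_value)
  expect_error(hypergeom_enrichment(6, 5, 5, 10), "Inconsistent")

  set.seed(7)
  for (i in 1:50) {
    N <- sample(4:12, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    k <- sample(max(0, K + n - N):min(K, n), 1)
    tab <- rbind(c(k, n - k), c(K - k, N - K - n + k))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(hypergeom_enrichment(k, K, n, N)$p_value,
                 fisher_exact(tab, "greater")$p_value)
  }
})

test_that("rank-sum exact path matches brute-force enumeration", {
  expect_equal(wilcoxon_rank_sum(1:3, 4:6, "less")$p_value, 1 / 20)
  expect_equal(wilcoxon_rank_sum(1:2, 3:4, "less")$p_value, 1 / 6)
  expect_match(wilcoxon_rank_sum(1:3, 4:6, "less")$method, "exact")
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "non-empty")

  set.seed(11)
  for (i in 1:30) {
    nx <- sample(2:6, 1)
    ny <- sample(2:6, 1)
    vals <- sample(1:50, nx + ny)  # no ties
    x <- vals[seq_len(nx)]
    y <- vals[-seq_len(nx)]
    for (alt in c("greater", "less")) {
      expect_equal(wilcoxon_rank_sum(x, y, alt)$p_value,
                   enumerate_ranksum_p(x, y, alt))
      expect_equal(wilcoxon_rank_sum(x, y, alt)$p_value,
                   stats::wilcox.test(x, y, alternative = alt,
                                      exact = TRUE)$p.value)
    }
  }
})

test_that("rank-sum approximation is symmetric under the null and tie-corrected", {
  res <- wilcoxon_rank_sum(1:10, 1:10, "greater")
  expect_match(res$method, "approximation")
  expect_equal(res$p_value, 0.5, tolerance = 0.05)

  # large-sample approximate path agrees with base R's corrected normal
  set.seed(3)
  x <- rpois(15, 10)
  y <- rpois(12, 12)
  expect_equal(
    wilcoxon_rank_sum(x, y, "less")$p_value,
    stats::wilcox.test(x, y, alternative = "less", exact = FALSE,
                       correct = TRUE)$p.value
  )
})

test_that("Spearman correlation handles perfect ranks, exact and approximate p", {
  expect_equal(spearman_cor(1:4, c(10, 20, 30, 40))$estimate, 1)
  expect_equal(spearman_cor(1:4, c(40, 30, 20, 10))$estimate, -1)
  expect_equal(spearman_cor(c(1, 2, 3), c(1, 3, 2))$estimate, 0.5)
  expect_error(spearman_cor(1:3, 1:4), "equal length")

  set.seed(5)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    x <- sample(1:100, n)
    y <- sample(1:100, n)
    ct <- stats::cor.test(x, y, method = "spearman",
                          alternative = "greater")
    res <- spearman_cor(x, y, "greater")
    expect_equal(res$estimate, unname(ct$estimate))
    expect_equal(res$p_value, ct$p.value, tolerance = 1e-10)
  }

  # t-approximation path (n > 8)
  x <- c(1, 3, 2, 5, 4, 7, 6, 9, 8, 10)
  y <- 1:10
  res <- spearman_cor(x, y, "greater")
  expect_match(res$method, "t approximation")
  expect_true(res$p_value < 0.01)
})

test_that("one-tailed p-values of opposite directions overlap at or above 1", {
  set.seed(13)
  for (i in 1:20) {
    k <- sample(0:10, 1)
    pg <- binom_test(k, 10, 0.4, "greater")$p_value
    pl <- binom_test(k, 10, 0.4, "less")$p_value
    expect_gte(pg + pl, 1)

    tab <- matrix(sample(1:6, 4, replace = TRUE), 2)
    expect_gte(fisher_exact(tab, "greater")$p_value +
                 fisher_exact(tab, "less")$p_value, 1)
  }
})
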