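# Exact Fisher tests (2x2, r x c, Monte-Carlo), chi-square with Cramer's V
# and the Mann-Whitney U test.

# independent brute force: enumerate the free block of a small table with
# expand.grid and factorial arithmetic (no recursion, no log-space)
brute_fisher <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  prob <- function(t) {
    prod(factorial(rs)) * prod(factorial(cs)) /
      (factorial(n) * prod(factorial(t)))
  }
  free <- expand.grid(rep(list(0:max(rs, cs)),
                          (nrow(tab) - 1) * (ncol(tab) - 1)))
  p_obs <- prob(tab)
  total <- 0
  for (i in seq_len(nrow(free))) {
    t <- matrix(0, nrow(tab), ncol(tab))
    t[seq_len(nrow(tab) - 1), seq_len(ncol(tab) - 1)] <-
      as.numeric(free[i, ])
    t[nrow(tab), seq_len(ncol(tab) - 1)] <-
      cs[seq_len(ncol(tab) - 1)] - colSums(t)[seq_len(ncol(tab) - 1)]
    t[, ncol(tab)] <- rs - rowSums(t)
    if (any(t < 0)) next
    p <- prob(t)
    if (p <= p_obs * (1 + 1e-7)) total <- total + p
  }
  total
}

table1_2x2 <- list(
  rnaseq = matrix(c(0, 11, 42, 0), 2),       # expected p = 1.31e-11
  methylation = matrix(c(7, 4, 4, 42), 2),   # expected p = 3.06e-04
  cncluster = matrix(c(8, 2, 10, 37), 2))    # expected p = 7.96e-04

test_that("2x2 Fisher reproduces published cluster-concordance p-values", {
  expect_equal(fisher_exact_2x2(table1_2x2$rnaseq), 1.31e-11,
               tolerance = 0.005)
  expect_equal(fisher_exact_2x2(table1_2x2$methylation), 3.06e-04,
               tolerance = 0.005)
  expect_equal(fisher_exact_2x2(table1_2x2$cncluster), 7.96e-04,
               tolerance = 0.005)
})

test_that("2x2 Fisher agrees with independent oracles", {
  expect_equal(fisher_exact_2x2(matrix(1, 2, 2)), 1)
  t1 <- matrix(c(2, 4, 3, 5), 2)
  expect_equal(fisher_exact_2x2(t1), brute_fisher(t1), tolerance = 1e-12)
  withr_seed(41)
  for (i in 1:20) {
    tab <- random_small_table(i, 2, 2, total = 16)
    expect_equal(fisher_exact_2x2(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("2x2 Fisher is invariant under row/column swaps and transpose", {
  for (i in 1:10) {
    tab <- random_small_table(100 + i, 2, 2, total = 20)
    p <- fisher_exact_2x2(tab)
    expect_equal(fisher_exact_2x2(tab[2:1, ]), p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[, 2:1]), p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(t(tab)), p, tolerance = 1e-12)
  }
})

test_that("r x c enumeration matches the 2x2 path and external oracles", {
  for (i in 1:10) {
    tab <- random_small_table(200 + i, 2, 2, total = 18)
    expect_equal(fisher_exact_rxc(tab, "exact"), fisher_exact_2x2(tab),
                 tolerance = 1e-12)
  }
  mirna <- matrix(c(9, 14, 1, 10, 0, 11, 1, 12), 2)
  p_mirna <- fisher_exact_rxc(mirna, "exact")
  expect_equal(p_mirna, stats::fisher.test(mirna)$p.value, tolerance = 1e-9)
  expect_equal(p_mirna, 0.018517, tolerance = 1e-4)
  # the published 1.95e-02 for this table behaves like a B = 2000
  # Monte-Carlo estimate; the exact value sits within its sampling error
  expect_lte(abs(p_mirna - 1.95e-02), 3 * sqrt(0.0195 * (1 - 0.0195) / 2000))

  pan <- matrix(c(0, 26, 12, 4, 0, 6, 2, 187), 2)
  expect_equal(fisher_exact_rxc(pan, "exact"),
               stats::fisher.test(pan)$p.value, tolerance = 1e-9)
})

test_that("enumerated fixed-margin probabilities sum to one", {
  for (i in 1:10) {
    tab <- random_small_table(300 + i, 2, 3, total = 15)
    lp <- nlsig:::fixed_margin_logprobs(rowSums(tab), colSums(tab))
    expect_equal(sum(exp(lp)), 1, tolerance = 1e-9)
  }
})

test_that("exact mode guards its enumeration budget", {
  big <- matrix(c(500, 480, 510, 505, 495, 490, 502, 508), 2, 4) * 50L
  expect_error(fisher_exact_rxc(big, "exact"), "montecarlo")
})

test_that("Monte-Carlo mode is floored at 1/(B+1) and tracks the exact p", {
  pan <- matrix(c(0, 26, 12, 4, 0, 6, 2, 187), 2)
  p_mc <- fisher_exact_rxc(pan, "montecarlo", B = 2000, seed = 1)
  expect_gte(p_mc, 1 / 2001)
  expect_lte(p_mc, 3 / 2001)    # true exact p is 2.9e-4: at most a few hits

  expect_error(fisher_exact_rxc(pan, "montecarlo", B = 0), "B")

  withr_seed(50)
  ok <- vapply(1:100, function(i) {
    tab <- random_small_table(400 + i, 2, 3, total = 20)
    pe <- fisher_exact_rxc(tab, "exact")
    pm <- fisher_exact_rxc(tab, "montecarlo", B = 2000, seed = i)
    abs(pm - pe) <= 3 * sqrt(pe * (1 - pe) / 2000) + 1 / 2001
  }, logical(1))
  expect_gte(sum(ok), 95)
})

test_that("chi-square and Cramer's V follow the textbook formulas", {
  perfect <- chi_square_cramers_v(matrix(c(10, 0, 0, 10), 2))
  expect_equal(perfect$cramers_v, 1)

  prop <- chi_square_cramers_v(matrix(c(2, 4, 4, 8, 6, 12), 2))
  expect_equal(prop$chisq, 0, tolerance = 1e-12)
  expect_equal(prop$cramers_v, 0, tolerance = 1e-12)

  withr_seed(55)
  tab <- matrix(rpois(12, 10) + 1, 3, 4)
  res <- chi_square_cramers_v(tab)
  exp_cell <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - exp_cell)^2 / exp_cell)
  expect_equal(res$chisq, chi2, tolerance = 1e-12)
  expect_equal(res$cramers_v, sqrt(chi2 / (sum(tab) * 2)), tolerance = 1e-12)
  expect_equal(res$df, 6L, ignore_attr = TRUE)

  expect_error(chi_square_cramers_v(matrix(c(1, 0, 2, 0), 2)), "degenerate")
})

test_that("Mann-Whitney U covers extremes, ties and exact small samples", {
  res <- mann_whitney_u(c(10, 11, 12), c(1, 2, 3))
  expect_equal(res$u, 9)              # every pair won by x
  expect_lte(res$p, 0.11)             # minimal two-sided exact p at 3v3

  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p, 0.99)

  expect_warning(tied <- mann_whitney_u(rep(2, 5), rep(2, 4)), "tied")
  expect_equal(tied$p, 1)

  withr_seed(61)
  for (i in 1:10) {
    x <- round(rnorm(4), 6); y <- round(rnorm(5, 0.5), 6)
    mine <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$u, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }

  # larger samples: normal approximation with tie and continuity corrections
  withr_seed(62)
  x <- round(rnorm(30), 1); y <- round(rnorm(35, 0.4), 1)
  mine <- mann_whitney_u(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))
  expect_equal(mine$u, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-9)

  expect_error(mann_whitney_u(numeric(0), 1), "nonempty")
})
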