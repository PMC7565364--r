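# Exact and asymptotic association tests for r x c contingency tables.
# The Fisher tests are implemented from first principles (log-space
# multivariate hypergeometric probabilities, full enumeration of the
# fixed-margin support, Patefield Monte-Carlo sampling); the chi-square
# machinery delegates to stats::chisq.test.

as_contingency <- function(tab) {
  if (!is.matrix(tab)) tab <- as.matrix(tab)
  if (!is.numeric(tab) || anyNA(tab) || any(tab < 0) || any(tab != floor(tab))) {
    stop("contingency table must contain non-negative integers", call. = FALSE)
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("contingency table needs at least 2 rows and 2 columns", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate margins: zero row or column sum", call. = FALSE)
  }
  storage.mode(tab) <- "double"
  tab
}

# Multivariate hypergeometric log-probability of a table given its margins.
log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

# Log-probabilities of every table sharing the given margins. The last row
# and last column of each table are forced by the margins, so the recursion
# only branches over the free cells.
fixed_margin_logprobs <- function(row_sums, col_sums) {
  r <- length(row_sums); cc <- length(col_sums)
  const <- sum(lgamma(row_sums + 1)) + sum(lgamma(col_sums + 1)) -
    lgamma(sum(row_sums) + 1)
  out <- new.env(parent = emptyenv())
  out$lp <- vector("list", 0L)
  fill_row <- function(i, col_rem, acc) {
    if (i == r) {
      if (any(col_rem < 0)) return(invisible())
      out$lp[[length(out$lp) + 1L]] <- const + acc - sum(lgamma(col_rem + 1))
      return(invisible())
    }
    recurse_cells <- function(j, row_rem, col_rem, acc) {
      if (j == cc) {
        x <- row_rem
        if (x > col_rem[cc]) return(invisible())
        nc <- col_rem; nc[cc] <- nc[cc] - x
        fill_row(i + 1L, nc, acc - lgamma(x + 1))
        return(invisible())
      }
      hi <- min(row_rem, col_rem[j])
      lo <- max(0, row_rem - sum(col_rem[(j + 1):cc]))
      if (hi < lo) return(invisible())
      for (x in lo:hi) {
        nc <- col_rem; nc[j] <- nc[j] - x
        recurse_cells(j + 1L, row_rem - x, nc, acc - lgamma(x + 1))
      }
    }
    recurse_cells(1L, row_sums[i], col_rem, acc)
  }
  fill_row(1L, col_sums, 0)
  unlist(out$lp)
}

# Upper bound on the number of tables enumerated (free rows only).
fixed_margin_support_bound <- function(row_sums, n_cols) {
  prod(choose(row_sums[-length(row_sums)] + n_cols - 1, n_cols - 1))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value under the point-probability rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (with a
#' relative tolerance of 1e-7 on the comparison, absorbing floating-point
#' noise at the boundary).
#'
#' @param tab 2x2 matrix of non-negative integers with positive margins.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as_contingency(tab)
  if (!all(dim(tab) == 2)) stop("table must be 2x2", call. = FALSE)
  m <- rowSums(tab)[1]; n <- rowSums(tab)[2]; k <- colSums(tab)[1]
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  d_obs <- stats::dhyper(tab[1, 1], m, n, k)
  min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
}

#' Fisher's exact test for an r x c table
#'
#' Exact mode enumerates every table sharing the observed margins and sums
#' the probabilities of those no more probable than the observed table
#' (point-probability rule, relative tolerance 1e-7); it refuses tables
#' whose support bound exceeds 1e7 and advises Monte-Carlo instead.
#' Monte-Carlo mode draws `B` tables from the fixed-margin null by
#' sequential conditional hypergeometric (Patefield) sampling and reports
#' `(1 + #{P(T_b) <= P(obs)}) / (B + 1)`, so the smallest attainable
#' p-value is `1 / (B + 1)` (5.0e-4 at the default B = 2000).
#'
#' @param tab r x c matrix of non-negative integers with positive margins.
#' @param mode `"exact"` or `"montecarlo"`.
#' @param B Monte-Carlo replicates (default 2000).
#' @param seed seed for Monte-Carlo mode.
#' @return p-value.
#' @export
fisher_exact_rxc <- function(tab, mode = c("exact", "montecarlo"),
                             B = 2000L, seed = 1L) {
  tab <- as_contingency(tab)
  mode <- match.arg(mode)
  lp_obs <- log_table_prob(tab) + log1p(1e-7)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (mode == "exact") {
    if (fixed_margin_support_bound(rs, ncol(tab)) > 1e7) {
      stop("fixed-margin support too large for exact enumeration; ",
           "use mode = 'montecarlo'", call. = FALSE)
    }
    lp <- fixed_margin_logprobs(rs, cs)
    min(1, sum(exp(lp[lp <= lp_obs])))
  } else {
    if (B < 1) stop("B must be >= 1", call. = FALSE)
    local_seed(seed, {
      draws <- stats::r2dtable(B, rs, cs)
      lp_b <- vapply(draws, log_table_prob, 0)
      (1 + sum(lp_b <= lp_obs)) / (B + 1)
    })
  }
}

#' Pearson chi-square test with Cramer's V
#'
#' Chi-square without continuity correction plus the effect size
#' `V = sqrt(chi2 / (N * (min(r, c) - 1)))`.
#'
#' @param tab r x c matrix of non-negative integers with positive margins.
#' @return list with `chisq`, `df`, `p`, `cramers_v`.
#' @export
chi_square_cramers_v <- function(tab) {
  tab <- as_contingency(tab)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  v <- sqrt(unname(ct$statistic) / (sum(tab) * (min(dim(tab)) - 1)))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, cramers_v = v)
}

#' Mann-Whitney U test
#'
#' U computed from mid-ranks. Small samples (both sizes below 8) use exact
#' enumeration of the permutation distribution of U (valid with ties);
#' larger samples use the normal approximation with tie correction and a
#' continuity correction. When every value across both samples is tied the
#' test is uninformative and p = 1 is returned with a warning.
#'
#' @param x,y numeric samples.
#' @return list with `u` (U for the first sample) and `p` (two-sided).
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty", call. = FALSE)
  nx <- length(x); ny <- length(y)
  all_r <- rank(c(x, y))
  u <- sum(all_r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (length(unique(c(x, y))) == 1L) {
    warning("all values tied across both samples; test uninformative")
    return(list(u = u, p = 1))
  }
  if (nx < 8 && ny < 8) {
    # exact permutation distribution of U given the observed (mid-)ranks
    combs <- utils::combn(nx + ny, nx)
    u_all <- colSums(matrix(all_r[combs], nrow = nx)) - nx * (nx + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(u_all <= u + eps), mean(u_all >= u - eps)))
  } else {
    n <- nx + ny
    ties <- table(c(x, y))
    mu <- nx * ny / 2
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(u = u, p = p)
}
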