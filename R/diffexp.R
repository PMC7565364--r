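#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over genes with
#' all-positive counts, of the ratio of each sample's count to the gene's
#' geometric mean, rescaled so the factors have geometric mean 1. Falls back
#' to total-count scaling (with a warning) when no gene is positive in every
#' sample.
#'
#' @param counts an [expr_matrix()] in the `counts` layer.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  stopifnot(inherits(counts, "expr_matrix"), expr_layer(counts) == "counts")
  m <- as_plain_matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    warning("no gene with all-positive counts; using total-count scaling")
    lib <- colSums(m)
    f <- lib / exp(mean(log(lib)))
    return(stats::setNames(f, colnames(m)))
  }
  lm <- log(m[pos, , drop = FALSE])
  loggeo <- rowMeans(lm)
  logf <- apply(lm - loggeo, 2, stats::median)
  f <- exp(logf - mean(logf))
  stats::setNames(f, colnames(m))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving in the input.
#'
#' @param p_raw numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_raw) {
  if (any(is.na(p_raw)) || any(p_raw < 0 | p_raw > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_raw, method = "BH")
}

#' Negative-binomial two-group Wald test
#'
#' Transparent per-gene test of group B versus group A on raw counts:
#' counts are normalized by the supplied size factors, the dispersion
#' `alpha` in `Var = mu + alpha * mu^2` is estimated per gene by pooled
#' method of moments (floored at 1e-8), and the Wald statistic is the
#' difference of log normalized group means divided by its delta-method
#' standard error under the NB variance, referred to a standard normal
#' (two-sided). The log2 fold change is
#' `log2((m_B + pc) / (m_A + pc))` with `pc = 0.5 / mean(size-adjusted
#' library sizes)`, so genes silent in both groups report a fold change of 0.
#'
#' @param counts an [expr_matrix()] in the `counts` layer.
#' @param group_a,group_b disjoint character vectors of sample ids, each of
#'   size at least 2. The reported fold change is B over A.
#' @param sf size factors; computed with [size_factors()] when `NULL`.
#' @return a `data.frame` with one row per gene: `gene_id`, `base_mean_a`,
#'   `base_mean_b`, `log2fc`, `p_raw`, `p_adj`.
#' @export
nb_two_group_test <- function(counts, group_a, group_b, sf = NULL) {
  stopifnot(inherits(counts, "expr_matrix"), expr_layer(counts) == "counts")
  ids <- colnames(counts)
  unknown <- setdiff(c(group_a, group_b), ids)
  if (length(unknown)) {
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(intersect(group_a, group_b))) {
    stop("groups overlap", call. = FALSE)
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  if (is.null(sf)) sf <- size_factors(counts)
  m <- as_plain_matrix(counts)
  y <- sweep(m, 2, sf[ids], "/")
  ya <- y[, group_a, drop = FALSE]
  yb <- y[, group_b, drop = FALSE]
  na <- length(group_a); nb <- length(group_b)
  ma <- rowMeans(ya); mb <- rowMeans(yb)
  va <- row_vars(ya); vb <- row_vars(yb)

  # pooled method-of-moments dispersion, df-weighted across the two groups
  disp_of <- function(v, mu) ifelse(mu > 0, (v - mu) / mu^2, 0)
  alpha <- ((na - 1) * disp_of(va, ma) + (nb - 1) * disp_of(vb, mb)) /
    (na + nb - 2)
  alpha <- pmax(alpha, 1e-8)

  pc <- 0.5 / mean(colSums(m)[ids] / sf[ids])
  log2fc <- log2((mb + pc) / (ma + pc))

  var_mean_a <- (ma + alpha * ma^2) / na
  var_mean_b <- (mb + alpha * mb^2) / nb
  se <- sqrt(var_mean_a / (ma + pc)^2 + var_mean_b / (mb + pc)^2)
  delta <- log(mb + pc) - log(ma + pc)
  z <- ifelse(se > 0, delta / se, 0)
  p_raw <- 2 * stats::pnorm(-abs(z))

  data.frame(gene_id = rownames(m), base_mean_a = ma, base_mean_b = mb,
             log2fc = log2fc, p_raw = p_raw, p_adj = bh_adjust(p_raw),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expression filter
#'
#' Keeps genes with at least `min_count` counts in at least `min_fraction`
#' of the samples (boundary inclusive: 3 of 4 samples passes at 0.75).
#'
#' @param counts an [expr_matrix()] in the `counts` layer.
#' @param min_count minimum count per sample (default 1).
#' @param min_fraction minimum fraction of samples (default 0.75).
#' @return character vector of retained gene ids.
#' @export
expression_filter <- function(counts, min_count = 1L, min_fraction = 0.75) {
  stopifnot(inherits(counts, "expr_matrix"), expr_layer(counts) == "counts")
  m <- as_plain_matrix(counts)
  keep <- rowMeans(m >= min_count) >= min_fraction
  rownames(m)[keep]
}

#' Differential-expression filter
#'
#' Strict thresholds: adjusted p strictly below `de_fdr` and absolute log2
#' fold change strictly above `de_abs_lfc`.
#'
#' @param results output of [nb_two_group_test()].
#' @param de_fdr adjusted p-value cutoff (default 0.001).
#' @param de_abs_lfc absolute log2 fold-change cutoff (default 2).
#' @return character vector of gene ids passing both filters.
#' @export
de_filter <- function(results, de_fdr = 0.001, de_abs_lfc = 2) {
  stopifnot(all(c("gene_id", "log2fc", "p_adj") %in% names(results)))
  results$gene_id[results$p_adj < de_fdr & abs(results$log2fc) > de_abs_lfc]
}
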