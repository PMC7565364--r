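# Shared fixture builders; everything is generated in code.

random_count_matrix <- function(n_genes, n_samples, seed = 1, lambda = 20) {
  withr_seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  expr_matrix(m, "counts")
}

# small deterministic two-class log2 training set with one clean feature
separated_training_set <- function(n_per_class = 20, seed = 1) {
  withr_seed(seed)
  n <- 2 * n_per_class
  x <- rbind(
    clean = c(rnorm(n_per_class, 0, 0.3), rnorm(n_per_class, 6, 0.3)),
    noise1 = rnorm(n, 2, 1),
    noise2 = rnorm(n, 2, 1))
  colnames(x) <- sprintf("s%02d", seq_len(n))
  y <- stats::setNames(rep(c("NL", "OT"), each = n_per_class), colnames(x))
  list(x = expr_matrix(x, "log2"), y = y)
}

random_small_table <- function(seed, nrow = 2, ncol = 3, total = 14) {
  withr_seed(seed)
  repeat {
    cells <- as.vector(stats::rmultinom(1, total, rep(1, nrow * ncol)))
    tab <- matrix(cells, nrow, ncol)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(tab)
  }
}

# seed without clobbering the session RNG state
withr_seed <- function(seed) {
  set.seed(seed)
  invisible(seed)
}

# reference cohort + truth used by several files (cached per test run)
default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(simulation_design(seed = 1))
    cache
  }
})
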