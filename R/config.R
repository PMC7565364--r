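#' Pipeline configuration
#'
#' Bundles the tunable constants of the whole pipeline with validated
#' defaults: the log2 pseudocount (0.01), the differential-expression filter
#' (BH-adjusted p < 0.001 and |log2FC| > 2), the expression filter (at least
#' 1 count in at least 75% of samples), the ranking stage (100 random
#' forests, top 50 genes), the signature search (sizes 1-3, 10-fold
#' stratified cross-validation, 80/20 train/test split), the k-nearest
#' neighbor classifier (k = 5, enforced odd so majority votes cannot tie)
#' and the Monte-Carlo replicate count for exact tests (B = 2000).
#'
#' @param pseudocount log2 standardization offset.
#' @param de_fdr BH-adjusted p-value cutoff (strict `<`).
#' @param de_abs_lfc absolute log2 fold-change cutoff (strict `>`).
#' @param expr_min_count,expr_min_fraction expression filter: keep genes with
#'   at least `expr_min_count` counts in at least `expr_min_fraction` of samples.
#' @param n_forests number of random forests averaged for gene ranking.
#' @param top_n_genes size of the ranked candidate pool.
#' @param signature_sizes integer vector of signature sizes to search.
#' @param cv_folds stratified cross-validation folds.
#' @param knn_k neighbors for the KNN classifier; must be odd.
#' @param test_fraction held-out test fraction of the stratified split.
#' @param mc_replicates Monte-Carlo replicates for r x c Fisher tests.
#' @param n_trees trees per forest.
#' @param auroc_tolerance AUROC slack used by the minimal-size selection rule.
#' @param n_clusters number of clusters cut from the dendrogram.
#' @param linkage agglomeration method for hierarchical clustering
#'   (default "ward").
#' @param seed integer seed driving all stochastic stages.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(pseudocount = 0.01,
                            de_fdr = 0.001,
                            de_abs_lfc = 2,
                            expr_min_count = 1L,
                            expr_min_fraction = 0.75,
                            n_forests = 100L,
                            top_n_genes = 50L,
                            signature_sizes = c(1L, 2L, 3L),
                            cv_folds = 10L,
                            knn_k = 5L,
                            test_fraction = 0.2,
                            mc_replicates = 2000L,
                            n_trees = 500L,
                            auroc_tolerance = 0.005,
                            n_clusters = 4L,
                            linkage = "ward",
                            seed = 1L) {
  assert_scalar_number(pseudocount, "pseudocount", lower = 1e-12)
  assert_scalar_number(de_fdr, "de_fdr", lower = 1e-12, upper = 1 - 1e-12)
  assert_scalar_number(de_abs_lfc, "de_abs_lfc", lower = 0)
  assert_scalar_number(expr_min_fraction, "expr_min_fraction",
                       lower = 1e-12, upper = 1 - 1e-12)
  assert_scalar_number(test_fraction, "test_fraction",
                       lower = 1e-12, upper = 1 - 1e-12)
  ints <- list(expr_min_count = expr_min_count, n_forests = n_forests,
               top_n_genes = top_n_genes, cv_folds = cv_folds, knn_k = knn_k,
               mc_replicates = mc_replicates, n_trees = n_trees,
               n_clusters = n_clusters)
  for (nm in names(ints)) {
    v <- ints[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v != floor(v)) {
      stop("'", nm, "' must be an integer >= 1", call. = FALSE)
    }
  }
  if (knn_k %% 2 == 0) stop("'knn_k' must be odd", call. = FALSE)
  signature_sizes <- sort(unique(as.integer(signature_sizes)))
  if (any(signature_sizes < 1)) stop("signature sizes must be >= 1", call. = FALSE)
  cfg <- list(pseudocount = pseudocount, de_fdr = de_fdr,
              de_abs_lfc = de_abs_lfc, expr_min_count = as.integer(expr_min_count),
              expr_min_fraction = expr_min_fraction,
              n_forests = as.integer(n_forests),
              top_n_genes = as.integer(top_n_genes),
              signature_sizes = signature_sizes,
              cv_folds = as.integer(cv_folds), knn_k = as.integer(knn_k),
              test_fraction = test_fraction,
              mc_replicates = as.integer(mc_replicates),
              n_trees = as.integer(n_trees),
              auroc_tolerance = auroc_tolerance,
              n_clusters = as.integer(n_clusters),
              linkage = match.arg(linkage, c("ward", "complete", "average")),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value YAML; keys as in [pipeline_config()]. Unknown keys are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}
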