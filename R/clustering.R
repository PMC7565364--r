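#' Center genes across samples
#'
#' Subtracts each gene's mean across samples from its log2 values, the row
#' standardization used by expression heatmaps. Sample-sample correlations
#' computed after centering are driven by each sample's deviation pattern
#' from the cohort average rather than by the shared absolute expression
#' profile, which is what lets co-regulated sample groups form tight
#' clusters.
#'
#' @param log_expr an [expr_matrix()] in the `log2` layer.
#' @return an [expr_matrix()] in the `log2` layer with zero-mean rows.
#' @export
center_genes <- function(log_expr) {
  stopifnot(inherits(log_expr, "expr_matrix"), expr_layer(log_expr) == "log2")
  m <- as_plain_matrix(log_expr)
  expr_matrix(m - rowMeans(m), "log2")
}

#' Pearson correlation distance between samples
#'
#' `d(i, j) = 1 - r(i, j)` with `r` the Pearson correlation across genes of
#' the log2-standardized profiles, so perfectly correlated samples are at
#' distance 0 and perfectly anti-correlated ones at 2. Genes with zero
#' variance across samples carry no correlation information and are dropped
#' with a message; a sample whose remaining profile has zero variance is an
#' error (its correlation is undefined).
#'
#' @param log_expr an [expr_matrix()] in the `log2` layer (genes x samples),
#'   typically restricted to a differentially expressed gene set.
#' @return symmetric sample x sample distance matrix with zero diagonal.
#' @export
pearson_distance <- function(log_expr) {
  stopifnot(inherits(log_expr, "expr_matrix"), expr_layer(log_expr) == "log2")
  m <- as_plain_matrix(log_expr)
  gv <- row_vars(m)
  if (any(gv == 0)) {
    message(sum(gv == 0), " zero-variance gene(s) dropped before correlation")
    m <- m[gv > 0, , drop = FALSE]
  }
  if (nrow(m) < 2) stop("need at least 2 genes with nonzero variance", call. = FALSE)
  sv <- apply(m, 2, stats::var)
  if (any(sv == 0)) {
    stop("zero-variance sample(s): ",
         paste(colnames(m)[sv == 0], collapse = ", "), call. = FALSE)
  }
  d <- 1 - stats::cor(m)
  d[d < 0] <- 0          # guard against -1e-16 rounding
  diag(d) <- 0
  d
}

#' Agglomerative hierarchical clustering of samples
#'
#' @param distances symmetric distance matrix (e.g. from [pearson_distance()]).
#' @param linkage `"complete"` (default), `"average"`, or `"ward"` (ward.D2).
#' @return an `hclust` merge tree.
#' @export
hierarchical_cluster <- function(distances,
                                 linkage = c("complete", "average", "ward")) {
  linkage <- match.arg(linkage)
  if (!is.matrix(distances) || !isSymmetric(unname(distances), tol = 1e-8)) {
    stop("'distances' must be a symmetric matrix", call. = FALSE)
  }
  method <- c(complete = "complete", average = "average", ward = "ward.D2")[linkage]
  stats::hclust(stats::as.dist(distances), method = method)
}

#' Cut a dendrogram into k clusters
#'
#' Cuts the `k - 1` tallest merges, yielding exactly `k` clusters.
#'
#' @param dendrogram an `hclust` tree.
#' @param k number of clusters, between 1 and the number of samples.
#' @return a `data.frame` with `sample_id` and `cluster` (character labels).
#' @export
cut_clusters <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "hclust"))
  n <- length(dendrogram$labels)
  if (k < 1 || k > n) stop("'k' must be between 1 and ", n, call. = FALSE)
  cl <- stats::cutree(dendrogram, k = k)
  data.frame(sample_id = names(cl), cluster = as.character(cl),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Anchor cluster labels on the normal controls: NL vs OT
#'
#' The cluster containing all normal control samples defines the
#' "normal-like" group: tumor samples sharing that cluster are labeled NL,
#' all other tumor samples OT. If the normals do not co-cluster the
#' anchoring rule is undefined and an error is raised.
#'
#' @param assignment `data.frame` from [cut_clusters()].
#' @param normal_ids character vector of normal control sample ids.
#' @return the assignment with a `group` column (`"NL"`/`"OT"`, `NA` for the
#'   normals themselves).
#' @export
assign_nl_ot <- function(assignment, normal_ids) {
  stopifnot(all(c("sample_id", "cluster") %in% names(assignment)))
  if (!length(normal_ids)) stop("no normal samples given", call. = FALSE)
  missing <- setdiff(normal_ids, assignment$sample_id)
  if (length(missing)) {
    stop("normal sample(s) not in assignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ncl <- unique(assignment$cluster[assignment$sample_id %in% normal_ids])
  if (length(ncl) != 1) {
    stop("normal samples split across clusters (",
         paste(ncl, collapse = ", "),
         "); the normal-anchoring rule is undefined", call. = FALSE)
  }
  is_normal <- assignment$sample_id %in% normal_ids
  assignment$group <- ifelse(is_normal, NA_character_,
                             ifelse(assignment$cluster == ncl, "NL", "OT"))
  assignment
}
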