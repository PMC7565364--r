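#' Stratified train/test split
#'
#' Splits samples into train and test sets preserving class proportions:
#' each class contributes `round(test_fraction * n_class)` samples to the
#' test set (clamped so both sets keep at least one member per class).
#' 238 samples with a 14-member minority class at `test_fraction = 0.2`
#' split into 190 train / 48 test.
#'
#' @param labels named character vector (or factor) of class labels, names
#'   are sample ids.
#' @param test_fraction fraction held out (default 0.2).
#' @param seed integer seed; the split is deterministic given it.
#' @return list with character vectors `train` and `test`.
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 1L) {
  if (is.null(names(labels))) stop("'labels' must be named by sample id", call. = FALSE)
  labels <- stats::setNames(as.character(labels), names(labels))
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least two classes", call. = FALSE)
  if (any(tab < 2)) {
    stop("class with fewer than 2 members: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  assert_scalar_number(test_fraction, "test_fraction", 1e-12, 1 - 1e-12)
  local_seed(seed, {
    test <- character(0)
    for (cl in names(tab)) {
      ids <- names(labels)[labels == cl]
      n_test <- min(max(round(test_fraction * length(ids)), 1L),
                    length(ids) - 1L)
      test <- c(test, sample(ids, n_test))
    }
    list(train = setdiff(names(labels), test), test = sort(test))
  })
}

# Stratified fold assignment; folds are reduced (with a warning) when the
# minority class has fewer members than requested folds.
make_stratified_folds <- function(y, folds, seed) {
  tab <- table(y)
  if (min(tab) < 2) stop("each class needs at least 2 members for CV", call. = FALSE)
  if (min(tab) < folds) {
    warning(sprintf("reducing CV folds from %d to %d (minority class size)",
                    folds, min(tab)))
    folds <- min(tab)
  }
  local_seed(seed, {
    fold <- integer(length(y))
    for (cl in names(tab)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

# KNN positive-class score: for each column of x_query, the fraction of its
# k nearest columns of x_ref (Euclidean, feature rows) labeled positive.
knn_scores <- function(x_ref, y_ref, x_query, k, positive = "NL") {
  stopifnot(nrow(x_ref) == nrow(x_query))
  if (k > ncol(x_ref)) stop("knn_k larger than the reference set", call. = FALSE)
  is_pos <- y_ref == positive
  # squared cross-distances via the expansion ||a-b||^2 = |a|^2 + |b|^2 - 2ab
  ra <- colSums(x_query^2)
  rb <- colSums(x_ref^2)
  d2 <- outer(ra, rb, "+") - 2 * crossprod(x_query, x_ref)
  apply(d2, 1, function(r) mean(is_pos[order(r)[seq_len(k)]]))
}

#' ROC curve and AUC
#'
#' Threshold sweep over the distinct scores; the reported AUC equals the
#' Mann-Whitney U statistic `U / (n_pos * n_neg)` with mid-rank tie handling,
#' i.e. the probability that a random positive outscores a random negative.
#'
#' @param scores numeric classifier scores, larger = more positive.
#' @param labels class labels aligned with `scores`.
#' @param positive label of the positive class (default `"NL"`).
#' @return list with `points` (a `data.frame` of FPR/TPR from (0,0) to (1,1))
#'   and `auc`.
#' @export
roc_curve <- function(scores, labels, positive = "NL") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)            # mid-ranks
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  last <- !duplicated(scores[ord], fromLast = TRUE)   # one point per threshold
  points <- data.frame(fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1))
  list(points = points, auc = auc)
}

#' Rank genes by averaged random-forest impurity importance
#'
#' Fits `n_forests` independently seeded random forests of classification
#' trees and averages each gene's mean-decrease-in-Gini-impurity importance
#' across forests; the `top_n` genes by decreasing mean importance (ties
#' broken lexicographically) form the candidate pool for the signature
#' search.
#'
#' @param x an [expr_matrix()] in the `log2` layer restricted to candidate
#'   genes (typically the NL-vs-OT differentially expressed genes).
#' @param y class labels aligned with the columns of `x` (or named by them).
#' @param n_forests forests to average (default 100).
#' @param top_n genes returned (default 50).
#' @param n_trees trees per forest (default 500; splits consider `sqrt(p)`
#'   genes, trees grow to purity).
#' @param seed base seed; forest `i` uses `seed + i`.
#' @return `data.frame` with `gene_id`, `importance`, `rank`, carrying an
#'   `n_forests` attribute.
#' @export
rank_genes_by_forest <- function(x, y, n_forests = 100L, top_n = 50L,
                                 n_trees = 500L, seed = 1L) {
  stopifnot(inherits(x, "expr_matrix"), expr_layer(x) == "log2")
  if (!is.null(names(y))) y <- y[colnames(x)]
  y <- factor(as.character(y))
  if (length(y) != ncol(x)) stop("labels do not match samples", call. = FALSE)
  if (min(table(y)) < 2) stop("both classes need at least 2 samples", call. = FALSE)
  if (top_n > nrow(x)) {
    stop("top_n (", top_n, ") exceeds the candidate pool (", nrow(x), ")",
         call. = FALSE)
  }
  df <- as.data.frame(t(as_plain_matrix(x)))
  total <- numeric(nrow(x))
  for (f in seq_len(n_forests)) {
    fit <- ranger::ranger(x = df, y = y, num.trees = n_trees,
                          importance = "impurity",
                          seed = seed + f, num.threads = 1L)
    total <- total + fit$variable.importance[colnames(df)]
  }
  imp <- total / n_forests
  ord <- order(-imp, rownames(x))
  out <- data.frame(gene_id = rownames(x)[ord], importance = unname(imp[ord]),
                    rank = seq_len(nrow(x)), stringsAsFactors = FALSE)
  out <- out[seq_len(top_n), , drop = FALSE]
  attr(out, "n_forests") <- as.integer(n_forests)
  out
}

# Precomputed fold structure shared by every candidate evaluation.
build_fold_structure <- function(y, fold, positive = "NL") {
  is_pos <- y == positive
  lapply(unique(fold), function(f) {
    te <- which(fold == f)
    tr <- which(fold != f)
    if (length(unique(y[tr])) < 2) {
      stop("degenerate fold: single-class training fold", call. = FALSE)
    }
    list(te = te, tr = tr, pos_tr = is_pos[tr])
  })
}

# Candidate-evaluation engine over a precomputed squared distance matrix and
# fold structure; hot path of the exhaustive search.
eval_candidate_cv <- function(d2, y, folds, k, positive = "NL") {
  n <- length(y)
  scores <- numeric(n)
  is_pos <- y == positive
  for (fs in folds) {
    sub <- d2[fs$te, fs$tr, drop = FALSE]
    kk <- min(k, ncol(sub))
    npos <- numeric(nrow(sub))
    for (j in seq_len(kk)) {       # extract the j-th nearest neighbor per row
      jmin <- max.col(-sub, ties.method = "first")
      npos <- npos + fs$pos_tr[jmin]
      sub[cbind(seq_len(nrow(sub)), jmin)] <- Inf
    }
    scores[fs$te] <- npos / kk
  }
  pred_pos <- scores > 0.5
  r <- rank(scores)
  n1 <- sum(is_pos); n0 <- n - n1
  list(scores = scores,
       cv_error = mean(pred_pos != is_pos),
       cv_auroc = (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0),
       cv_sensitivity = mean(pred_pos[is_pos]),
       cv_specificity = mean(!pred_pos[!is_pos]))
}

#' Cross-validated evaluation of a gene signature
#'
#' Scores a fixed gene set with a k-nearest-neighbor classifier (Euclidean
#' distance on log2 expression of the signature genes) under stratified
#' cross-validation. Per-fold predictions are pooled before computing the
#' error rate, AUROC, sensitivity and specificity, with NL as the positive
#' class; the ROC score of a sample is the fraction of its k nearest
#' neighbors labeled NL.
#'
#' @param genes character vector of signature gene ids.
#' @param x_train an [expr_matrix()] in the `log2` layer.
#' @param y_train class labels (`"NL"`/`"OT"`) aligned with (or named by)
#'   the columns of `x_train`.
#' @param knn_k neighbors (odd; default 5).
#' @param cv_folds stratified folds (default 10; reduced with a warning if
#'   the minority class is smaller).
#' @param seed seed for the fold assignment.
#' @return list with `genes`, `cv_error`, `cv_auroc`, `cv_sensitivity`,
#'   `cv_specificity` and the pooled per-sample `scores`.
#' @export
evaluate_signature <- function(genes, x_train, y_train, knn_k = 5L,
                               cv_folds = 10L, seed = 1L) {
  stopifnot(inherits(x_train, "expr_matrix"), expr_layer(x_train) == "log2")
  missing <- setdiff(genes, rownames(x_train))
  if (length(missing)) {
    stop("gene(s) not in expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.null(names(y_train))) y_train <- y_train[colnames(x_train)]
  y <- as.character(y_train)
  folds <- build_fold_structure(y, make_stratified_folds(y, cv_folds, seed))
  x <- as_plain_matrix(x_train)[genes, , drop = FALSE]
  d2 <- matrix(0, ncol(x), ncol(x))
  for (g in seq_len(nrow(x))) d2 <- d2 + outer(x[g, ], x[g, ], "-")^2
  res <- eval_candidate_cv(d2, y, folds, knn_k)
  c(list(genes = sort(genes)), res)
}

#' Number of candidate signatures for a pool
#'
#' @param pool_size genes in the ranked pool.
#' @param sizes signature sizes searched.
#' @return total count of combinations, `sum(choose(pool_size, sizes))`.
#' @export
signature_combination_count <- function(pool_size, sizes) {
  sum(choose(pool_size, sizes))
}

#' Exhaustive minimal-signature search
#'
#' Evaluates every gene combination of each requested size from the ranked
#' pool with [evaluate_signature()]'s cross-validation scheme (a single fold
#' assignment is shared by all candidates), then selects the minimal
#' signature: among all candidates, find the maximum cross-validated AUROC
#' `A*`; the selected signature is the smallest-size candidate with
#' `cv_auroc >= A* - auroc_tolerance`, ties broken by lower error, then
#' higher sensitivity, then lexicographic gene ids.
#'
#' @param ranked ranked pool from [rank_genes_by_forest()] (or a character
#'   vector of gene ids).
#' @param sizes signature sizes to search (default 1:3).
#' @param x_train,y_train,knn_k,cv_folds,seed as in [evaluate_signature()].
#' @param auroc_tolerance slack below the best AUROC still counted as "best
#'   performance" when preferring smaller signatures (default 0.005).
#' @return list with `candidates` (a `data.frame`, one row per evaluated
#'   combination, sorted by the selection order), `selected` (the winning
#'   row), and `n_evaluated`.
#' @export
exhaustive_search <- function(ranked, sizes = c(1L, 2L, 3L), x_train, y_train,
                              knn_k = 5L, cv_folds = 10L, seed = 1L,
                              auroc_tolerance = 0.005) {
  pool <- if (is.data.frame(ranked)) ranked$gene_id else as.character(ranked)
  if (!length(pool)) stop("ranked pool is empty", call. = FALSE)
  if (max(sizes) > length(pool)) {
    stop("pool smaller than the largest requested size", call. = FALSE)
  }
  stopifnot(inherits(x_train, "expr_matrix"), expr_layer(x_train) == "log2")
  pool <- sort(pool)                       # input-order invariance
  missing <- setdiff(pool, rownames(x_train))
  if (length(missing)) {
    stop("gene(s) not in expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.null(names(y_train))) y_train <- y_train[colnames(x_train)]
  y <- as.character(y_train)
  folds <- build_fold_structure(y, make_stratified_folds(y, cv_folds, seed))

  x <- as_plain_matrix(x_train)[pool, , drop = FALSE]
  d2_gene <- lapply(seq_along(pool), function(g) outer(x[g, ], x[g, ], "-")^2)
  names(d2_gene) <- pool

  n_cand <- signature_combination_count(length(pool), sizes)
  sig_lab <- character(n_cand)
  met <- matrix(NA_real_, n_cand, 5,
                dimnames = list(NULL, c("size", "cv_error", "cv_auroc",
                                        "cv_sensitivity", "cv_specificity")))
  i <- 0L
  for (s in sort(sizes)) {
    combos <- utils::combn(pool, s, simplify = FALSE)
    for (genes in combos) {
      d2 <- d2_gene[[genes[1]]]
      if (s > 1) for (g in genes[-1]) d2 <- d2 + d2_gene[[g]]
      r <- eval_candidate_cv(d2, y, folds, knn_k)
      i <- i + 1L
      sig_lab[i] <- paste(genes, collapse = "+")
      met[i, ] <- c(s, r$cv_error, r$cv_auroc, r$cv_sensitivity,
                    r$cv_specificity)
    }
  }
  cand <- data.frame(signature = sig_lab, met, stringsAsFactors = FALSE)
  a_star <- max(cand$cv_auroc)
  eligible <- cand$cv_auroc >= a_star - auroc_tolerance
  s_min <- min(cand$size[eligible])
  pick <- which(eligible & cand$size == s_min)
  pick <- pick[order(cand$cv_error[pick], -cand$cv_sensitivity[pick],
                     cand$signature[pick])]
  selection_order <- order(!eligible, cand$size, cand$cv_error,
                           -cand$cv_sensitivity, cand$signature)
  list(candidates = cand[selection_order, , drop = FALSE],
       selected = cand[pick[1], , drop = FALSE],
       selected_genes = strsplit(cand$signature[pick[1]], "+", fixed = TRUE)[[1]],
       best_cv_auroc = a_star,
       n_evaluated = nrow(cand))
}

#' Held-out evaluation of a signature
#'
#' Trains the KNN on the reference samples and scores the held-out samples,
#' reporting test AUROC, error, sensitivity and specificity (NL positive).
#'
#' @param genes signature gene ids.
#' @param x_train,y_train reference log2 expression and labels.
#' @param x_test,y_test held-out log2 expression and labels.
#' @param knn_k neighbors (default 5).
#' @return list of test metrics plus per-sample `scores`.
#' @export
test_signature <- function(genes, x_train, y_train, x_test, y_test, knn_k = 5L) {
  stopifnot(inherits(x_train, "expr_matrix"), inherits(x_test, "expr_matrix"),
            expr_layer(x_train) == "log2", expr_layer(x_test) == "log2")
  for (m in list(x_train, x_test)) {
    miss <- setdiff(genes, rownames(m))
    if (length(miss)) stop("gene(s) missing: ", paste(miss, collapse = ", "),
                           call. = FALSE)
  }
  if (!is.null(names(y_train))) y_train <- y_train[colnames(x_train)]
  if (!is.null(names(y_test))) y_test <- y_test[colnames(x_test)]
  scores <- knn_scores(as_plain_matrix(x_train)[genes, , drop = FALSE],
                       as.character(y_train),
                       as_plain_matrix(x_test)[genes, , drop = FALSE],
                       knn_k)
  is_pos <- as.character(y_test) == "NL"
  pred_pos <- scores > 0.5
  list(genes = sort(genes),
       test_auroc = roc_curve(scores, as.character(y_test))$auc,
       test_error = mean(pred_pos != is_pos),
       test_sensitivity = mean(pred_pos[is_pos]),
       test_specificity = mean(!pred_pos[!is_pos]),
       scores = stats::setNames(scores, colnames(x_test)))
}
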