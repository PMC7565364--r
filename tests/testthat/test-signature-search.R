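# Stratified splitting, forest-based gene ranking, KNN signature evaluation,
# exhaustive minimal-signature search and ROC machinery.

test_that("stratified split preserves class proportions and counts", {
  labels <- stats::setNames(rep(c("NL", "OT"), c(14, 224)),
                            sprintf("s%03d", 1:238))
  sp <- stratified_split(labels, 0.2, seed = 11)
  expect_length(sp$test, 48)
  expect_length(sp$train, 190)
  expect_identical(sum(labels[sp$test] == "NL"), 3L)

  small <- stats::setNames(rep(c("NL", "OT"), each = 5), letters[1:10])
  sp2 <- stratified_split(small, 0.2, seed = 1)
  expect_identical(as.integer(table(small[sp2$test])[c("NL", "OT")]),
                   c(1L, 1L))

  expect_identical(stratified_split(labels, 0.2, seed = 3),
                   stratified_split(labels, 0.2, seed = 3))
  expect_false(identical(stratified_split(labels, 0.2, seed = 3)$test,
                         stratified_split(labels, 0.2, seed = 4)$test))
  expect_error(stratified_split(stats::setNames(c("NL", "OT", "OT"),
                                                letters[1:3]), 0.2),
               "fewer than 2")
})

test_that("ROC AUC equals the pairwise-comparison estimator", {
  r <- roc_curve(c(0, 0, 1, 1), c("OT", "OT", "NL", "NL"))
  expect_equal(r$auc, 1)
  expect_equal(roc_curve(rep(0.3, 8), rep(c("NL", "OT"), 4))$auc, 0.5)

  withr_seed(17)
  for (i in 1:5) {
    scores <- sample(round(runif(200), 2))  # ties on purpose
    labels <- sample(rep(c("NL", "OT"), c(60, 140)))
    pos <- scores[labels == "NL"]; neg <- scores[labels == "OT"]
    brute <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
    expect_equal(roc_curve(scores, labels)$auc, brute, tolerance = 1e-12)
  }

  pts <- roc_curve(runif(50), sample(rep(c("NL", "OT"), 25)))$points
  expect_equal(pts[1, ], data.frame(fpr = 0, tpr = 0), ignore_attr = TRUE)
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  expect_error(roc_curve(1:3, c("NL", "NL", "NL")), "both classes")
})

test_that("forest ranking recovers planted discriminative genes", {
  make_planted <- function(seed) {
    withr_seed(seed)
    n <- 60
    y <- stats::setNames(rep(c("NL", "OT"), c(15, 45)), sprintf("s%02d", 1:n))
    x <- matrix(rnorm(100 * n, 4, 1), 100, n,
                dimnames = list(sprintf("g%03d", 1:100), names(y)))
    x[c("g001", "g002"), y == "OT"] <- x[c("g001", "g002"), y == "OT"] + 5
    list(x = expr_matrix(x, "log2"), y = y)
  }
  hits <- vapply(1:10, function(s) {
    p <- make_planted(s)
    rk <- rank_genes_by_forest(p$x, p$y, n_forests = 5, top_n = 10,
                               n_trees = 200, seed = s)
    all(c("g001", "g002") %in% rk$gene_id[1:5])
  }, logical(1))
  expect_gte(sum(hits), 9)

  # strong signal: one forest and many forests agree on the top gene
  p <- make_planted(1)
  top1 <- rank_genes_by_forest(p$x, p$y, n_forests = 1, top_n = 1,
                               n_trees = 200, seed = 3)$gene_id
  top100 <- rank_genes_by_forest(p$x, p$y, n_forests = 20, top_n = 1,
                                 n_trees = 200, seed = 3)$gene_id
  expect_identical(top1, top100)

  expect_error(rank_genes_by_forest(p$x, p$y, top_n = 200), "exceeds")
})

test_that("permuted labels destroy the planted genes' ranks", {
  withr_seed(23)
  n <- 60
  y0 <- rep(c("NL", "OT"), c(15, 45))
  x <- matrix(rnorm(100 * n, 4, 1), 100, n,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:n)))
  x[c("g001", "g002"), y0 == "OT"] <- x[c("g001", "g002"), y0 == "OT"] + 5
  em <- expr_matrix(x, "log2")
  ranks <- vapply(1:20, function(i) {
    yp <- stats::setNames(sample(y0), colnames(x))
    rk <- rank_genes_by_forest(em, yp, n_forests = 2, top_n = 100,
                               n_trees = 100, seed = i)
    mean(match(c("g001", "g002"), rk$gene_id))
  }, numeric(1))
  expect_gte(stats::median(ranks), 25)
  expect_lte(stats::median(ranks), 75)
})

test_that("KNN cross-validation scores signatures correctly", {
  sep <- separated_training_set(20, seed = 2)
  res <- evaluate_signature("clean", sep$x, sep$y, knn_k = 5, cv_folds = 10,
                            seed = 1)
  expect_equal(res$cv_error, 0)
  expect_equal(res$cv_auroc, 1)
  expect_equal(res$cv_sensitivity, 1)
  expect_equal(res$cv_specificity, 1)

  # uninformative constant feature: neighbors are arbitrary, AUROC near 1/2
  xconst <- unclass(sep$x)
  xconst["noise1", ] <- 7
  resc <- evaluate_signature("noise1", expr_matrix(xconst, "log2"), sep$y,
                             seed = 1)
  expect_gte(resc$cv_auroc, 0.25)
  expect_lte(resc$cv_auroc, 0.75)

  withr_seed(14)
  big <- separated_training_set(100, seed = 3)
  yperm <- stats::setNames(sample(big$y), names(big$y))
  resp <- evaluate_signature("clean", big$x, yperm, seed = 2)
  expect_gte(resp$cv_auroc, 0.35)
  expect_lte(resp$cv_auroc, 0.65)

  expect_error(evaluate_signature("missing", sep$x, sep$y), "not in")
})

test_that("fold reduction kicks in for tiny minority classes", {
  sep <- separated_training_set(20, seed = 4)
  y <- sep$y
  y[y == "NL"] <- "OT"
  y[1:3] <- "NL"
  expect_warning(res <- evaluate_signature("clean", sep$x, y, cv_folds = 10,
                                           seed = 1),
                 "reducing CV folds")
  expect_true(is.finite(res$cv_auroc))
})

test_that("exhaustive search counts combinations exactly", {
  expect_identical(signature_combination_count(100, 2), 4950)
  expect_identical(signature_combination_count(50, 2), 1225)
  expect_identical(signature_combination_count(50, 1:3), 20875)

  withr_seed(6)
  n <- 40
  y <- stats::setNames(rep(c("NL", "OT"), c(10, 30)), sprintf("s%02d", 1:n))
  x <- matrix(rnorm(50 * n), 50, n,
              dimnames = list(sprintf("g%03d", 1:50), names(y)))
  sr <- exhaustive_search(rownames(x), sizes = 2, expr_matrix(x, "log2"), y,
                          cv_folds = 5, seed = 1)
  expect_identical(sr$n_evaluated, 1225L)
  expect_identical(nrow(sr$candidates), 1225L)
})

test_that("selection prefers the smallest signature at best performance", {
  # two genes jointly separate the classes; each alone does not
  withr_seed(9)
  n <- 60
  y <- stats::setNames(rep(c("NL", "OT"), each = n / 2), sprintf("s%02d", 1:n))
  theta <- runif(n / 2, 0, 2 * pi)
  g1 <- c(3 * cos(theta), rnorm(n / 2, 0, 0.4))
  g2 <- c(3 * sin(theta), rnorm(n / 2, 0, 0.4))
  x <- rbind(gA = g1, gB = g2, gC = rnorm(n), gD = rnorm(n))
  colnames(x) <- names(y)
  em <- expr_matrix(x, "log2")
  sr <- exhaustive_search(rownames(x), sizes = 1:2, em, y, cv_folds = 5,
                          seed = 2)
  expect_identical(sort(sr$selected_genes), c("gA", "gB"))
  expect_identical(sr$selected$size, 2)

  # pool order invariance, and adding an irrelevant gene never ousts the pair
  sr2 <- exhaustive_search(c("gD", "gB", "gC", "gA"), sizes = 1:2, em, y,
                           cv_folds = 5, seed = 2)
  expect_identical(sr2$selected, sr$selected)
  expect_identical(sr2$candidates, sr$candidates)

  sep <- separated_training_set(20, seed = 5)
  sr3 <- exhaustive_search(c("clean", "noise1"), sizes = 1:2, sep$x, sep$y,
                           cv_folds = 5, seed = 1)
  expect_identical(sr3$selected_genes, "clean")
  expect_identical(sr3$selected$size, 1)

  expect_error(exhaustive_search(character(0), 1, em, y), "empty")
  expect_error(exhaustive_search(c("gA", "gB"), sizes = 3, em, y),
               "pool smaller")
})

test_that("held-out evaluation reports test metrics for a trained KNN", {
  tr <- separated_training_set(20, seed = 6)
  te <- separated_training_set(10, seed = 7)
  res <- test_signature("clean", tr$x, tr$y, te$x, te$y, knn_k = 5)
  expect_equal(res$test_auroc, 1)
  expect_equal(res$test_error, 0)
  expect_error(test_signature("nope", tr$x, tr$y, te$x, te$y), "missing")
})
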