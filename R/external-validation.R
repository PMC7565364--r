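#' Classify an external cohort with a reference-trained KNN
#'
#' Transfers a discovered signature to an independent cohort: the query
#' expression is log2-standardized with the same pseudocount as the
#' reference, and each query sample is labeled NL or OT by majority vote of
#' its `knn_k` nearest reference samples (Euclidean distance in
#' signature-gene space). No cross-cohort batch correction is applied beyond
#' the shared log2 standardization.
#'
#' @param reference_expr [expr_matrix()] in the `log2` layer (the labeled
#'   reference cohort).
#' @param reference_labels `"NL"`/`"OT"` labels aligned with (or named by)
#'   the reference samples.
#' @param signature_genes character vector of signature gene ids; must be
#'   present in both cohorts.
#' @param query_expr [expr_matrix()] in the `counts` or `abundance` layer
#'   (log2-standardized internally) or already in the `log2` layer.
#' @param knn_k neighbors (odd; default 5).
#' @param pseudocount log2 offset applied to the query (default 0.01).
#' @return a `transfer_result` list: `predictions` (`data.frame` with
#'   `sample_id`, `group`, `score`), `counts` (table of predicted groups),
#'   `signature_genes`.
#' @export
classify_external <- function(reference_expr, reference_labels,
                              signature_genes, query_expr,
                              knn_k = 5L, pseudocount = 0.01) {
  stopifnot(inherits(reference_expr, "expr_matrix"),
            expr_layer(reference_expr) == "log2",
            inherits(query_expr, "expr_matrix"))
  if (knn_k %% 2 == 0) stop("'knn_k' must be odd", call. = FALSE)
  miss_ref <- setdiff(signature_genes, rownames(reference_expr))
  if (length(miss_ref)) {
    stop("signature gene(s) missing from reference: ",
         paste(miss_ref, collapse = ", "), call. = FALSE)
  }
  miss_q <- setdiff(signature_genes, rownames(query_expr))
  if (length(miss_q)) {
    stop("signature gene(s) missing from query: ",
         paste(miss_q, collapse = ", "), call. = FALSE)
  }
  if (expr_layer(query_expr) != "log2") {
    query_expr <- log2_standardize(query_expr, pseudocount)
  }
  if (!is.null(names(reference_labels))) {
    reference_labels <- reference_labels[colnames(reference_expr)]
  }
  y <- as.character(reference_labels)
  scores <- knn_scores(
    as_plain_matrix(reference_expr)[signature_genes, , drop = FALSE], y,
    as_plain_matrix(query_expr)[signature_genes, , drop = FALSE], knn_k)
  group <- ifelse(scores > 0.5, "NL", "OT")
  res <- list(predictions = data.frame(sample_id = colnames(query_expr),
                                       group = group, score = unname(scores),
                                       row.names = NULL,
                                       stringsAsFactors = FALSE),
              counts = table(factor(group, levels = c("NL", "OT"))),
              signature_genes = sort(signature_genes))
  class(res) <- "transfer_result"
  res
}

#' Consensus NL calls across two signatures
#'
#' A query sample is consensus NL only when both transfer results predict
#' NL; all other samples are OT.
#'
#' @param result_a,result_b `transfer_result`s over the same query samples.
#' @return a `transfer_result` with the consensus predictions and the vector
#'   `nl_ids` of consensus NL sample ids.
#' @export
intersect_predictions <- function(result_a, result_b) {
  stopifnot(inherits(result_a, "transfer_result"),
            inherits(result_b, "transfer_result"))
  a <- result_a$predictions; b <- result_b$predictions
  if (!setequal(a$sample_id, b$sample_id)) {
    stop("the two results cover different query samples", call. = FALSE)
  }
  b <- b[match(a$sample_id, b$sample_id), ]
  group <- ifelse(a$group == "NL" & b$group == "NL", "NL", "OT")
  res <- list(predictions = data.frame(sample_id = a$sample_id, group = group,
                                       score = pmin(a$score, b$score),
                                       row.names = NULL,
                                       stringsAsFactors = FALSE),
              counts = table(factor(group, levels = c("NL", "OT"))),
              signature_genes = union(result_a$signature_genes,
                                      result_b$signature_genes),
              nl_ids = a$sample_id[group == "NL"])
  class(res) <- "transfer_result"
  res
}

#' Survival comparison of predicted groups in the query cohort
#'
#' Joins the transfer predictions with the query survival records and
#' compares predicted NL vs OT by Kaplan-Meier and log-rank. Samples without
#' survival are classified but excluded here (counts reported); when a
#' predicted group has fewer than 2 samples with survival, the report is
#' returned without a test.
#'
#' @param result a `transfer_result`.
#' @param records `data.frame` with `sample_id`, `time` (or
#'   `survival_months`) and `event`.
#' @return list with `km` (per-group [kaplan_meier()] fits), `medians`
#'   (with `NA` = not reached), `logrank` (or `NULL`), `n_with_survival`,
#'   `n_excluded`.
#' @export
validate_survival <- function(result, records) {
  stopifnot(inherits(result, "transfer_result"))
  if ("survival_months" %in% names(records) && !"time" %in% names(records)) {
    records$time <- records$survival_months
  }
  stopifnot(all(c("sample_id", "time", "event") %in% names(records)))
  pred <- result$predictions
  merged <- merge(pred, records[, c("sample_id", "time", "event")],
                  by = "sample_id")
  merged <- merged[!is.na(merged$time) & !is.na(merged$event), , drop = FALSE]
  n_excluded <- nrow(pred) - nrow(merged)
  if (n_excluded > 0) {
    message(n_excluded, " classified sample(s) lack survival and are excluded")
  }
  groups <- split(merged, merged$group)
  km <- lapply(groups, kaplan_meier)
  medians <- vapply(km, function(k) k$median, 0)
  lr <- NULL
  if (length(groups) == 2 && all(vapply(groups, nrow, 0L) >= 2)) {
    lr <- logrank_test(groups[[1]], groups[[2]])
  }
  list(km = km, medians = medians, logrank = lr,
       n_with_survival = nrow(merged), n_excluded = n_excluded)
}
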