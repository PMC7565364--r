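#' Run the discovery pipeline end to end
#'
#' Chains the stages on a synthetic cohort:
#' `simulate` (cohort generation), `de` (normal-vs-tumor differential
#' expression defining the clustering gene set), `cluster` (Pearson-distance
#' hierarchical clustering, k-cluster cut, normal-anchored NL/OT labeling),
#' `discover` (NL-vs-OT differential expression, stratified 80/20 split,
#' random-forest gene ranking, exhaustive minimal-signature search, held-out
#' test evaluation), `survival` (Kaplan-Meier and log-rank, NL vs OT) and
#' `validate` (transfer of the selected signature to a second, independently
#' simulated cohort, with survival comparison of the predicted groups).
#'
#' Stages must form a prefix of that chain unless earlier outputs already
#' exist in `outdir`. Every stage derives its own seed deterministically
#' from `config$seed` plus a stage-name offset, so a stage rerun reproduces
#' its outputs bit for bit; gene counts before and after each filter are
#' logged via `message()` and recorded in the manifest.
#'
#' @param config a [pipeline_config()].
#' @param design a [simulation_design()]; its seed is overridden by the
#'   stage-derived seed.
#' @param stages character vector, prefix of
#'   `c("simulate","de","cluster","discover","survival","validate")`, or
#'   `"all"`.
#' @param outdir output directory; created if missing. `NULL` keeps
#'   everything in memory and writes nothing.
#' @return invisibly, a list with `state` (all intermediate objects) and
#'   `manifest` (config snapshot, seeds, filter counts, outputs, timings).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         design = simulation_design(),
                         stages = "all", outdir = NULL) {
  all_stages <- c("simulate", "de", "cluster", "discover", "survival",
                  "validate")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  stages <- all_stages[all_stages %in% stages]
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  st <- new.env(parent = emptyenv())
  manifest <- list(config = unclass(config), design = unclass(design),
                   seed = config$seed, stages = stages,
                   versions = list(r = as.character(getRversion()),
                                   nlsig = as.character(
                                     utils::packageVersion("nlsig"))),
                   filter_counts = list(), outputs = list(), timings = list())
  stage_seed <- function(stage) config$seed + stage_seed_offset(stage)
  emit <- function(stage, name, writer) {
    if (is.null(outdir)) return(invisible())
    path <- file.path(outdir, name)
    writer(path)
    manifest$outputs[[stage]] <<- c(manifest$outputs[[stage]], name)
    invisible(path)
  }
  need <- function(obj, stage, producer) {
    if (!is.null(st[[obj]])) return(invisible())
    stop("stage '", stage, "' needs '", obj, "': run stage '", producer,
         "' first (or include it in 'stages')", call. = FALSE)
  }

  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    switch(stage,
      simulate = {
        design$seed <- stage_seed("simulate")
        cohort <- simulate_cohort(design)
        st$cohort <- cohort
        st$normal_ids <- cohort$samples$sample_id[
          cohort$samples$tissue_class == "normal"]
        st$tumor_ids <- cohort$samples$sample_id[
          cohort$samples$tissue_class == "tumor"]
        emit("simulate", "counts.tsv",
             function(p) write_expression_matrix(cohort$counts, p))
        emit("simulate", "abundance.tsv",
             function(p) write_expression_matrix(cohort$abundance, p))
        emit("simulate", "samples.tsv",
             function(p) write_sample_table(cohort$samples, p))
        emit("simulate", "truth.json", function(p)
          jsonlite::write_json(unclass(cohort$truth), p, auto_unbox = TRUE,
                               digits = NA))
      },
      de = {
        need("cohort", "de", "simulate")
        counts <- st$cohort$counts
        de_nt <- nb_two_group_test(counts, st$normal_ids, st$tumor_ids)
        st$de_normal_tumor <- de_nt
        st$cluster_genes <- de_filter(de_nt, config$de_fdr, config$de_abs_lfc)
        manifest$filter_counts$de_normal_vs_tumor <-
          c(before = nrow(de_nt), after = length(st$cluster_genes))
        message("de: ", nrow(de_nt), " genes tested, ",
                length(st$cluster_genes), " pass FDR<", config$de_fdr,
                " & |log2FC|>", config$de_abs_lfc)
        emit("de", "de_normal_vs_tumor.tsv", function(p)
          utils::write.table(de_nt, p, sep = "\t", quote = FALSE,
                             row.names = FALSE))
      },
      cluster = {
        need("cohort", "cluster", "simulate")
        need("cluster_genes", "cluster", "de")
        loga <- log2_standardize(st$cohort$abundance, config$pseudocount)
        sub <- expr_matrix(as_plain_matrix(loga)[st$cluster_genes, ,
                                                 drop = FALSE], "log2")
        d <- pearson_distance(center_genes(sub))
        tree <- hierarchical_cluster(d, config$linkage)
        assign <- cut_clusters(tree, config$n_clusters)
        assign <- assign_nl_ot(assign, st$normal_ids)
        st$assignment <- assign
        st$groups <- stats::setNames(assign$group, assign$sample_id)
        n_nl <- sum(assign$group == "NL", na.rm = TRUE)
        message("cluster: k=", config$n_clusters, ", ", n_nl,
                " tumor(s) labeled NL")
        manifest$filter_counts$cluster_nl <- n_nl
        emit("cluster", "cluster_assignment.tsv", function(p)
          utils::write.table(assign, p, sep = "\t", quote = FALSE,
                             row.names = FALSE, na = ""))
      },
      discover = {
        need("cohort", "discover", "simulate")
        need("groups", "discover", "cluster")
        counts <- st$cohort$counts
        tumors <- st$tumor_ids
        expressed <- expression_filter(counts, config$expr_min_count,
                                       config$expr_min_fraction)
        manifest$filter_counts$expression_filter <-
          c(before = nrow(counts), after = length(expressed))
        message("discover: expression filter keeps ", length(expressed),
                "/", nrow(counts), " genes")
        nl_ids <- tumors[st$groups[tumors] == "NL"]
        ot_ids <- tumors[st$groups[tumors] == "OT"]
        counts_f <- expr_matrix(as_plain_matrix(counts)[expressed, ,
                                                        drop = FALSE],
                                "counts")
        de_no <- nb_two_group_test(counts_f, nl_ids, ot_ids)
        candidates <- de_filter(de_no, config$de_fdr, config$de_abs_lfc)
        manifest$filter_counts$de_nl_vs_ot <-
          c(before = nrow(de_no), after = length(candidates))
        message("discover: ", length(candidates),
                " NL-vs-OT DE candidate genes")
        st$de_nl_ot <- de_no

        loga <- log2_standardize(st$cohort$abundance, config$pseudocount)
        split <- stratified_split(st$groups[tumors], config$test_fraction,
                                  seed = stage_seed("discover"))
        st$split <- split
        x_all <- as_plain_matrix(loga)
        x_train <- expr_matrix(x_all[candidates, split$train, drop = FALSE],
                               "log2")
        x_test <- expr_matrix(x_all[candidates, split$test, drop = FALSE],
                              "log2")
        y_train <- st$groups[split$train]
        y_test <- st$groups[split$test]
        top_n <- min(config$top_n_genes, length(candidates))
        ranked <- rank_genes_by_forest(x_train, y_train,
                                       n_forests = config$n_forests,
                                       top_n = top_n,
                                       n_trees = config$n_trees,
                                       seed = stage_seed("discover"))
        manifest$filter_counts$ranked_pool <- top_n
        search <- exhaustive_search(ranked, config$signature_sizes,
                                    x_train, y_train,
                                    knn_k = config$knn_k,
                                    cv_folds = config$cv_folds,
                                    seed = stage_seed("discover"),
                                    auroc_tolerance = config$auroc_tolerance)
        message("discover: ", search$n_evaluated,
                " candidate signatures evaluated; selected ",
                search$selected$signature)
        st$ranked <- ranked
        st$search <- search
        st$test_eval <- test_signature(search$selected_genes, x_train,
                                       y_train, x_test, y_test, config$knn_k)
        st$x_train <- x_train; st$y_train <- y_train
        emit("discover", "ranked_genes.tsv", function(p)
          utils::write.table(ranked, p, sep = "\t", quote = FALSE,
                             row.names = FALSE))
        emit("discover", "signature_candidates.tsv", function(p)
          utils::write.table(search$candidates, p, sep = "\t", quote = FALSE,
                             row.names = FALSE))
        emit("discover", "selected_signature.json", function(p)
          jsonlite::write_json(list(genes = search$selected_genes,
                                    cv = as.list(search$selected),
                                    test = st$test_eval[c("test_auroc",
                                                          "test_error",
                                                          "test_sensitivity",
                                                          "test_specificity")]),
                               p, auto_unbox = TRUE, digits = NA))
      },
      survival = {
        need("cohort", "survival", "simulate")
        need("groups", "survival", "cluster")
        samp <- as.data.frame(st$cohort$samples)
        samp <- samp[samp$tissue_class == "tumor", ]
        samp$group_pred <- st$groups[samp$sample_id]
        samp$time <- samp$survival_months
        by_group <- split(samp, samp$group_pred)
        st$km <- lapply(by_group, kaplan_meier)
        st$logrank <- if (length(by_group) == 2 &&
                          all(vapply(by_group, nrow, 0L) >= 2)) {
          logrank_test(by_group$NL, by_group$OT)
        } else NULL
        emit("survival", "survival_report.json", function(p)
          jsonlite::write_json(
            list(medians = lapply(st$km, function(k)
              if (k$median_reached) k$median else "not reached"),
              logrank = st$logrank), p, auto_unbox = TRUE, digits = NA))
      },
      validate = {
        need("search", "validate", "discover")
        vdesign <- design
        vdesign$seed <- stage_seed("validate")
        # the validation cohort shares the reference cohort's gene-level
        # biology; only its samples are new
        vcohort <- simulate_cohort(vdesign, gene_params = st$cohort$gene_params)
        vtumors <- vcohort$samples$sample_id[
          vcohort$samples$tissue_class == "tumor"]
        loga <- log2_standardize(st$cohort$abundance, config$pseudocount)
        ref <- expr_matrix(
          as_plain_matrix(loga)[, st$tumor_ids, drop = FALSE], "log2")
        query <- expr_matrix(
          as_plain_matrix(vcohort$abundance)[, vtumors, drop = FALSE],
          "abundance")
        transfer <- classify_external(ref, st$groups[st$tumor_ids],
                                      st$search$selected_genes, query,
                                      knn_k = config$knn_k,
                                      pseudocount = config$pseudocount)
        st$transfer <- transfer
        vsamp <- as.data.frame(vcohort$samples)
        st$transfer_survival <- validate_survival(
          transfer, vsamp[, c("sample_id", "survival_months", "event")])
        st$validation_cohort <- vcohort
        emit("validate", "transfer_predictions.tsv", function(p)
          utils::write.table(transfer$predictions, p, sep = "\t",
                             quote = FALSE, row.names = FALSE))
        emit("validate", "transfer_survival.json", function(p)
          jsonlite::write_json(
            list(counts = as.list(transfer$counts),
                 medians = as.list(st$transfer_survival$medians),
                 logrank = st$transfer_survival$logrank),
            p, auto_unbox = TRUE, digits = NA))
      })
    manifest$timings[[stage]] <- round(proc.time()[["elapsed"]] - t0, 3)
  }
  if (!is.null(outdir)) {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(state = as.list(st), manifest = manifest))
}
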