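#' Simulation design for a synthetic glioma-like cohort
#'
#' Describes a bulk RNA-seq cohort with the structure the analysis assumes:
#' a handful of normal control tissues, a small "normal-like" (NL) tumor
#' subgroup whose expression profile matches the normal baseline, and a
#' large "other tumors" (OT) group carrying many differentially expressed
#' genes. A few planted signature genes separate NL from OT bimodally
#' (half up-regulated in OT, half down-regulated, emulating marker pairs
#' such as an immune receptor up in aggressive tumors and a neuronal
#' transporter down). Survival is exponential with a group-dependent hazard
#' (OT median about 14.9 months by default; NL hazard a quarter of that)
#' under independent uniform administrative censoring calibrated to a
#' target censoring fraction.
#'
#' @param n_normal,n_nl,n_ot group sizes (defaults 5 / 14 / 224).
#' @param n_genes total genes simulated.
#' @param n_de_genes genes differentially expressed in OT (includes the
#'   signature genes).
#' @param de_lfc_mean absolute log2 fold change planted on ordinary DE genes.
#' @param nb_dispersion negative-binomial dispersion `alpha` in
#'   `Var = mu + alpha * mu^2`.
#' @param baseline_log_mean,baseline_log_sd per-gene baseline means are
#'   `2^N(baseline_log_mean, baseline_log_sd)`.
#' @param n_signature_genes planted signature genes (subset of the DE genes).
#' @param signature_lfc absolute log2 fold change planted on signature genes.
#' @param n_ot_subtypes OT expression subtypes (default 3, emulating the
#'   heterogeneous tumor sub-clusters that the analysis pools into a single
#'   OT group). Subtypes share which genes are dysregulated but differ in
#'   degree: each ordinary DE gene's fold change is scaled by a
#'   per-gene-permuted multiplier per subtype. Set to 1 for a homogeneous
#'   OT group. Signature genes are never modulated (OT-wide by design).
#' @param subtype_modulation half-width of the subtype multiplier range:
#'   multipliers are evenly spaced in `[1 - m, 1 + m]` (default 0.7, i.e.
#'   0.3x / 1x / 1.7x of the planted fold change for three subtypes).
#' @param hazard_ot OT event hazard per month (default `log(2)/14.9`, i.e.
#'   median survival 14.9 months).
#' @param hazard_nl_ratio NL hazard as a fraction of the OT hazard.
#' @param censor_fraction target fraction of censored tumor samples.
#' @param gene_length_kb optional per-gene transcript lengths in kb used for
#'   the FPKM-like abundance layer; drawn uniformly in \[0.5, 5\] if `NULL`.
#' @param seed integer seed; the whole cohort is deterministic given the design.
#' @return a validated list of class `simulation_design`.
#' @export
simulation_design <- function(n_normal = 5L, n_nl = 14L, n_ot = 224L,
                              n_genes = 2000L, n_de_genes = 300L,
                              de_lfc_mean = 3.0, nb_dispersion = 0.3,
                              baseline_log_mean = 4.0, baseline_log_sd = 1.5,
                              n_signature_genes = 4L, signature_lfc = 5.0,
                              n_ot_subtypes = 3L,
                              subtype_modulation = 0.7,
                              hazard_ot = log(2) / 14.9,
                              hazard_nl_ratio = 0.25,
                              censor_fraction = 0.3,
                              gene_length_kb = NULL,
                              seed = 1L) {
  des <- list(n_normal = as.integer(n_normal), n_nl = as.integer(n_nl),
              n_ot = as.integer(n_ot), n_genes = as.integer(n_genes),
              n_de_genes = as.integer(n_de_genes), de_lfc_mean = de_lfc_mean,
              nb_dispersion = nb_dispersion,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              n_signature_genes = as.integer(n_signature_genes),
              signature_lfc = signature_lfc,
              n_ot_subtypes = as.integer(n_ot_subtypes),
              subtype_modulation = subtype_modulation,
              hazard_ot = hazard_ot,
              hazard_nl_ratio = hazard_nl_ratio,
              censor_fraction = censor_fraction,
              gene_length_kb = gene_length_kb, seed = as.integer(seed))
  with(des, {
    if (n_de_genes + n_signature_genes > n_genes) {
      stop("infeasible design: n_de_genes + n_signature_genes > n_genes",
           call. = FALSE)
    }
    if (n_signature_genes > n_de_genes) {
      stop("infeasible design: more signature genes than DE genes", call. = FALSE)
    }
    if (min(n_normal, n_nl, n_ot, n_genes) < 1) {
      stop("all group and gene counts must be >= 1", call. = FALSE)
    }
    if (n_ot_subtypes < 1 || n_ot_subtypes > n_ot) {
      stop("n_ot_subtypes must be between 1 and n_ot", call. = FALSE)
    }
    if (subtype_modulation < 0 || subtype_modulation >= 1) {
      stop("subtype_modulation must be in [0, 1)", call. = FALSE)
    }
    if (hazard_ot <= 0 || hazard_nl_ratio <= 0 || nb_dispersion <= 0) {
      stop("all rates must be > 0", call. = FALSE)
    }
    if (de_lfc_mean < 0 || signature_lfc < 0) {
      stop("planted fold changes are absolute log2 magnitudes (>= 0)",
           call. = FALSE)
    }
  })
  if (!is.null(gene_length_kb)) {
    if (length(gene_length_kb) != des$n_genes || any(gene_length_kb <= 0)) {
      stop("gene_length_kb must be ", des$n_genes, " positive values",
           call. = FALSE)
    }
  }
  assert_scalar_number(des$censor_fraction, "censor_fraction",
                       lower = 1e-6, upper = 1 - 1e-6)
  class(des) <- "simulation_design"
  des
}

# Uniform(0, horizon) censoring of Exponential(rate) events gives
# P(censored) = (1 - exp(-rate * horizon)) / (rate * horizon).
# Solve the group-size-weighted mixture for the horizon hitting the target.
censoring_horizon <- function(rates, weights, target) {
  pc <- function(m) {
    sum(weights * (1 - exp(-rates * m)) / (rates * m)) / sum(weights)
  }
  stats::uniroot(function(m) pc(m) - target,
                 lower = 1e-6, upper = 1e7, tol = 1e-10)$root
}

#' Simulate a synthetic cohort with planted subgroup structure
#'
#' Draws counts per gene and sample from a negative binomial with
#' `Var = mu + alpha * mu^2`. Normal and NL samples share the per-gene
#' baseline mean; OT samples have the baseline shifted by the planted log2
#' fold change on DE genes (half up, half down). Signature genes are the
#' first `n_signature_genes` DE genes and carry `signature_lfc` instead
#' (half up-in-OT, half down-in-OT). The abundance layer is FPKM-like:
#' `counts / (gene_length_kb * library_size / 1e6)`. Tumor survival is
#' exponential by group hazard, right-censored by an independent uniform
#' horizon calibrated so the expected censored fraction matches the design.
#'
# Gene-level parameters of a simulated cohort: per-gene baseline means,
# transcript lengths, the planted DE set with directions, and the subtype
# modulation multipliers. Drawn once per biology; a validation cohort drawn
# against the same parameters shares the genes' behaviour while its samples
# are new.
draw_gene_params <- function(d) {
  base_log2 <- stats::rnorm(d$n_genes, d$baseline_log_mean, d$baseline_log_sd)
  lengths_kb <- if (is.null(d$gene_length_kb)) {
    stats::runif(d$n_genes, 0.5, 5)
  } else d$gene_length_kb
  de_idx <- sort(sample.int(d$n_genes, d$n_de_genes))
  sig_idx <- de_idx[seq_len(d$n_signature_genes)]
  other_de <- setdiff(de_idx, sig_idx)
  # every DE gene shifts in every OT sample (half up, half down); OT
  # subtypes modulate the *degree* of the shift per gene, giving the
  # pooled OT group internal heterogeneity while keeping each DE gene
  # detectable in the normal-vs-tumor contrast
  lfc <- numeric(d$n_genes)
  if (length(other_de)) {
    lfc[other_de] <- rep_len(c(d$de_lfc_mean, -d$de_lfc_mean),
                             length(other_de))
  }
  if (length(sig_idx)) {
    sig_up <- sig_idx[seq_len(ceiling(length(sig_idx) / 2))]
    lfc[sig_idx] <- -d$signature_lfc
    lfc[sig_up] <- d$signature_lfc
  }
  mods <- if (d$n_ot_subtypes > 1) {
    seq(1 - d$subtype_modulation, 1 + d$subtype_modulation,
        length.out = d$n_ot_subtypes)
  } else 1
  mod_mat <- matrix(1, d$n_genes, d$n_ot_subtypes)
  if (d$n_ot_subtypes > 1 && length(other_de)) {
    for (g in other_de) mod_mat[g, ] <- sample(mods)
  }
  structure(list(base_log2 = base_log2, lengths_kb = lengths_kb,
                 de_idx = de_idx, sig_idx = sig_idx, lfc = lfc,
                 mod_mat = mod_mat, n_genes = d$n_genes),
            class = "sim_gene_params")
}

#' @param design a [simulation_design()].
#' @param gene_params optionally, the `gene_params` element of a previously
#'   simulated cohort: the new cohort then shares that cohort's gene-level
#'   biology (baseline means, lengths, DE set and directions) and only the
#'   samples are drawn afresh — the situation of an independent validation
#'   cohort.
#' @return a list with elements `counts` and `abundance` ([expr_matrix()]),
#'   `samples` (a [sample_table()] with true `group` filled in for reference),
#'   `truth` (see [planted_truth()]) and `gene_params`.
#' @export
simulate_cohort <- function(design = simulation_design(), gene_params = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  d <- design
  if (!is.null(gene_params)) {
    stopifnot(inherits(gene_params, "sim_gene_params"))
    if (gene_params$n_genes != d$n_genes) {
      stop("gene_params were drawn for ", gene_params$n_genes,
           " genes, design has ", d$n_genes, call. = FALSE)
    }
  }
  local_seed(d$seed, {
    gene_ids <- sprintf("gene%04d", seq_len(d$n_genes))
    sample_ids <- c(sprintf("NORM%02d", seq_len(d$n_normal)),
                    sprintf("NL%03d", seq_len(d$n_nl)),
                    sprintf("OT%03d", seq_len(d$n_ot)))
    group <- rep(c("normal", "NL", "OT"), c(d$n_normal, d$n_nl, d$n_ot))

    gp <- if (is.null(gene_params)) draw_gene_params(d) else gene_params
    mu0 <- 2^gp$base_log2
    lengths_kb <- gp$lengths_kb
    de_idx <- gp$de_idx; sig_idx <- gp$sig_idx; lfc <- gp$lfc
    ot_subtype <- rep_len(seq_len(ncol(gp$mod_mat)), d$n_ot)

    n_samples <- length(sample_ids)
    mu <- matrix(mu0, d$n_genes, n_samples)
    ot_cols <- which(group == "OT")
    mu[, ot_cols] <- mu[, ot_cols] *
      2^(lfc * gp$mod_mat[, ot_subtype, drop = FALSE])
    size <- 1 / d$nb_dispersion
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = size),
                     d$n_genes, n_samples,
                     dimnames = list(gene_ids, sample_ids))

    lib <- colSums(counts)
    abundance <- counts / outer(lengths_kb, lib / 1e6)
    # samples with an (unrealistic) all-zero library would divide by zero
    abundance[, lib == 0] <- 0

    tumor <- group != "normal"
    rates <- ifelse(group[tumor] == "NL",
                    d$hazard_ot * d$hazard_nl_ratio, d$hazard_ot)
    horizon <- censoring_horizon(
      rates = c(d$hazard_ot * d$hazard_nl_ratio, d$hazard_ot),
      weights = c(d$n_nl, d$n_ot), target = d$censor_fraction)
    event_time <- stats::rexp(sum(tumor), rate = rates)
    censor_time <- stats::runif(sum(tumor), 0, horizon)
    time <- pmin(event_time, censor_time)
    event <- as.integer(event_time <= censor_time)

    grade <- rep(NA_character_, n_samples)
    grade[group == "NL"] <- sample(c("G2", "G3"), d$n_nl, TRUE, c(0.57, 0.43))
    grade[group == "OT"] <- sample(c("G3", "G4"), d$n_ot, TRUE, c(0.3, 0.7))

    samples <- sample_table(data.frame(
      sample_id = sample_ids,
      tissue_class = ifelse(tumor, "tumor", "normal"),
      cohort = "synthetic",
      group = ifelse(group == "normal", NA_character_, group),
      grade = grade,
      survival_months = replace(rep(NA_real_, n_samples), tumor, time),
      event = replace(rep(NA_integer_, n_samples), tumor, event),
      stringsAsFactors = FALSE))

    subtype_lab <- rep(NA_character_, n_samples)
    subtype_lab[ot_cols] <- paste0("OT", ot_subtype)
    truth <- list(
      group = stats::setNames(group, sample_ids),
      ot_subtype = stats::setNames(subtype_lab, sample_ids),
      de_gene_ids = gene_ids[de_idx],
      signature_gene_ids = gene_ids[sig_idx],
      signature_direction = stats::setNames(
        ifelse(lfc[sig_idx] > 0, "up-in-OT", "down-in-OT"),
        gene_ids[sig_idx]),
      gene_length_kb = stats::setNames(lengths_kb, gene_ids),
      censoring_horizon_months = horizon)
    class(truth) <- "planted_truth"

    list(counts = expr_matrix(counts, "counts"),
         abundance = expr_matrix(abundance, "abundance"),
         samples = samples,
         truth = truth,
         gene_params = gp)
  })
}

#' Planted ground truth for a simulation design
#'
#' Returns the truth object (`group` per sample, DE gene ids, signature gene
#' ids with direction) that [simulate_cohort()] emits for the same design and
#' seed, without keeping the expression matrices.
#'
#' @param design a [simulation_design()].
#' @return a `planted_truth` list.
#' @export
planted_truth <- function(design = simulation_design()) {
  simulate_cohort(design)$truth
}
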