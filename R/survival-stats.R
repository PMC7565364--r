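# Survival machinery: product-limit curves, log-rank comparison, Cox
# proportional hazards (Efron ties), null-model Martingale residuals and the
# expression-category construction used for signature-based Cox models.
# Estimation is delegated to the survival package; this file owns the
# surrounding contracts (median "not reached" semantics, residual arithmetic,
# binning rules).

as_surv_records <- function(records) {
  stopifnot(all(c("time", "event") %in% names(records)))
  records <- records[!is.na(records$time) & !is.na(records$event), , drop = FALSE]
  if (!nrow(records)) stop("no usable survival records", call. = FALSE)
  if (any(records$time <= 0)) stop("survival times must be > 0", call. = FALSE)
  if (!all(records$event %in% 0:1)) stop("event must be 0/1", call. = FALSE)
  records
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with right censoring. The median is the first
#' time at which the survival curve drops to 0.5 or below; when the curve
#' never reaches 0.5 the median is reported as not reached (`NA` with
#' `median_reached = FALSE`), mirroring the usual "> max observed time"
#' reading.
#'
#' @param records `data.frame` with columns `time` (months, > 0) and `event`
#'   (1 = death, 0 = censored).
#' @return list with `step` (`data.frame` of `time`, `n_risk`, `n_event`,
#'   `surv`), `median`, `median_reached`, `max_time`.
#' @export
kaplan_meier <- function(records) {
  records <- as_surv_records(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  step <- data.frame(time = fit$time, n_risk = fit$n.risk,
                     n_event = fit$n.event, surv = fit$surv)
  reached <- any(fit$surv <= 0.5)
  med <- if (reached) min(fit$time[fit$surv <= 0.5]) else NA_real_
  list(step = step, median = med, median_reached = reached,
       max_time = max(records$time))
}

#' Log-rank test between two survival groups
#'
#' Standard observed-minus-expected chi-square statistic over the pooled
#' event times, 1 degree of freedom.
#'
#' @param records_a,records_b `data.frame`s with `time` and `event`.
#' @return list with `chisq`, `p`, `df`.
#' @export
logrank_test <- function(records_a, records_b) {
  a <- as_surv_records(records_a)
  b <- as_surv_records(records_b)
  pooled <- rbind(data.frame(time = a$time, event = a$event, grp = "A"),
                  data.frame(time = b$time, event = b$event, grp = "B"))
  if (sum(pooled$event) == 0) stop("no events in the pooled data", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = pooled)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(chisq = unname(sd$chisq), p = p, df = 1L)
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie handling. Categorical covariates
#' enter with the stated reference level; continuous covariates enter as is.
#' Reports, per coefficient, the log hazard `beta`, the hazard ratio
#' `exp(beta)` with its Wald 95% confidence interval, and the Wald p-value.
#' Suspected monotone-likelihood separation (unbounded coefficients) is
#' flagged rather than returned silently.
#'
#' @param records `data.frame` with `time`, `event` and the covariate columns.
#' @param covariates character vector of covariate column names.
#' @param reference_levels optional named list giving the reference level of
#'   categorical covariates (defaults to the first level alphabetically).
#' @return list with `coefficients` (`data.frame`: `term`, `beta`, `hr`,
#'   `ci_lower`, `ci_upper`, `p`), `loglik`, `n`, `n_event`, `converged`,
#'   `separation`.
#' @export
cox_fit <- function(records, covariates, reference_levels = NULL) {
  records <- as_surv_records(records)
  missing_cov <- setdiff(covariates, names(records))
  if (length(missing_cov)) {
    stop("covariate(s) not in records: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  df <- records
  for (cv in covariates) {
    if (is.character(df[[cv]]) || is.factor(df[[cv]])) {
      lev <- levels(factor(df[[cv]]))
      ref <- reference_levels[[cv]]
      if (!is.null(ref)) {
        if (!ref %in% lev) stop("reference level '", ref, "' not observed for ",
                                cv, call. = FALSE)
        lev <- c(ref, setdiff(lev, ref))
      }
      df[[cv]] <- factor(df[[cv]], levels = lev)
    }
  }
  df <- df[stats::complete.cases(df[, c("time", "event", covariates)]), ,
           drop = FALSE]
  if (sum(df$event) < 1) stop("need at least one event", call. = FALSE)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(sprintf("`%s`", covariates),
                                       collapse = " + ")))
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        monotone <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  s <- summary(fit)
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  coefs <- data.frame(term = names(beta), beta = unname(beta),
                      hr = unname(exp(beta)),
                      ci_lower = unname(exp(beta - 1.96 * se)),
                      ci_upper = unname(exp(beta + 1.96 * se)),
                      p = unname(s$coefficients[, "Pr(>|z|)"]),
                      row.names = NULL, stringsAsFactors = FALSE)
  separation <- monotone || any(abs(beta) > 15 | se > 100, na.rm = TRUE)
  converged <- all(is.finite(beta)) && all(is.finite(se))
  if (separation) {
    warning("possible monotone likelihood (separation): ",
            "unbounded coefficient detected")
  }
  list(coefficients = coefs, loglik = unname(fit$loglik[2]),
       n = fit$n, n_event = fit$nevent,
       converged = converged, separation = separation,
       score_chisq = unname(fit$score))
}

#' Martingale residuals under the covariate-free Cox model
#'
#' `residual_i = event_i - H(t_i)` with `H` the Nelson-Aalen cumulative
#' hazard (`sum of d_j / n_j` over event times up to `t_i`). Plotted against
#' a continuous covariate these residuals diagnose whether the covariate can
#' enter a Cox model linearly.
#'
#' @param records `data.frame` with `time` and `event`.
#' @return numeric vector of residuals, one per record (input order).
#' @export
martingale_residuals_null <- function(records) {
  records <- as_surv_records(records)
  t_ev <- sort(unique(records$time[records$event == 1]))
  d <- vapply(t_ev, function(t) sum(records$time == t & records$event == 1), 0)
  n_risk <- vapply(t_ev, function(t) sum(records$time >= t), 0)
  haz <- d / n_risk
  H <- cumsum(haz)
  cumhaz_at <- function(t) {
    i <- findInterval(t, t_ev)
    ifelse(i == 0, 0, H[pmax(i, 1)])
  }
  records$event - cumhaz_at(records$time)
}

#' Combined expression categories for a 2-gene signature
#'
#' Bins the first gene by empirical tertiles (low/medium/high) and the
#' second by its median (low/high), giving the six combined categories used
#' as a categorical signature covariate in Cox models. Thresholds are
#' computed on a reference cohort (by default the input itself) so they can
#' be reused on new samples; a value falling exactly on a threshold is
#' assigned to the lower bin.
#'
#' @param expr_gene1,expr_gene2 numeric expression vectors over the same
#'   samples.
#' @param gene_names length-2 character vector used in the labels.
#' @param reference optional list with numeric vectors `gene1`, `gene2` from
#'   which thresholds are computed instead.
#' @return factor of labels `"<g1>_<low|medium|high>-<g2>_<low|high>"` with
#'   all 6 levels, plus a `thresholds` attribute.
#' @export
categorize_signature_expression <- function(expr_gene1, expr_gene2,
                                            gene_names = c("gene1", "gene2"),
                                            reference = NULL) {
  if (length(expr_gene1) != length(expr_gene2)) {
    stop("expression vectors must cover the same samples", call. = FALSE)
  }
  ref1 <- if (is.null(reference)) expr_gene1 else reference$gene1
  ref2 <- if (is.null(reference)) expr_gene2 else reference$gene2
  q1 <- stats::quantile(ref1, c(1 / 3, 2 / 3), names = FALSE, type = 7)
  q2 <- stats::median(ref2)
  if (q1[1] == q1[2] || stats::var(ref1) == 0 || stats::var(ref2) == 0) {
    stop("degenerate expression thresholds (constant or near-constant vector)",
         call. = FALSE)
  }
  lvl1 <- ifelse(expr_gene1 <= q1[1], "low",
                 ifelse(expr_gene1 <= q1[2], "medium", "high"))
  lvl2 <- ifelse(expr_gene2 <= q2, "low", "high")
  labels <- paste0(gene_names[1], "_", lvl1, "-", gene_names[2], "_", lvl2)
  all_levels <- as.vector(t(outer(
    paste0(gene_names[1], "_", c("low", "medium", "high")),
    paste0(gene_names[2], "_", c("low", "high")),
    function(a, b) paste0(a, "-", b))))
  out <- factor(labels, levels = all_levels)
  attr(out, "thresholds") <- list(gene1_tertiles = q1, gene2_median = q2)
  out
}
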