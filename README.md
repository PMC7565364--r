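# nlsig

Discovery of a **normal-like (NL) tumor subgroup** in bulk RNA-seq cohorts,
and of **minimal k-gene classifier signatures** separating it from the other
tumors (OT).

Some tumors express a transcriptome nearly indistinguishable from normal
control tissue. They carry fewer genomic alterations and survive markedly
longer, but no single marker or histological feature identifies them.
`nlsig` implements the full discovery workflow for such a subgroup:

1. **Differential expression** on raw counts: median-of-ratios size
   factors, a negative-binomial Wald test with method-of-moments
   dispersion (`Var = μ + αμ²`), Benjamini–Hochberg correction, and the
   strict filters `p_adj < 0.001` and `|log2FC| > 2` after an expression
   filter (≥ 1 count in ≥ 75% of samples).
2. **Unsupervised clustering** of samples on the normal-vs-tumor DE genes:
   `log2(x + 0.01)` standardization, per-gene centering, Pearson
   correlation distance `d = 1 − r`, agglomerative clustering (Ward by
   default), a k = 4 cut, and *normal anchoring*: the cluster containing
   all normal controls defines NL; every other tumor is OT.
3. **Signature search**: stratified 80/20 split (238 samples → 190/48);
   genes ranked by mean decrease in Gini impurity averaged over 100 random
   forests; exhaustive evaluation of every 1-, 2- and 3-gene combination
   from the top 50 with a k-nearest-neighbor classifier (k = 5, Euclidean
   distance on log2 expression) under 10-fold stratified cross-validation;
   selection of the smallest signature whose cross-validated AUROC is
   within 0.005 of the best.
4. **Survival statistics**: Kaplan–Meier with "not reached" medians,
   log-rank tests, Cox proportional hazards (Efron ties, Wald CIs,
   separation flagging), null-model Martingale residuals, and tertile ×
   median expression categories for signature covariates.
5. **Exact association tests**, implemented from first principles:
   Fisher's exact test for 2×2 and r×c tables by full fixed-margin
   enumeration (point-probability rule) or Monte-Carlo (Patefield
   sampling, p floored at 1/(B+1)), chi-square with Cramér's V
   `V = sqrt(χ²/(N·(min(r,c)−1)))`, and Mann–Whitney U.
6. **External validation**: transfer of a discovered signature to an
   independent cohort by a reference-trained KNN after identical log2
   standardization, consensus calls across signatures, and survival
   comparison of the predicted groups.

A **synthetic cohort generator** (`simulate_cohort()`) provides cohorts
with the exact structure the analysis assumes — negative-binomial counts,
a 5/14/224 normal/NL/OT design over 2000 genes, three OT expression
subtypes, four planted bimodal signature genes, exponential survival with
a 14.9-month OT median and an NL hazard ratio of 0.25, calibrated uniform
censoring — so every stage is testable end to end without any downloads.
See the methods vignette (`vignettes/normal-like-discovery.Rmd`) for the
model, the design choices and their rationale.

## Worked example

```r
library(nlsig)

cfg <- pipeline_config(seed = 1)
res <- run_pipeline(cfg, simulation_design(),
                    stages = c("simulate", "de", "cluster", "discover",
                               "survival"))
#> de: 2000 genes tested, 108 pass FDR<0.001 & |log2FC|>2
#> cluster: k=4, 14 tumor(s) labeled NL
#> discover: expression filter keeps 1892/2000 genes
#> discover: 208 NL-vs-OT DE candidate genes
#> discover: 20875 candidate signatures evaluated; selected gene0004

st <- res$state
st$search$selected
#>   signature size   cv_error  cv_auroc cv_sensitivity cv_specificity
#> 1  gene0004    1 0.01052632 0.9951752      0.9090909      0.9944134

st$test_eval$test_auroc          # held-out 48-sample test set
#> [1] 0.9962963

sapply(st$km, function(k) k$median)   # median survival, months
#>       NL       OT
#> 43.29019 15.69334

st$logrank$p                     # NL vs OT log-rank
#> [1] 0.01052047
```

Reading the output: the clustering stage recovered all 14 planted
normal-like tumors (they co-clustered with the 5 normal controls at k = 4);
the exhaustive search over 20 875 candidate signatures selected a single
planted signature gene whose cross-validated AUROC (0.995) was within the
0.005 tolerance of the best candidate, so the minimal-size rule stopped at
one gene; on the held-out test set that signature reaches AUROC 0.996; and
the NL group's median survival (43.3 months) clearly exceeds the OT
median of 15.7 months (log-rank p = 0.011), consistent with the planted
hazard ratio of 0.25 against an OT median of 14.9 months.

The same objects are written as TSV/JSON when `outdir` is given, together
with a manifest that makes the run reproducible bit for bit. Exact tests
are available directly, e.g. a 2×2 cluster-concordance table:

```r
fisher_exact_2x2(matrix(c(0, 11, 42, 0), 2))
#> [1] 1.311927e-11
```

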