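---
title: "Discovering a normal-like tumor subgroup and minimal gene signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering a normal-like tumor subgroup and minimal gene signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlsig)
```

## The problem

In bulk RNA-seq tumor cohorts that include a few normal control tissues, a
small fraction of tumors can present an expression profile that is nearly
indistinguishable from normal tissue. Such "normal-like" (NL) tumors tend to
carry fewer genomic alterations and to have markedly better survival than
the remaining "other tumors" (OT), yet they are invisible to histology and
to single-marker assays. `nlsig` implements a complete, testable pipeline
for (i) discovering an NL subgroup by unsupervised clustering anchored on
the normal controls, (ii) finding *minimal* k-gene classifier signatures
(k = 1–3) that separate NL from OT, and (iii) characterizing the subgroup
with survival and exact association statistics.

## The pipeline, stage by stage

### Differential expression (`nb_two_group_test`)

Raw counts are normalized by median-of-ratios size factors (rescaled to
geometric mean 1). Each gene is tested with a transparent negative-binomial
Wald test: the dispersion $\alpha$ in $\mathrm{Var} = \mu + \alpha\mu^2$ is
estimated per gene by a df-weighted method of moments pooled across the two
groups (floored at $10^{-8}$), and the statistic is the difference of log
normalized group means over its delta-method standard error, referred to a
standard normal. The log2 fold change is
$\log_2\{(m_B + pc)/(m_A + pc)\}$ with $pc$ equal to half a count in an
average size-adjusted library, so genes silent in both groups report a fold
change of exactly zero. Two deliberate simplifications relative to
full-featured DE packages: no dispersion shrinkage across genes and no
outlier handling. The downstream filters (`p_adj < 0.001` and
`|log2FC| > 2`, both strict, after a `>= 1` count in `>= 75%` of samples
expression filter) operate far from the regime where those refinements
matter, and the test suite checks the test's type-I calibration and its
power on planted fold changes directly.

### Clustering and NL anchoring (`pearson_distance`, `hierarchical_cluster`)

Samples are clustered on the genes differentially expressed between normal
and tumor tissue, after `log2(x + 0.01)` standardization, using the Pearson
correlation distance $d = 1 - r$ and agglomerative clustering. Two design
choices matter here:

* **Per-gene centering** (`center_genes()`) is applied before computing
  sample–sample correlations, exactly as expression heatmaps standardize
  rows. Without it every pair of samples shares the absolute expression
  profile (which genes are high, which low), that shared component
  dominates every covariance, and no biological sample group can form a
  tight cluster. After centering, correlations are driven by each sample's
  deviation from the cohort average — the signal the subgrouping is about.
  `pearson_distance()` itself stays a plain Pearson distance so that its
  algebraic contract (affine invariance per sample, $d \in [0, 2]$) holds;
  centering is an explicit, separate step.
* **Ward linkage by default.** Complete linkage keys on the *maximum*
  pairwise distance inside a cluster, a statistic that correlation
  distances on noisy counts inflate badly through low-expression genes; in
  practice it shaves outlier samples off the small normal-anchored cluster.
  Ward (ward.D2) minimizes within-cluster variance and is robust to those
  tails. Complete and average linkage remain available via
  `pipeline_config(linkage = )`.

The tree is cut into `n_clusters = 4` groups (no automatic selection of k;
four is the structure this analysis is designed around, and the synthetic
cohort below plants exactly that). The cluster containing **all** normal
controls defines NL; if the normals do not co-cluster the anchoring rule is
undefined and the pipeline raises an explicit error rather than guessing —
the seed-swept tests quantify how often that happens.

### Signature search (`rank_genes_by_forest`, `exhaustive_search`)

Tumors are split 80/20 by a stratified split (238 samples with a 14-member
NL class split 190/48). On the training set, the NL-vs-OT differentially
expressed genes are ranked by the mean decrease in Gini impurity averaged
over `n_forests = 100` independently seeded random forests (500 trees each,
$\sqrt{p}$ features per split, grown to purity; the `ranger` engine with
one thread, for determinism). Every combination of 1, 2 and 3 genes from
the top 50 is then scored by a k-nearest-neighbor classifier (Euclidean
distance on the log2 expression of the signature genes, no per-gene
rescaling) under 10-fold stratified cross-validation, pooling per-fold
predictions before computing the error rate, AUROC (equal to the
Mann–Whitney statistic, mid-rank ties), sensitivity and specificity, with
NL as the positive class and the fraction of NL neighbors as the ROC score.

The selection rule operationalizes "smallest signature with the best
performance": find the maximum cross-validated AUROC $A^*$ over all
candidates, keep candidates with AUROC $\ge A^* - 0.005$, and among those
take the smallest size, breaking ties by lower error, then higher
sensitivity, then lexicographic gene ids. The 0.005 tolerance
(`auroc_tolerance`) is this package's concrete reading of an informal
rule; it is configurable. With strongly bimodal planted markers a single
gene frequently attains the best AUROC, in which case the rule correctly
returns a 1-gene signature — minimality is preferred over matching any
particular signature size.

Two parameters have no external specification and are package choices,
stated prominently: the KNN neighborhood `knn_k = 5` (odd, so majority
votes cannot tie; small enough for an 11-member minority class in the
training folds) and the reduction of cross-validation folds to the minority
class size (with a warning) when that class is smaller than the requested
fold count, so small cohorts still run.

### Survival and association statistics

Kaplan–Meier curves, log-rank tests and Cox proportional-hazards
regressions (Efron tie handling, Wald confidence intervals, explicit
flagging of monotone-likelihood separation) stand on the `survival`
package; medians that never reach $S(t) \le 0.5$ are reported as "not
reached" rather than a number. Null-model Martingale residuals
($\delta_i - \hat H(t_i)$ with $\hat H$ the Nelson–Aalen estimator) support
linearity diagnostics for continuous covariates; where a gene's expression
fails that check, `categorize_signature_expression()` builds the 3×2
categorical signature covariate (first gene by empirical tertiles, second
by its median, values exactly on a threshold assigned to the lower bin).
The tertile-by-median scheme is inferred from the level structure such
models are reported with; the exact quantiles are otherwise unspecified and
this is a documented package choice.

Fisher exact tests are implemented from first principles because the
published concordance tables are the package's exact-value anchors: the
two-sided p is the point-probability rule (sum of fixed-margin tables no
more probable than the observed one, with a relative tolerance of $10^{-7}$
on the comparison), computed by full recursive enumeration of the
fixed-margin support in log-space (guarded at $10^7$ tables) or by
Monte-Carlo with Patefield fixed-margin sampling,
$p = (1 + \#\{P(T_b) \le P(\mathrm{obs})\})/(B + 1)$, whose floor at the
default $B = 2000$ is $1/2001 \approx 5.0\times10^{-4}$ — the floor visible
in published Monte-Carlo p-values. `fisher.test` and an independent
expand-grid enumeration serve as oracles in the tests, never as the
implementation.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions the pipeline assumes, at
their published scale: 5 normal controls, 14 NL tumors and 224 OT tumors
over 2000 genes. Counts are negative binomial with
$\mathrm{Var} = \mu + \alpha\mu^2$, $\alpha = 0.3$; per-gene baseline means
are $2^{N(4, 1.5)}$. NL and normal samples share the baseline; OT samples
shift 300 DE genes by $\pm 3$ log2 units (half up, half down). Four
signature genes (a subset of the DE genes) carry $\pm 5$ log2 units, two up
and two down in OT, emulating bimodal marker pairs. The abundance layer is
FPKM-like (`counts / (length_kb * library_size / 1e6)`) with transcript
lengths drawn once per gene. Survival is exponential per group — the OT
hazard defaults to $\ln 2 / 14.9$ per month, i.e. a 14.9-month median, and
NL to a quarter of that — under independent uniform administrative
censoring whose horizon is calibrated by root-finding so the expected
censored fraction is 0.30.

**OT subtypes.** The cohort this analysis is modeled on has four clusters:
the normal-anchored one plus three tumor sub-clusters that the analysis
pools into OT. A homogeneous OT group cannot reproduce that: with one OT
profile a k = 4 cut must split the loose baseline blob, and the anchoring
rule fails by construction. The generator therefore gives OT three
expression subtypes that share *which* genes are dysregulated but differ in
*degree*: each ordinary DE gene's fold change is multiplied, per subtype,
by a per-gene-permuted factor from 0.3/1.0/1.7
(`n_ot_subtypes = 3`, `subtype_modulation = 0.7`). This multiplicative form
is the only subtype structure whose genes survive the normal-vs-tumor DE
filter in both directions — subtype-private down-regulated genes
mathematically cannot reach $|log2FC| > 2$ after mixture dilution across
224 tumors. Signature genes are never modulated: they are OT-wide
discriminators by design. The modulation width was fixed at 0.7 during
generator design as the value at which the four planted clusters are
geometrically distinct under centered Pearson distance.

A validation cohort is drawn against the *same gene-level parameters*
(`simulate_cohort(design, gene_params = )`): baseline means, lengths, DE
set, directions and modulations are properties of the genes, not of the
cohort, exactly as in a real external dataset; only the samples are new.

**What the generator does not model:** batch or platform effects between
cohorts, GC/length biases, library-size confounding with group, correlated
gene modules beyond the planted group structure, non-proportional hazards,
or informative censoring. Passing tests therefore demonstrate that the
pipeline recovers the structure it assumes when that structure is present
at realistic noise levels — not that it is robust to the many ways real
cohorts violate those assumptions.

## Numerical choices and degenerate inputs

* Pseudocount 0.01 throughout log2 standardization; applied identically to
  reference and query cohorts before KNN transfer.
* Dispersion floored at $10^{-8}$; all-zero genes report zero fold change
  and p = 1.
* Distance ties in KNN resolve to the lowest sample index; hierarchical
  merge ties follow `hclust`'s deterministic order.
* Zero-variance genes are dropped (with a message) before correlation;
  zero-variance *samples* are an error naming the sample.
* Every stochastic stage derives its seed from one configuration seed plus
  a stage-name offset, so stages can be rerun in isolation bit-for-bit.
* Degenerate contingency margins, single-class folds, monotone-likelihood
  Cox fits and constant expression vectors are explicit errors or flagged
  results, never silent numbers.

## Scale of the validation runs

The seed-swept recovery checks in the test suite run the full default
cohort (243 samples, 2000 genes) through the whole chain. For the ten-seed
signature-recovery sweep the ranking and search stages run at a reduced
depth chosen for the purpose — 25 forests of 100 trees over the top 25
genes (2 625 candidate signatures per seed) — which on strongly separated
planted markers ranks and selects identically to the full
100 × 500 / top-50 configuration (the single-run checks and the acceptance
script use the full configuration). The log-rank calibration uses 1000
null replicates at n = 100 per arm; Cox hazard-ratio recovery uses 100
replicates at n = 500 with ~30% censoring.

## Known limitations

* The NB Wald test is mildly anti-conservative at small sample sizes (its
  null rejection rate sits near the upper end of the tested band); the
  strict double filter absorbs this for discovery purposes.
* The anchoring rule requires the normals to co-cluster at the configured
  k; on a minority of simulated seeds they do not, and the pipeline stops
  with an explicit error. This is reported, not patched over.
* KNN transfer applies no batch correction beyond shared log2
  standardization; across platforms with gene-specific biases the
  neighborhoods can shift. The transfer tests only cover
  same-generative-process cohorts.
* Exact agreement with any particular published DE package is a non-goal;
  agreement is at the level of filter outcomes on well-separated genes.
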