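---
title: "Methods: severity stratification of IPF transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: severity stratification of IPF transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipfstrat)
```

# The analysis problem

Idiopathic pulmonary fibrosis (IPF) cohorts profiled on expression
microarrays show strong molecular heterogeneity that correlates only
loosely with the standard severity measures — percent-predicted FEV1, FVC
and D~LCO~. `ipfstrat` stratifies patients by expression *before* asking
which genes change, so that genes shared by all patient subgroups (the
*core* signature) can be separated from genes private to the most severe
subgroup (the *advanced* signature), and both can be turned into
diagnostic classifiers and a candidate biomarker panel.

This vignette documents the statistical model behind each stage, the
tunable parameters and their defaults, the numerical conventions, and the
limits of what the synthetic cohorts can establish.

# Preprocessing

Raw matrices may carry several probes per gene symbol. Duplicates are
collapsed per sample with the **median** by default (robust to a single
aberrant probe; `mean` available), then values are log2-transformed with a
pseudo-count offset (default 1 for raw intensities; use 0 / skip for
pre-logged data) and **median-centered per gene**. Median centering is
idempotent, so running the step on already-centered data is harmless.
Classifier stages additionally min–max scale each gene to [0, 1] using a
reference learned on the training cohort only; validation values outside
the training range are clipped, and a gene constant in training maps to
0.5.

# Subtype discovery

Principal components are fitted on **disease samples only** — so the axes
describe variation among patients rather than the patient-versus-control
contrast — and all samples are projected onto them. Clustering runs on the
scores of the top-variance genes:

* `variance_fraction` (default 0.25): fraction of genes, by unbiased
  sample variance among disease samples, fed to PCA. The top quartile is
  the conventional choice for this kind of cohort.
* `explained_variance` (default 0.9): components are retained until their
  cumulative explained-variance fraction reaches this target. The source
  analyses do not state how many components fed clustering; a cumulative
  target adapts the dimension to the realized signal and is exposed as
  configuration.

Patients are clustered with **Ward's minimum-variance criterion on
Euclidean distances** (`hclust` method `ward.D2`, the Lance–Williams form
of Ward on unsquared distances). The cluster count is selected by clinical
separation: for each candidate *k* in `[k_min, k_max]` (defaults 2 and
10), the score is the mean over FEV1, FVC and D~LCO~ of

> (range of cluster means) / (pooled within-cluster standard deviation),

and the selected *k* is the smallest whose score is within `tolerance`
(default 0.05, relative) of the maximum over the range — the smallest
number of clusters that attains essentially maximal lung-function
separation. Samples missing a measure are dropped for that measure;
measures with no usable data are skipped. A degenerate pooled SD of zero
maps to score 0 (if the means agree) or infinity (if they differ).

Clusters are renamed C1…Ck so that mean D~LCO~ is nonincreasing — C1 is
the mildest, Ck the most severe — with FVC and then FEV1 breaking ties.
D~LCO~ leads because it is the measure that most sharply contrasts the
severe cluster block. The clustering-free baseline grouping
(`severity_group()`) classifies a patient as mild-to-moderate when
FVC ≥ 55% or D~LCO~ ≥ 40% predicted, severe when the available measures
all fail those cut-offs, and unknown when both are missing.

# Differential expression

Each cluster is contrasted against the control group with a two-group
linear model per gene: effect = difference of group means (the log2 fold
change), pooled residual variance s²_g on d = n₁ + n₂ − 2 degrees of
freedom. Variances are shrunk toward an empirical-Bayes prior — a scaled
inverse-chi-square with hyperparameters (d₀, s₀²) estimated by matching
the first two moments of log s²_g to a scaled F distribution
(digamma/trigamma equations; the trigamma inverse is solved by Newton
iteration). When the observed spread of log variances does not exceed
sampling noise the prior is degenerate (d₀ = ∞) and the common variance is
the moment-consistent constant exp(mean(log s²_g) − ψ(d/2) + log(d/2)).
The moderated statistic is

> t̃_g = (mean difference) / sqrt(s̃²_g · (1/n₁ + 1/n₂)),
> s̃²_g = (d₀ s₀² + d s²_g)/(d₀ + d),

referred to a t distribution on d₀ + d degrees of freedom (normal in the
d₀ = ∞ limit; the ordinary two-sample t in the d₀ = 0 limit). Genes with
zero residual variance are excluded from the prior fit with a warning.

P-values are Benjamini–Hochberg adjusted **within each contrast**, since
DEG counts are reported per cluster; a DEG satisfies q ≤ 0.05 *and*
|log2 FC| ≥ 1, both thresholds inclusive. Note that BH adjustment is a
monotone transform of the p-value order but is *not* idempotent — applying
it to its own output can change values — so adjusted p-values are computed
exactly once per contrast.

Clinical group comparisons from summary statistics use the pooled-variance
two-sample t (df = n₁ + n₂ − 2) and the Pearson chi-square on 2×2 counts
without continuity correction, the conventions behind published
demographics tables.

# Signatures

From the per-cluster DEG sets the package derives membership counts per
gene (`overlap_groups()`), the **core** signature (intersection across all
clusters; genes that flip direction between clusters are flagged
discordant and kept), and **cluster-unique** signatures (genes DEG in
exactly one cluster); the unique set of the most severe cluster is
exported as the *advanced* signature. Gene co-expression modules cut a
complete-linkage dendrogram over 1 − Pearson distance at `n_modules`
(default 3, matching the three major module blocks such cohorts show); a
constant gene row has undefined correlation and is assigned by the
zero-correlation convention with a warning.

# Classifier validation

Signature classifiers are L2-regularized logistic models
(`l2_strength` default 1.0, the era-typical tooling default) fit by BFGS
with analytic gradients from a zero start, hence fully deterministic; the
intercept is unpenalized. Signatures are first restricted to genes present
in every cohort. Stratified 2-fold cross-validation (fold seed default 17)
precedes the final fit on all training samples; within each fold the
min–max reference is learned on the training part only.

The decision threshold is calibrated to a **sensitivity floor** (default
0.9): among candidate thresholds achieving at least the floor on the
calibration scores, the one maximizing specificity is chosen. Candidate
thresholds are the *midpoints between consecutive unique scores* (plus the
extremes) rather than the scores themselves, and specificity ties resolve
to the lowest threshold: a threshold sitting exactly on the minimum
positive training score generalizes poorly, while a mid-gap cut preserves
the sensitivity margin at no specificity cost. The ROC curve itself sweeps
the unique scores, and the AUC is the Mann–Whitney probability that a
random disease sample outscores a random control, ties counting ½.

# Candidate prioritization

Known disease genes (the training set) are enriched against an annotation
database — one gene-set category per feature class (biological process,
cellular component, phenotypes, pathway, disease) — with one-sided
hypergeometric tests, BH-adjusted within each category. A candidate gene's
**functional similarity** is the sum of −log10 q over enriched terms
(q ≤ 0.05) that also annotate it; the scorer is deliberately simple,
deterministic and documented, and sits behind a single function so a
service-backed scorer could replace it. Candidates already in the training
set are removed; the remainder are ranked by similarity and by absolute
log2 fold change (the maximum over contrasts where the gene is a DEG —
which cluster's fold change to use is otherwise unspecified), and the two
rankings are combined by the **rank product** RP = (r₁ r₂)^{1/2} with
average-rank ties. The top `top_fraction` (default 0.10) is reported.

# Biomarker panel search

Secreted/BALF-annotated candidates are ranked by the magnitude of their
coefficients in a logistic model over all candidates, then nested models
on the top 1…`k_max` (default 50) genes are trained, calibrated and
scored; the selected panel is the smallest k with specificity > 0.8
(strict) and sensitivity ≥ 0.9 (inclusive), and the full per-k trace is
retained so minimality can be audited. Two evaluation conventions are
implemented, reflecting a genuine ambiguity in how such panels are scored:
on the training cohort's own predictions, or on a held-out cohort
(`eval_m`/`eval_labels`) with the threshold optionally re-calibrated on
that cohort's scores (`recalibrate`), which is the convention the pipeline
uses — training-cohort evaluation with only a dozen controls is dominated
by threshold overfitting, while per-cohort sensitivity calibration matches
how validation cohorts are conventionally scored.

# The synthetic cohort generator

`generate_cohort()` draws expression as baseline + subgroup effect +
N(0, σ²_g) on the log2 scale with σ²_g ~ d₀s₀²/χ²_{d₀}, exactly the prior
the moderated-t machinery assumes. Defaults (all overridable):

* **Scale**: 2,000 genes × (12 controls + 96 patients in K = 6 subgroups
  of 16) — structured like the motivating cohort but small enough that the
  whole test suite runs in seconds; `paper_scale = TRUE` emits
  14,110 × (12 + 131).
* **Modules** (effect 2.0 log2 units): a disease-wide core module (80 up,
  40 down), three mixed-pattern modules mirroring the reported
  module-by-cluster blocks, one unique module per subgroup (60 genes; real
  cohorts show substantial cluster-unique expression, and without these
  blocks two subgroup pairs would be nearly indistinguishable in
  expression), and an 80-gene advanced module active only in the most
  severe subgroup.
* **Variance prior**: d₀ = 16, s₀² = 0.25 — typical residual SD ≈ 0.5
  log2 units with moderate gene-to-gene spread. A much heavier-tailed
  prior puts large numbers of pure-noise genes into the top-variance set
  used for clustering, which is a property of noisy platforms rather than
  of the cohorts this workflow targets.
* **Clinical measures**: disease subgroup means decline linearly with
  severity (FEV1 85→50, FVC 80→45, D~LCO~ 75→35 percent predicted) with
  within-subgroup SD 4; controls draw from means (94.3, 91.8, 97.0) with
  SDs (9.9, 7.4, 21.3), matching typical healthy-control summaries for
  these measures. The tight within-subgroup spread
  encodes the strong cluster-by-lung-function separation the workflow's
  model selection assumes.
* **Planted biomarkers**: 11 secreted genes, each informative (effect 1.7)
  in 2 cyclically assigned subgroups, at a fixed residual variance s₀², among
  49 uninformative secreted genes. Because no single gene covers every
  subgroup, a cohort-wide sensitivity floor is only attainable by panels
  that jointly cover all subgroups — individually weak, jointly
  informative, the regime a minimal-panel search is meant for.
* **Knowledge base**: a synthetic annotation database per feature
  category, with one planted disease-like term containing the known
  (training) genes and the planted candidate genes (10 core genes with a
  1.5× effect boost) plus random background terms.

What the generator does **not** emulate: probe-level artifacts, batch
effects, residual gene–gene correlation beyond the planted modules,
platform differences between cohorts, and missing clinical data. Passing
recovery tests on these cohorts therefore demonstrates that the
implementation is correct and well-calibrated under its own assumptions —
not that the workflow resolves real IPF heterogeneity, which depends on
external data the package deliberately does not download.

# Problem sizes and determinism

The test suite and the acceptance script run the generator at its default
scale: 25 seeds for structure recovery, 10 seeds for null calibration,
classifier validation and the panel search, 5,000 genes for variance-prior
recovery — sizes chosen so a complete run finishes in well under a minute
on a single core while keeping medians stable. All randomness flows
through explicit seeds; model fits themselves are deterministic
(closed-form statistics, BFGS from a zero start, seeded fold assignment),
so identical seeds reproduce identical reports bit for bit.

# Known limitations

* The cluster-count rule inherits the noise of clinical summaries: with
  very diffuse within-subgroup lung function the 5% tolerance band can
  admit a larger k than the planted one (splitting an extreme cluster
  inflates the range of cluster means slightly).
* Training-cohort panel evaluation with a dozen controls overfits both the
  logistic coefficients and the threshold; the held-out convention is
  strongly preferred and is the default in the pipeline.
* The functional-similarity scorer is a transparent surrogate for
  service-based gene prioritization tools; absolute scores are not
  comparable across databases, only ranks within one analysis.
* With class-imbalanced training data (12 controls vs 131 patients) the
  logistic intercept absorbs the prior odds; scores on cohorts with a
  different class balance shift accordingly, which is why thresholds are
  calibrated rather than fixed at 0.5.
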