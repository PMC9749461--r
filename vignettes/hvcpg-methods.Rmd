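---
title: "Methods: discovering tissue-independent hypervariable CpGs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering tissue-independent hypervariable CpGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hvcpg)
```

## The problem

DNA methylation at most CpG sites is tightly constrained, but a small
minority of sites vary markedly between people while remaining consistent
within a person — across tissues, across ethnicities, and over time. Such
hypervariable CpGs (hvCpGs) are candidates for epigenetic variation that is
established very early in development (before gastrulation, or even before
cleavage) and then maintained systemically. Finding them from public
methylation-array data requires separating genuine interindividual
variability from the many mundane sources of variance in any one dataset:
technical batch structure, cell-type composition, age and sex effects,
genotype (mQTL) effects, and probe artefacts.

`hvcpg` implements the full discovery and characterisation pipeline as
composable, tested functions, together with a synthetic-data generator that
plants each of these variance sources with known ground truth so that every
stage can be validated without access to restricted cohort data.

## The detection rule

For each dataset the per-probe **Beta value** (methylated fraction, in
\[0, 1\]) is preprocessed, and the unbiased sample variance of each probe is
ranked within the dataset. A probe is *flagged* in a dataset when its
variance lies in the top $i\%$ of retained probes (default $i = 5$; ties at
the cutoff are included). A CpG is called an **hvCpG** when

* it is covered (survives filtering) in at least `min_datasets` datasets
  (default 15), and
* it is flagged in at least $j\%$ of the datasets covering it (default
  $j = 65$, compared inclusively).

Because variance ranks in independent datasets are independent under the
null, the probability that one CpG clears the default rule by chance is a
binomial tail on the order of $10^{-10}$, so an empty result is expected in
the absence of cross-dataset signal. The `threshold_grid()` function maps
the sensitivity of the called set to $(i, j)$; counts are monotone
(non-decreasing in $i$, non-increasing in $j$) because the flag sets are
nested. Probes on technically-unreliable lists (low intra-class correlation
in replicate screens) are removed from the final call with
`apply_reliability_filter()`.

## Preprocessing

`preprocess_dataset()` chains three stages, in the order the variance
analysis expects:

1. **Probe filters** (`filter_probes()`): detection p-value > 0.01 in more
   than 5% of samples (when detection p-values exist), membership in
   multi-mapping / X-Y / SNP-proximal exclusion lists, and any missing Beta
   value in the dataset.
2. **Residual adjustment** (`adjust_covariates()`): Beta is mapped to the
   M scale, $M = \log_2\!\big(\beta/(1-\beta)\big)$; the sample scores of
   the first `n_pcs` principal components (default 10) of the centred M
   matrix are computed; each probe's M values are regressed on the scores
   plus age and sex in one linear model; residuals plus the probe's fitted
   intercept are mapped back to Beta.
3. **Outlier removal** (`remove_outliers()`): per probe, values outside
   Tukey's outer fences $[Q_1 - 3\,\mathrm{IQR},\; Q_3 + 3\,\mathrm{IQR}]$
   are set to missing (linear-interpolation quantiles; the common analytic
   default, since no convention is canonical).

Two deliberate numerical choices are worth spelling out. First, the
back-transform. An M value defined with $\log_2$ has the inverse
$2^M/(1+2^M)$; the natural-exponential form $e^M/(1+e^M)$ is a different
function and does not invert the base-2 logit. `m_to_beta()` defaults to the
consistent base-2 inverse — required for the exact identity
`adjust_covariates()` with zero regressors — and offers
`mode = "natural"` for compatibility with analyses that used the
natural-exponential form. Second, the intercept add-back: raw residuals
would centre every probe at $M = 0$ (Beta 0.5), destroying the methylation
level; adding the fitted intercept preserves it while leaving the removed
covariate structure out. Beta values of exactly 0 or 1 are clamped at
$10^{-6}$ before the logit and the clamp count is reported.

## Matched controls

Analyses of hvCpG properties are confounded by their unusual marginal
distribution (high variance, intermediate methylation), so two matched
control constructions are provided.

**Distribution-matched controls** (`ks_match_controls()`): each target CpG,
in sorted-id order, is matched without replacement to the background CpG
whose Beta distribution in a chosen reference dataset is least
distinguishable by a two-sided Kolmogorov–Smirnov test, requiring
$p > 0.1$. The scan over the full candidate pool computes the KS statistic
$D$ with a compiled merge over presorted samples; since the two-sided
p-value is strictly decreasing in $\sqrt{nm/(n+m)}\,D$, ranking candidates
by that quantity ranks them by p-value, and the exact `ks.test` p-value is
then evaluated on the leading candidates to pick the maximum. The selection
is verified in the test suite against a brute-force all-pairs `ks.test`
scan. Without-replacement matching keeps the control set injective, so no
control is double-counted in downstream enrichments; targets with no
qualifying candidate are reported unmatched rather than force-matched.

**mQTL-matched controls** (`mqtl_match_controls()`): each target is matched
to a candidate with exactly the same number of mQTL associations, mean
variance explained within a tolerance (default 0.005 — "similar" is not
quantified anywhere authoritative, so it is a configurable package choice),
and coverage in at least as many datasets. The variance explained by one
mQTL with per-allele effect $\beta$ and minor allele frequency $m$ is
$2\beta^2 m(1-m)$ — the variance of an additive Hardy–Weinberg locus.
Reading this as a *fraction* of methylation variance assumes $\beta$ is on
the standardized-methylation scale; the functions document rather than hide
this assumption.

## Clusters and de-clustering

Co-methylation decays with genomic distance. `correlation_decay_profile()`
estimates the decay from data: for every same-chromosome pair of CpGs
within `max_dist`, the Spearman correlation of their Beta vectors is
computed in each dataset with at least 100 samples, and pair-by-dataset
values are averaged within 100 bp distance bins (per-pair-per-dataset equal
weight by default; a dataset-first averaging mode is also available, since
the pooling order is a genuine free choice). `fit_decay_length()` fits
$A e^{-d/L}$ to the binned profile by Levenberg–Marquardt least squares.

`build_clusters()` performs single-linkage chaining per chromosome:
consecutive CpGs at most `gap` bp apart (default 4000, the distance at
which correlations level out; the boundary is inclusive, a package choice
where the convention is unstated) join one cluster; maximal chains of size
one are singletons. `decluster()` draws one uniform member per cluster and
keeps all singletons, giving a set of size
$n_\text{clusters} + n_\text{singletons}$ with pairwise same-chromosome
spacing beyond the gap — removing the within-cluster dependence that would
otherwise bias set-level statistics.

## Cross-germ-layer covariation and SIV power

Systemic interindividual variation (SIV) is methylation that differs
between individuals but agrees across an individual's tissues from
different germ layers. With a fetal multi-tissue design of three
germ-layer-pair groups, `inter_germlayer_correlation()` computes, per CpG,
the Pearson correlation between the two tissues across the individuals of
each group and averages the three groups (groups with zero variance are
excluded and counted). `interindividual_variation()` is the range of
per-individual cross-tissue mean Beta values.

`siv_power()` estimates the power of a small-cohort SIV screen: for each
CpG it draws `n_individuals` (default 4) tissue triplets from a
multivariate normal with the CpG's tissue means and cross-tissue
covariance, evaluates the SIV predicate, and repeats `n_reps` times
(default 1000), reporting the passing fraction with its Monte-Carlo
standard error. The predicate's range component is fixed at 0.2 Beta units
by default; the correlation component of the published screen definitions
is not fully standardised, so it is user-configurable
(`siv_predicate_spec()`). Draws are clipped to \[0, 1\] by default because
Beta values live there; an unclipped mode exists for comparison against
analytic or brute-force oracles. Covariances are repaired to positive
semidefinite by clipping eigenvalues at zero within a $10^{-10}$ tolerance;
anything more negative is treated as an input error rather than silently
fixed.

## Enrichment machinery

`fisher_enrichment()` builds the 2×2 target/comparator × in/out-of-feature
table and reports the two-sided Fisher's exact p-value, the
conditional-MLE odds ratio, the sample (cross-product) odds ratio with a
Haldane–Anscombe 0.5 correction when a zero cell occurs, and the fold
ratio of proportions — both odds-ratio estimators are reported because
neither is canonical. `proximity_enrichment()` tests proximity to BED
interval tracks at multiple distance thresholds; a CpG inside an interval
has distance 0, and the 1-based probe coordinates versus 0-based half-open
BED convention is converted explicitly (and tested). `bootstrap_ci()`
provides percentile intervals over resamples of the analysis unit — the
CpG, since the statistics are defined over CpG sets — with B = 1000 by
default. `set_overlap_report()` screens published CpG sets (restricted to
the array background), keeps those overlapping at least 1% of the target,
and appends Benjamini–Hochberg q-values next to the raw p-values.
`sex_split_stability()` re-derives top-variance flags within male-only and
female-only halves of large, sex-balanced datasets: genuinely
hypervariable CpGs stay flagged in at least one half, while CpGs whose
pooled bimodality is purely sex-driven lose their flag in both.

## The synthetic-data generator

`simulate_study()` emulates the statistical structure of a multi-cohort
array compendium with known ground truth:

* **Baseline**: per-CpG Gaussian means on the M scale (SD 1.5), residual SD
  0.35 M, mapped to Beta by the base-2 inverse logit — so Beta is in (0, 1)
  by construction, never clipped.
* **Shared hypervariable CpGs**: 2–3-component mixtures centred at
  intermediate Beta (0.4–0.6), component spread scaled by
  `hv_variance_multiplier`; the component levels are shared across datasets,
  the per-sample memberships are not.
* **Dataset-specific hypervariable CpGs**: the same construction active in
  exactly one dataset.
* **mQTL-driven CpGs**: additive per-allele effects on the M scale with
  Hardy–Weinberg genotypes at the configured MAF, genotypes drawn
  independently per dataset (the real cohorts are disjoint); genotype
  matrices are retained so planted effects can be re-estimated.
* **Batch structure**: a rank-`n_batch_components` sample-score × CpG-loading
  term per dataset.
* **Clustered co-methylation**: cluster members placed within a configurable
  genomic span share a Gaussian latent field with correlation
  $e^{-d/L}$ ($L$ = `cluster_decay_bp`, default 2000 bp).
* **Sex/age effects**, missingness and detection failures at configurable
  rates (all zero by default).

One design decision deserves emphasis: per-CpG baseline means are drawn
independently per dataset. In real data, baselines correlate across
cohorts, and since Beta-scale variance depends on the methylation level
through $\beta(1-\beta)$, correlated baselines would induce correlated
variance ranks even without any planted signal. Drawing baselines
independently makes the null regime genuinely null — variance ranks
exchangeable across datasets — which is the regime under which the
intersection rule's specificity claim is stated and tested. The generator
therefore validates the *rule*, not the real-data base rate of shared
baseline structure; on real data the principal-component adjustment is the
stage that absorbs shared technical variance, and the generator's batch
components exercise that pathway separately.

What the generator does *not* emulate: Infinium probe-type chemistry and
BMIQ-correctable biases (the pipeline accepts pre-normalised matrices),
explicit cell-type mixtures (the low-rank batch term stands in), and
genotype sharing between cohorts. Passing tests therefore demonstrate the
correctness and calibration of the algorithms under the stated generative
model, not the field-accuracy of any specific biological count.

## Problem sizes and test design

The test suite validates the detection rule at the study scale the method
is designed for — 30 datasets of 100 samples over 20,000 CpGs — with 100
null replicates for the specificity property and one replicate with 200
planted hypervariable CpGs (multiplier 5) for sensitivity and false
discoveries. The Fisher oracle is checked exhaustively for all 2×2 tables
with margins up to 15 plus a seeded sample of tables with margins up to 30;
KS matching on 500 targets against 5000 candidates; decay recovery from 30
planted clusters of 8 CpGs over 6 kb profiled in two 120-sample datasets;
germ-layer correlation recovery on 10,000 CpGs with the 9/10/8 group
design. These sizes keep each property statistically decisive while the
whole suite completes on a single CPU in well under half an hour.

## Known limitations

* The KS matcher evaluates the exact p-value only on the leading candidates
  by the scaled statistic; with heavily unequal per-probe sample sizes
  (extensive missingness) the asymptotic ordering could in principle differ
  from the exact ordering near the boundary. The postconditions (p > 0.1,
  injectivity) hold regardless, and the selection is cross-checked against
  brute force in the tests.
* `adjust_covariates()` requires complete Beta values; run the missingness
  filter first (the pipeline does).
* Fisher's exact p-values are discrete and conservative; the null
  calibration test asserts a bounded rejection rate rather than exact
  uniformity.
* The mQTL variance-explained fraction inherits whatever effect-size scale
  the input summary table uses; it is a faithful transform, not a
  re-estimation.
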