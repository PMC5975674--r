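---
title: "Multi-omics handprints: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics handprints: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handprint)
```

## The problem

A *fingerprint* is a biomarker signature derived from a single technical
platform; a *handprint* integrates several platforms measured on the same
patients. This package implements a four-step pipeline for deriving
handprints from multi-omics cohorts with survival follow-up:

1. **Data preparation** — missing-data handling with an explicit decision
   procedure, outlier flagging, optional location–scale batch adjustment,
   z-normalization.
2. **Feature filtering** — survival-anchored per-feature linear models
   (an optional stage).
3. **Integration and clustering** — per-platform patient affinity
   matrices fused by similarity network fusion (SNF), then subsampled
   consensus spectral clustering with a stability statistic and a
   constrained choice of the number of clusters.
4. **Biomarker derivation** — one-vs-rest differential signatures with
   BH-FDR, hypergeometric gene-set enrichment, SVM-ranked recursive
   feature elimination feeding a random-forest classifier, and a
   multi-block sparse PLS discriminant model.

## Step 1: data preparation

**Missing data.** Each feature's missing fraction is compared with a
threshold (default 0.10, strictly `<`): below it the feature is imputed
(mean, k-nearest-neighbour mean, zero, or the below-LLQ conventions LLQ,
LLQ/2, LLQ/√2, where LLQ is the platform's lower limit of quantitation);
at or above it the feature is collapsed to a presence/absence row — whose
group association can be tested with an uncorrected 2×2 Pearson
chi-square on detection rates — or imputed with a flag. The boundary is
deliberately strict at the threshold: exactly 10% missing goes to the
high-missingness branch. The kNN imputation distance is Euclidean over
mutually observed, feature-z-scored values; this is a conventional choice
where only "mean of nearest neighbours" is prescribed. Robustness of
imputation should be assessed by re-running the downstream filter with a
second method and comparing the selected sets (e.g. Jaccard overlap).

**Outliers** are flagged by a robust z-score |x − median|/(1.4826·MAD)
above 5 and never removed: genuine biological extremes carry
information, so flagging is the only defensible default. MAD = 0
features are skipped with a warning.

**Batch adjustment** is a per-feature location–scale correction: each
batch is centred to the feature's grand mean and rescaled to the pooled
within-batch SD. It requires ≥ 2 batches of ≥ 2 samples and preserves
each feature's grand mean exactly. Empirical-Bayes shrinkage across
features is deliberately out of scope.

## Step 2: the survival-anchored filter

For each feature the linear model

$$x_f = \beta_0 + \beta_1\,\text{vital status} + \beta_2\,\text{survival time} + \varepsilon$$

is fitted and the two-sided *t*-test on $\beta_1$ retained; features with
nominal $p < 0.05$ (strict) pass. Survival time is the **total days
lived** — enrolment age in days plus post-enrolment follow-up — and
censored patients enter with their observed time: this is an ordinary
linear model used as a *filter*, not a censoring-aware survival model,
and it is documented as such. No FDR correction is applied here;
multiplicity control belongs to the signature stage, where inferential
claims are made. With feature values as the response, one model per
feature yields one p-value per feature, which is the only reading of
"testing for survival status with survival time as a cofactor" that does
so.

## Step 3: fusion and consensus clustering

**Affinity kernel.** After z-normalization, Euclidean distances feed the
scaled exponential kernel
$W_{ij} = \exp\{-d_{ij}^2 / (\mu\,\varepsilon_{ij})\}$ with the locally
adaptive bandwidth
$\varepsilon_{ij} = (\bar d_i^{(K)} + \bar d_j^{(K)} + d_{ij})/3$, where
$\bar d_i^{(K)}$ is the mean distance from $i$ to its $K$ nearest
neighbours. Defaults: $K = \max(10, n/10)$ capped at $n-1$; $\mu = 0.5$,
the midpoint of the kernel's recommended $[0.3, 0.8]$ range.

**Cross-diffusion.** Each view's kernel is normalized into a stabilized
full kernel $P$ (off-diagonal rows sum to 1/2, diagonal 1/2 — this keeps
the iteration bounded) and a sparse kernel $S$ (row-normalized
restriction to each sample's $K$ nearest neighbours). The update
$P^{(v)} \leftarrow S^{(v)}\,\overline{P^{(-v)}}\,S^{(v)\top}$ is
iterated (default $t = 20$, early stop at max-abs change < 1e-6), each
round re-symmetrized and re-stabilized. The fused matrix is the average
of the final kernels with the diagonal set to each row's off-diagonal
maximum, so self-similarity cannot dominate the spectral step. A single
view returns its symmetrized stabilized kernel unchanged.

**Spectral clustering** uses the symmetric normalized Laplacian, the
bottom-k eigenvectors row-normalized to the unit sphere, and k-means
with seeded k-means++ initialization, 10 restarts, best inertia kept.

**Consensus and DIS.** For each candidate $k$, $B = 100$ subsamples of
80% of the patients (samples only, never features) are clustered and the
consensus entry of a pair is the fraction of co-sampled runs in which it
co-clustered. Stability is summarized by the *deviation from ideal
stability*:

$$\mathrm{DIS}(M) = \operatorname{mean}_{i<j}\; 2\min(M_{ij},\, 1 - M_{ij}),$$

the mean mass away from $\{0,1\}$ — exactly the non-horizontality of the
consensus CDF between its endpoints: 0 under perfect stability, 1 when
every pair is maximally ambiguous. Pairs never co-sampled are excluded.

**Choosing k.** A candidate is *feasible* when its smallest cluster has
≥ 10 patients and both vital status (chi-square) and survival (log-rank)
differ across clusters at $\alpha = 0.05$. Among feasible candidates
whose DIS lies within 10% (relative) of the smallest feasible DIS, the
**largest** k is chosen: when stability is comparable, distinguishing
more clusters is clinically preferable. If no candidate passes the
survival constraints the selection falls back to size + DIS feasibility
with a prominent warning; an empty feasible set is an error with a
per-k diagnostic table.

## Step 4: signatures and predictive models

**One-vs-rest signatures.** Per platform and cluster, an OLS on the
cluster indicator (algebraically the pooled-variance t-test) is
BH-adjusted *within that platform-by-contrast family* — matching the
per-platform, per-contrast structure in which such results are reported —
and features with $q < 0.05$ form the signature, signed by the indicator
coefficient.

**Enrichment** intersects every gene set with the universe of measured,
mapped genes of the platform (not the whole genome — the standard
detection-bias control), computes the upper hypergeometric tail of the
overlap and BH-adjusts across terms.

**RFE** ranks features by linear-SVM weights (squared weights summed
over one-vs-rest machines for multi-class), refits at each candidate
size inside leave-group-out cross-validation, and chooses the smallest
size within one standard deviation of the best mean accuracy — a
standard parsimony rule operationalizing "the smallest number of
features that allows satisfactory separation". The downstream classifier
is a random forest tuned by CV on the training partition only; the final
model refuses fewer than 10 training observations per predictor unless
explicitly overridden.

**Multi-block sPLS-DA.** Per component, block weight vectors maximize
the design-weighted sum of covariances among block scores and with the
dummy-coded class scores; sparsity is a soft-threshold to the per-block
keep-count (shrinkage by the (keep+1)-th largest magnitude, then
renormalization); each block is deflated by its own scores. The default
design is *full* (all between-block weights 1), maximizing cross-block
agreement. Prediction assigns each block's nearest class centroid in
score space and combines blocks by design-weighted vote, ties broken by
total distance. Keep-counts are tuned by repeated k-fold CV on balanced
error rate, ties toward fewer features. These numerics are this
package's own; they are not intended to reproduce any other
implementation bit for bit.

## The synthetic cohort generator

The generator is first-class, tested code: it is the substrate on which
every pipeline property is validated.

* **Subtypes**: multinomial labels over k clusters (default 3,
  balanced, n = 150).
* **Views**: 3 views of 200 features, 30 informative, effect δ = 1.5 SD
  over unit Gaussian noise. Each view's informative features separate
  only one pair of clusters (the second cluster of the pair is
  mean-shifted; the first and all unlisted clusters share the baseline),
  so view 1 resolves cluster 2, view 2 cluster 3, view 3 cluster 1 — no
  single view resolves the full structure, their fusion does. This is
  the complementary-views regime the integration step exists for.
* **Survival**: exponential post-enrolment time with cluster-specific
  hazard, administratively right-censored at the horizon that realizes
  the requested censoring fraction (default 30%); total days lived =
  enrolment age (normal, mean 60 years, SD 10 years, in days) plus the
  censored time, with both components kept in the clinical table.
  Default hazards are 1/250, 1/350 and 1/2800 per day. The uneven
  spacing is deliberate: a cluster's vital-status contrast is the
  distance between its death probability and the cohort mean, so with
  evenly spaced death probabilities the middle subtype's survival link
  vanishes and a survival-anchored filter would (correctly) discard its
  features. Defaults keep every cluster's death probability ≥ ~0.2 away
  from the mean so that *every* subtype is genuinely survival-linked.
* **Missingness and batch**: optional MCAR masking, below-quantile LLQ
  truncation (limit recorded), and additive per-batch feature offsets
  recorded in the clinical table.
* **Seeding**: the global seed expands to fixed per-component child
  seeds (labels, each view, survival, missingness, batch), so each
  component is independently reproducible and regeneration is
  bitwise-identical.

What the generator does **not** emulate: count-based RNA-seq noise,
methylation beta-value distributions, informative (non-MCAR beyond LLQ)
missingness, or correlated feature blocks. Passing tests therefore
demonstrate the pipeline's contracts under Gaussian mean-shift
structure, not performance on any particular real platform.

## Numerical choices and degenerate inputs

* Sample alignment orders ids lexicographically (byte order), making
  downstream seeded runs locale-independent and bit-stable; id matching
  is exact, never fuzzy.
* The 10% missingness boundary is strict (`<` imputes, `≥` collapses).
* Chi-square tests are uncorrected (no Yates continuity correction),
  df = 1 for 2×2; zero-margin rows/columns are dropped with a warning,
  fully degenerate tables return p = 1 with a warning.
* Near-perfect OLS fits (residual at machine-noise level) are detected
  explicitly: a noise-level coefficient reports t = 0, p = 1; a genuine
  coefficient with zero residual reports p = 0.
* Coincident samples give a zero kernel bandwidth; it is floored at
  1e-12 with a warning.
* Constant features are dropped at z-normalization (warning) and get
  p = 1 in the filter.
* k-means++ centres receive 1e-10 jitter so duplicate embedding rows
  cannot produce coincident initial centres.
* Consensus pairs never co-sampled are NaN and excluded from DIS; a
  warning reports the uncovered-pair count.
* BH re-adjustment of already-adjusted values is *not* an identity (the
  step-up map is not idempotent); the package asserts the true
  properties instead: q ≥ p, monotonicity, and that re-adjustment never
  shrinks a q-value.

## Problem sizes used in validation

The test-suite and the acceptance script validate on the reference
conditions: 20 cohorts for the fusion-complementarity property, 10 for
cluster-number recovery (k ∈ 2..6, B = 50, subsample fraction 0.8), 20
all-null cohorts of 2000 features × 60 samples for filter calibration,
1000 null replicates each for the detection-rate and log-rank type-I
error, 10 seeds of 500 features × 200 samples for RFE recovery (LGOCV
with 10 iterations — enough splits for a stable one-SD rule at this
signal strength), and a stratified 2/3 holdout for the sPLS-DA balanced
error rate. These sizes are the package's validation design; all are
configurable at call sites.

## Known limitations

* The filter's linear model ignores censoring by construction; it is a
  screening device, not an inference.
* DIS as implemented is one operationalization of "deviation from
  horizontality" of the consensus CDF; other formulations exist and
  numerical DIS values are not comparable across definitions.
* SNF results depend on K, μ and t; cohort-level conclusions should be
  checked for robustness over a small grid of these.
* The interface is programmatic (functions + `run_handprint()`
  orchestrator); there is no shell subcommand layer, as the intended
  users drive the pipeline from R scripts.
* No Cox models, no empirical-Bayes batch correction, no TCGA download
  client; inputs must arrive as pre-harmonized matrices.
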