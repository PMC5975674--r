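# handprint

Multi-omics patient stratification by similarity network fusion and
consensus spectral clustering, with survival-anchored feature filtering
and downstream biomarker derivation.

## The problem

Complex diseases hide *endotypes* — subtypes driven by distinct
mechanisms — that no single molecular platform resolves. Given several
feature × sample matrices (e.g. transcriptomics, methylation, miRNA)
plus a clinical table with vital status and survival time, this package
derives a **handprint**: a patient partition supported by all platforms
jointly, together with per-platform biomarker signatures and predictive
models of cluster membership.

The pipeline has four steps:

1. **Data preparation** — a missing-data decision procedure (features
   with < 10% missing are imputed — mean, kNN-mean, zero, LLQ, LLQ/2,
   LLQ/√2; features at or above 10% are collapsed to presence/absence and
   tested by an uncorrected 2×2 χ² on detection rates — or imputed with a
   flag), robust-z outlier *flagging* (never removal), location–scale
   batch adjustment, z-normalization.
2. **Survival-anchored filtering** — per feature, the linear model
   `value ~ vital_status + survival_time` (survival time = total days
   lived); features with nominal p < 0.05 on the vital-status
   coefficient pass.
3. **Fusion and clustering** — per-view affinities
   `W_ij = exp(−d_ij² / (μ ε_ij))` with the locally adaptive bandwidth
   `ε_ij = (mean K-NN dist of i + mean K-NN dist of j + d_ij)/3`, fused
   by SNF cross-diffusion `P(v) ← S(v) · mean(P(−v)) · S(v)ᵀ`; then
   subsampled consensus spectral clustering. Stability per k is the
   **deviation from ideal stability**,
   `DIS = mean over pairs of 2·min(M_ij, 1 − M_ij)`, and k is the
   largest candidate within 10% of the best feasible DIS subject to
   minimum cluster size 10 and significant vital-status (χ²) and
   survival (log-rank) differences across clusters.
4. **Biomarkers** — one-vs-rest signatures per platform (OLS on the
   cluster indicator, Benjamini–Hochberg FDR within each
   platform × contrast family), hypergeometric gene-set enrichment
   against the measured universe, linear-SVM recursive feature
   elimination with the one-SD size rule feeding a random forest, and a
   multi-block sparse PLS-DA (soft-thresholded block weights,
   design-weighted centroid vote).

A first-class synthetic-cohort generator plants k subtypes as
mean-shifted feature blocks spread *complementarily* across views (no
single view resolves all clusters), with cluster-linked exponential
survival, right censoring, MCAR/below-LLQ missingness and batch
offsets — the substrate for all validation.

## Worked example

```r
library(handprint)

g <- generate_cohort(synthetic_spec(seed = 42))   # 150 patients, 3 views
g$dataset
#> multi_omics_dataset: 3 views, 150 aligned samples
#>   mrna: 200 features
#>   methylation: 200 features
#>   mirna: 200 features

h <- run_handprint(g$dataset,
                   pipeline_config(k_range = 2:6, consensus_B = 50,
                                   seed = 42))
h
#> handprint: k = 3 clusters over 150 samples
#>   mrna: 66 significant one-vs-rest features
#>   methylation: 89 significant one-vs-rest features
#>   mirna: 95 significant one-vs-rest features

round(h$assignment$rationale, 4)
#>   k    dis min_size p_status p_logrank size_ok feasible
#> 1 2 0.1002       59        0    0.0014       1        1
#> 2 3 0.0000       41        0    0.0000       1        1
#> 3 4 0.1124       18        0    0.0000       1        1
#> 4 5 0.1681       20        0    0.0000       1        1
#> 5 6 0.1749       15        0    0.0000       1        1

adjusted_rand_index(h$assignment$labels, g$labels)
#> [1] 1
```

Reading the output: DIS is 0 at k = 3 — every consensus entry is 0 or 1,
i.e. the three planted subtypes are perfectly stable under resampling —
while neighbouring k are an order of magnitude less stable; all
candidates pass the cluster-size and survival constraints, so the
selection keeps k = 3 (no larger k comes within the DIS tolerance). The
recovered labels match the planted ones exactly (adjusted Rand index 1).
Each platform then yields dozens of one-vs-rest signature features at
q < 0.05.

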