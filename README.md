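# neuroexcursion

Analysis tools linking individual differences in human sensorimotor
adaptation to the structure of large-scale brain networks. The package is
aimed at motor-learning and network-neuroscience researchers who have (a)
trial-wise visuomotor-rotation behavior and (b) ROI-level BOLD time series
for resting and task scans, and want to connect learner phenotypes to how
far task activity departs from each subject's resting network structure.

## What it computes

**Learner phenotyping.** Trial errors are cleaned (reaction-time filters,
spline detrending, 3-SD outlier interpolation), summarized as circular
early error on each day and savings (day 1 − day 2), and clustered by
complete-linkage agglomeration on the Manhattan distance between
standardized features. A parametric bootstrap against a single-Gaussian
null evaluates each candidate cluster count through its within/total
sum-of-squares ratio.

**Manifold excursion.** PCA of the day-1 rest scan gives an orthonormal
basis V retaining 75% of variance. For each task volume x_t the excursion

    r_t = ||(I − V Vᵀ)(x_t − μ)|| / ||x_t − μ||  ∈ [0, 1]

is the fraction of centered activation lying off the resting manifold.
Curves are standardized to the pre-rotation baseline; *early excursion*
averages the first four 8-trial blocks after rotation onset.

**mfPCA.** The four excursion curves per subject (2 networks × 2 days) are
smoothed by GCV cubic splines and decomposed by multivariate functional
PCA; component scores are compared across phenotypes with Kruskal-Wallis
and Conover-Iman post hoc tests (Benjamini-Hochberg adjusted).

**Covariance centering.** Shrinkage covariance matrices over equal-length
(177-volume) epochs are centered at the group's Fréchet-mean rest
covariance under the affine-invariant SPD geometry:

    T_ij = R_i^{1/2} logm(R_i^{−1/2} S_ij R_i^{−1/2}) R_i^{1/2}
    T^c_ij = G T_ij Gᵀ,  G = R̄^{1/2} R_i^{−1/2}
    S^c_ij = R̄^{1/2} expm(R̄^{−1/2} T^c_ij R̄^{−1/2}) R̄^{1/2}

removing static subject differences while preserving each task-versus-rest
shift.

**Joint embedding.** Centered tangent vectors are approximated as
T_i ≈ Σ_k λ_ik h_k h_kᵀ (shared unit patterns, free-sign scores) by greedy
rank-one deflation with monotone alternating updates; scores are tested
with a mixed-design ANOVA (epoch and day within subject, phenotype
between).

A synthetic-data generator produces behavior, ROI time series, and
covariance sets with planted ground truth for all of the above, and
`run_pipeline()` chains every stage end to end.

## Worked example

```r
library(neuroexcursion)

res <- run_pipeline(pipeline_config(n_subjects_per_group = 10, seed = 1))
res
#> Sensorimotor-adaptation analysis pipeline
#>   subjects: 30 (10 per phenotype), seed 1
#>   behavioral clusters: k = 3, ARI vs ground truth = 1.000
#>   mfPCA variance explained: 90.1%, 2.9%, 1.1%
#>   cognitive embedding mean residual norm: 0.087
#>   sensorimotor embedding mean residual norm: 0.080
```

The three behavioral clusters recover the planted FF/SS/SF phenotypes
exactly (adjusted Rand index 1.0). Early excursion separates the planted
engagement levels:

```r
res$early_excursion |>
  dplyr::group_by(group) |>
  dplyr::summarise(mean_early_excursion = mean(early_excursion))
#> # A tibble: 3 × 2
#>   group mean_early_excursion
#>   <chr>                <dbl>
#> 1 FF                  1.12
#> 2 SF                  1.10
#> 3 SS                  0.209
```

FF and SF learners (planted off-manifold step 1.2 baseline-signal units on
day 1) show far larger standardized excursion than SS learners (step 0.4),
and the first mfPCA component separates the groups
(`res$mfpca_tests$p_value[1]` ≈ 6e-5). Result objects have broom-style
`tidy()`/`glance()` methods and `autoplot()` figures; `plot_excursion()`
draws the per-subject curves.

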