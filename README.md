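# hbrnorm

Neuroanatomical normative modeling of regional cortical thickness, for
studying the *heterogeneity* of atrophy in clinical cohorts (e.g.
biomarker-confirmed Alzheimer's disease) rather than group-average effects.

Case-control comparisons answer "is the average patient thinner than the
average control?". Normative modeling instead asks, for **each patient and
each brain region**, "is this measurement unusually low for a person of this
age and sex, scanned on this scanner?" — and then studies how those
individual deviation maps differ across patients.

## The model

For each of the 148 regions of the Destrieux parcellation (74 gyri and
sulci per hemisphere), thickness in a multi-site healthy reference cohort is
modeled with a hierarchical Bayesian regression:

    y_ij = beta0_j + beta_age_j * age_i + beta_sex_j * female_i
           + u_{s(i),j} + e_ij,        e_ij ~ N(0, sigma_{s(i),j}^2)

with site random intercepts `u_{s,j} ~ N(0, tau_j^2)` and per-site noise
variances pooled hierarchically (`sigma_{s,j}^2 ~ IG(a0, b0_j)`). Inference
is a blocked Gibbs sampler with conjugate updates on per-site sufficient
statistics; the site-variance hyperparameter is sampled with the site
offsets integrated out (slice step), which avoids the usual funnel
degeneracy.

The fitted model is then **transferred to a new site** from a small local
control sample (n = 20 by default): the site offset and noise variance are
re-estimated with the reference posterior as prior, treating the new site's
noise as a site-level rescaling of the reference noise profile. Each
clinical scan becomes a vector of deviation z-scores

    z_ij = (y_ij - mu_hat_ij) / sd_hat_ij

using the posterior-predictive mean and sd (observation noise *plus*
parameter uncertainty). Regions with `z < -1.96` (the bottom 2.5% of the
normative range; negative deviations only) are *outliers*; per-subject
outlier maps feed:

- **total outlier count** (TOC, 0–148) and its group contrasts
  (ANCOVA on log(TOC+1), Mann-Whitney, Pearson correlation with age),
- **regional prevalence maps**, superior-temporal-sulcus (STS) status
  (none / unilateral / bilateral), temporal (30 regions) vs extratemporal
  (118) prevalence and the location-by-phenotype two-way ANOVA,
- **Hamming-distance heterogeneity**: pairwise counts of discordant
  outlier flags, per-subject median distance to own group, and a
  permutation-based group comparison,
- **SUVR associations**: regressions of TOC and mean thickness on amyloid
  SUVR, with a median split.

A seeded multi-site cohort simulator (`generator_config()`,
`generate_reference()`, `generate_adaptation()`, `generate_clinical()`,
`generate_suvr()`) produces reference / adaptation / clinical cohorts with
known ground truth, so every stage is testable without clinical data.

## Worked example

```r
library(hbrnorm)

cfg <- generator_config(n_reference = 2000, n_sites = 10, seed = 1)
ref <- generate_reference(cfg)
fit <- fit_reference(ref$cohort, ref$thickness, seed = 1)

adp     <- generate_adaptation(cfg, ref$truth)      # 20 controls, new site
adapted <- adapt_site(fit, adp$cohort, adp$thickness)
cli     <- generate_clinical(cfg, ref$truth)        # 86 patients
dev     <- score(fit, adapted, cli$cohort, cli$thickness)

o   <- flag_outliers(dev)           # z < -1.96
toc <- total_outlier_count(o)
median(toc); range(toc)
#> 25        9 54

head(outlier_prevalence(o)$ranked, 3)
#>                                name prevalence hemisphere lobe_group
#> lh_S_temporal_sup lh_S_temporal_sup   46.51163       left   temporal
#> rh_Pole_temporal   rh_Pole_temporal   40.69767      right   temporal
#> rh_S_temporal_sup rh_S_temporal_sup   38.37209      right   temporal

lobe_prevalence_summary(o)
#>      lobe_group mean_prevalence sd_prevalence n_regions
#> 1      temporal        27.63566      6.624940        30
#> 2 extratemporal        16.43674      4.421677       118

H <- hamming_matrix(o)
group_dissimilarity(H, cli$cohort$stage)$groups
#>             group median iqr  n
#> dementia dementia   50.5 8.5 41
#> MCI           MCI   37.5 7.5 45
compare_group_dissimilarity(H, cli$cohort$stage)
#> dissimilarity_regression: stat = 124.2 (df 1, 84), estimate = -13.36, p = 0.001
```

The clinical cohort was generated with core atrophy in the bilateral STS
plus idiosyncratic regional spread that is stronger at the dementia stage —
and that is exactly what the analysis recovers: the STS tops the prevalence
ranking, temporal prevalence exceeds extratemporal, the median TOC sits in
the low tens with a wide range, and the dementia group is more internally
heterogeneous (higher median Hamming distance) than the MCI group.

`run_pipeline(cfg, "out/")` runs simulate → fit → adapt → score → analyze in
one call and writes every table (cohorts, thickness, z-scores, outlier
matrix, prevalence, Hamming matrix, statistics) plus a checksummed
`manifest.json`.

## Limitations

Regions are modeled independently (148 separate fits); spatial covariance
between regions is not modeled, which should be kept in mind when
interpreting Hamming distances. The simulator draws core-region atrophy
independently per region, so bilateral STS involvement is less frequent
than in real cohorts where atrophy is strongly bilateral. See the methods
vignette (`vignettes/normative-modeling.Rmd`) for the full account of
model, priors, generator design and numerical choices.
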