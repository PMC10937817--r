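---
title: "Normative modeling of cortical thickness: model, transfer, and heterogeneity statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative modeling of cortical thickness: model, transfer, and heterogeneity statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the hierarchical
model and its assumptions, the site-transfer design, what the synthetic
cohort generator does and does not emulate, the numerical choices, and the
known limitations. Everything stated here about the package's behaviour is
computed by the test suite or the acceptance script; nothing is quoted from
external results.

## 1. The problem

Group-average case-control comparisons hide within-group variability: two
patients can both be "typical" at the group level while sharing almost no
atrophied regions. Normative modeling reframes the analysis around the
individual: a large healthy reference cohort defines, per brain region, the
expected distribution of cortical thickness given age and sex (and scanner
site); each patient is then expressed as a vector of deviation z-scores,
and the analysis studies the *pattern* of extreme negative deviations
(outliers) across patients.

## 2. The hierarchical model

For each region $j$ of the 148-region Destrieux parcellation, independently,

$$y_{ij} = \beta_{0j} + \beta_{aj}\,\mathrm{age}_i + \beta_{sj}\,\mathrm{female}_i
          + u_{s(i)j} + \varepsilon_{ij},\qquad
  \varepsilon_{ij}\sim N(0,\sigma^2_{s(i)j}),$$

with site random intercepts $u_{sj}\sim N(0,\tau_j^2)$ and per-site noise
variances pooled through $\sigma^2_{sj}\sim \mathrm{IG}(a_0, b_{0j})$.
Assumptions worth making explicit:

* **Gaussian residuals** per region and site. Regional mean thickness is an
  average over many vertices, so this is usually benign.
* **Additive, homogeneous covariate effects**: one age slope per region,
  linear in age over the reference range; sex enters as an indicator
  (female = 1). Age is centered at the reference mean for numerical
  stability (this changes the intercept's meaning, not predictions).
* **Site effects are an intercept shift plus a noise-scale change.** This
  is the heteroscedastic multi-site structure that motivates hierarchical
  rather than pooled regression.
* **Regions are modeled independently** (148 separate fits). Structural
  covariance between regions is *not* modeled; see Limitations.

### Priors and inference

Inference is a blocked Gibbs sampler operating on per-site sufficient
statistics (so its cost is independent of the number of subjects, and a
subject-row permutation changes results only at floating-point level):

* $\beta_j$: conjugate normal update, vague $N(0, 100^2)$ prior per
  coefficient.
* $\sigma^2_{sj}$: conjugate inverse-gamma update. The hyper-shape $a_0$ is
  fixed at 3 (moderate pooling); the hyper-scale $b_{0j}$ is sampled
  conjugately (Gamma(0.1, 0.1) prior). Sampling the shape too would be
  non-conjugate, and the fixed-shape scheme passes the calibration suite.
* $\tau_j^2$: sampled **with the site offsets integrated out** — the
  residual site means satisfy $\bar r_{sj} \sim N(0, \tau_j^2 +
  \sigma^2_{sj}/n_s)$, so the marginal posterior of $\tau_j^2$ given
  $(\beta_j, \sigma_j)$ is one-dimensional and is sampled by a slice step,
  with a half-Cauchy(0.5 mm) prior on $\tau_j$. Sampling $\tau^2$
  conditionally on the $u_s$ values instead creates the classic funnel:
  with few sites the chain can collapse into $\tau^2 \to 0$, pinning all
  site offsets at zero and biasing the intercept. The partially collapsed
  step removes this failure mode.
* Variances are floored at $10^{-12}$ so that degenerate (noise-free)
  inputs remain finite; in that regime the coefficients are recovered to
  machine-level accuracy (the test suite checks $10^{-6}$), with the caveat
  that the intercept is only identified jointly with the mean site offset.

One pipeline seed fans out to per-region substreams keyed by region id, so
results are reproducible regardless of execution order, and callers' RNG
streams are restored on exit. Default run length is 900 iterations (300
burn-in, thin 3, 200 retained draws per region); each region's age-slope
chain gets a split-chain diagnostic and is flagged (never dropped) above
1.05.

## 3. Site transfer (adaptation)

A clinical cohort is scanned at a site the reference model has never seen.
The transfer step (`adapt_site()`) re-estimates, per region, the new site's
offset $u_{\mathrm{new},j}$ and noise variance
$\sigma^2_{\mathrm{new},j}$ from a small local control sample (default
n = 20), holding the covariate effects fixed:

* $u_{\mathrm{new},j}$ gets the reference hyperposterior
  $N(0, \tau_j^2)$ as its prior, at full strength.
* $\sigma^2_{\mathrm{new},j}$ gets an inverse-gamma prior with small fixed
  shape (default 20) centered at $\phi\, m_j$, where $m_j$ is the
  cross-site mean noise variance of region $j$ under the reference
  posterior and $\phi$ is a **single site-level rescaling factor**
  estimated from the adaptation residuals of all regions jointly.

The $\phi$ construction mirrors the model's own generative form (site noise
= regional noise profile $\times$ site scale). It is what makes transfer
from 20 controls *stable*: 20 subjects give each region only ~19 degrees of
freedom for its variance, and with purely per-region estimates the
chi-square noise of $\hat\sigma$ alone pushes the tail of the z-scores
from the nominal 2.5% to above 3% (the convexity of
$\Phi(-1.96\,\hat\sigma/\sigma)$ in $\hat\sigma$), while full-strength
transfer of the reference variance hyperposterior fails in the opposite
way whenever the new scanner is noisier or quieter than the reference pool
— scanner or field-strength mismatch between a clinical site and research
reference data is the rule, not the exception. Sharing the site-level
scale across regions while letting the per-region likelihood (weight
$n/2$) absorb genuine regional departures keeps the held-out null
calibration inside 2.5 ± 0.5 percentage points, which the acceptance suite
verifies end-to-end. `prior_shape` is user-visible for data where the
shared-scale assumption is doubtful.

Uncertainty is propagated by pairing: each retained reference draw
$(\beta_t, \tau^2_t)$ conditions a short inner Gibbs chain for
$(u_{\mathrm{new},t}, \sigma^2_{\mathrm{new},t})$, so adaptation draws stay
matched to reference draws.

## 4. Deviation scores and outliers

For a clinical subject $i$, $\hat\mu_{ij}$ and $\hat\sigma_{ij}$ are the
posterior-predictive mean and sd obtained by averaging over the paired
draws ($\hat\sigma^2$ = expected observation noise *plus* the variance of
the predictive mean across draws — parameter uncertainty matters at
n = 20), and

$$z_{ij} = (y_{ij} - \hat\mu_{ij})/\hat\sigma_{ij}.$$

A region is an **outlier** when $z_{ij} < -1.96$, i.e. in the bottom 2.5%
of the normative range; the inequality is strict, and only negative
deviations are flagged (the scientific target is atrophy). The threshold is
configurable; full z-score matrices are always retained so other thresholds
need no refit. Subjects whose age falls outside the reference support are
scored but flagged as extrapolated.

## 5. The synthetic cohort generator

The generator exists so that the whole pipeline — including its failure
modes — is testable with known ground truth. Its defaults emulate the study
conditions the package targets:

| parameter | default | rationale |
|---|---|---|
| `n_reference`, `n_sites` | 2000, 10 | desk-scale stand-in for a large pooled multi-site reference cohort |
| `age_range_reference` | 18–90 y | wide adult reference support |
| `n_adaptation` | 20 | small local control sample at the clinical site |
| `n_clinical`, `age_range_clinical` | 86, 49.1–87.4 y | memory-clinic cohort scale and age span |
| `sex_ratio` | 0.488 female | near-balanced clinical composition |
| `baseline_range` | 2.0–3.0 mm | realistic regional mean cortical thickness |
| `age_slope_range` | −0.012 to −0.002 mm/y | cortical thinning with age, region-specific |
| `sigma_range` | 0.08–0.18 mm | between-subject regional sd |
| `site_intercept_sd` | 0.05 mm | scanner-level offsets |
| `site_scale_sdlog` | 0.2 | log-normal noise-scale spread across sites (the heteroscedasticity that motivates the hierarchy) |
| `core_penetrance` | 0.6 | probability of core (bilateral STS) atrophy per region |
| `idiosyncratic_rate` | 0.15 | mean per-region rate of idiosyncratic atrophy (≈ 22 regions) |
| `effect_range` | 2.5–5 σ | atrophy depth in residual-sd units |
| `temporal_weight` | 2 | temporal regions accumulate idiosyncratic outliers at twice the extratemporal rate |

Clinical subgroup labels (stage MCI/dementia 38/48, phenotype
amnestic/non-amnestic 64/22, depression ongoing/past/none 24/7/51 with a
few missing) modulate the rates multiplicatively: dementia spreads more
than MCI, non-amnestic presentations spread further outside the temporal
lobe, ongoing depression carries a lower burden. SUVR is generated as
`mean + slope * standardized(burden) + noise` with a negative default
slope. All generators are bit-deterministic under a fixed master seed, via
per-stage substreams.

**What the generator does *not* emulate** — and therefore what passing
tests do not establish about real data: spatial covariance between
neighbouring or homologous regions (core-region hits are drawn
independently per region, so bilateral STS involvement is rarer than in
real cohorts); longitudinal structure; non-Gaussian thickness
distributions; segmentation failures and motion artifacts; missing data.

## 6. Statistical design decisions

* **log(count + 1)** for outlier-count ANCOVAs: the count 0 is attainable
  and must stay finite.
* **Welch t-tests** region-wise (no homogeneity assumption), two-tailed,
  with Benjamini–Hochberg FDR at 0.05; zero-variance regions are reported
  as NA, never dropped silently.
* **Mann–Whitney U** companions use exact enumeration below a combined
  n of 20 and the tie-corrected normal approximation otherwise.
* **Bonferroni** is reserved for the three-group STS-status comparisons
  (pairwise t-tests); categorical STS contrasts use chi-squared tests
  without continuity correction (df = 2 tables).
* **Dissimilarity group comparison**: per-subject median Hamming distance
  to own-group peers, regressed on group. Because those medians are
  functions of one shared distance matrix they are dependent, and the
  parametric F-test is anti-conservative — in the package's null
  simulations its type-I error was several times nominal. The reported
  p-value is therefore a seeded label-permutation p (default 999
  permutations, medians recomputed per relabeling); the parametric p is
  retained as `p_param` for reference. This choice is what lets the test
  hold its nominal size in the calibration suite.
* **Two-way location × phenotype ANOVA** is run on region-level
  prevalences (148 regions × 2 locations × 2 phenotypes); the one-way
  location ANOVA on pooled prevalences (df 1, 146) is reported alongside,
  since df conventions for this design differ across packages and reports.
* **Median SUVR split**: strictly above the median is "high"; ties go to
  "low".

## 7. Problem sizes and runtime choices

The test suite exercises the full model at the study scale (reference
n = 2000 across 10 sites; 20 adaptation controls; 86-subject clinical
cohort; 200 held-out subjects for calibration) and uses reduced
configurations (n = 400, 4 sites; shorter chains) for module-level
properties; null-calibration properties use 1000 simulation replicates and
the heterogeneity-direction property 100 generator seeds. These sizes are
the package's choices for a reproducible desk-scale validation; all of
them are configuration values, not limits.

## 8. Limitations

* Region independence: no spatial or bilateral covariance, in the model or
  the generator; Hamming distances inherit this caveat.
* Gaussian likelihoods only; no warped/non-Gaussian normative variants.
* Site adaptation recalibrates intercept and noise only; covariate slopes
  transfer unchanged.
* The z-score rule with an estimated denominator is only approximately
  normal; with 20 adaptation controls its tail calibration depends on the
  transfer prior (Section 3), and the packaged default is designed for,
  and verified under, the shared-site-scale noise structure.
* SUVR is consumed as a per-subject scalar; no image-level amyloid
  quantification.
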