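---
title: "Genomic and environmental prediction for maize multi-environment trials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic and environmental prediction for maize multi-environment trials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metGP)
```

## The problem

Maize breeding programs evaluate hybrids in multi-environment trial (MET)
networks: a set of sites, each planted over several years, with a panel of
hybrids that changes as new material enters and older material is dropped.
The question the package addresses is forward prediction: given phenotypes,
marker genotypes, and field-level weather and soil records, how well can the
performance of hybrids be predicted in a year or site that was never
observed — including hybrids that themselves were never phenotyped? The
pipeline couples genomic prediction (GBLUP through a genomic relationship
matrix) with growth-stage environmental covariates so that
genotype-by-environment (GxE) interaction becomes partially predictable from
measurable environmental drivers.

## Pipeline overview

The stages mirror a standard MET analysis:

1. **Stage-1 phenotypic analysis** (`stage1_blues()`). Each environment (a
   site-by-year combination) is analyzed separately with the model
   $y_{ij} = \mu + G_i + R_j + \varepsilon_{ij}$, genotype fixed and
   replicate random. Replicates of one experiment planted seven or more days
   apart experienced different weather at the same phenological stage and
   are relabeled as distinct, unreplicated environments. Plots with
   absolute studentized conditional residuals above 3 are flagged and
   removed, and the model is refit once (flag, remove, refit — not
   iterated: the rule is deterministic and matches common practice).
2. **Genotype processing** (`geno_pipeline()`). Markers with more than two
   observed alleles are removed; taxa with under 70% site coverage or over
   8% heterozygosity are discarded; monomorphic markers and markers missing
   or heterozygous in more than 5% of parents are dropped; missing calls are
   imputed; markers with minor allele frequency below 2% and markers above
   the LD threshold (window 100, step 5, $r^2 > 0.99$) are pruned. In-silico
   hybrid dosages are the mean of the two parents' dosages, followed by a
   final 2% MAF filter on the hybrid panel. The genomic relationship matrix
   is $G = XX'/p$ with $X$ column-centered and scaled to unit variance
   (sample SD, $n-1$ denominator — the scaling convention is documented
   because it fixes the diagonal mean at $(n-1)/n$).
3. **Weather engine** (`qc_aggregate_daily()` and friends). Sub-daily
   station records are screened by record-count, range, persistence
   (zero within-day variability) and internal-consistency tests, then
   aggregated to daily values; the daily mean temperature is
   $(T_{min}+T_{max})/2$. Gaps are filled by inverse-distance weighting
   from neighbouring stations. Derived daily variables: Baskerville–Emin
   single-sine growing degrees above 10 °C, astronomical day length,
   photothermal time (growing degrees × day length), Tetens vapour pressure
   deficit, FAO-56 Penman–Monteith reference evapotranspiration, and the
   daily water balance (precipitation + irrigation − ET0).
4. **Environmental covariates** (`stage_covariates()`, `assemble_W()`).
   Three hybrid-specific growth windows are anchored on the planting and
   50%-silking dates: vegetative [planting, silking−7), flowering
   [silking−7, silking+14), grain filling [silking+14, silking+79) — 65
   days, the interval after which physiological maturity is normally
   reached. Thirteen weather covariates are computed per window (totals of
   water input, ET0, water balance, radiation, growing degrees and
   photothermal time; means of daily mean/min/max temperature; frequencies
   of days with >5 mm water and with maxima above 30 °C and 35 °C; and the
   sum of maxima above 30 °C), plus four soil covariates (sand, silt, clay,
   organic matter) and optionally longitude/latitude. Frequencies are
   expressed as fractions of window days so windows of different lengths
   are comparable; thresholds are strict inequalities. For plant height the
   grain-filling weather covariates are masked, since the trait is measured
   shortly after flowering. Columns are centered and scaled; `assemble_W()`
   accepts a training index so the statistics can be fitted on training
   rows only and applied to test rows.
5. **Reaction-norm models** (`build_kernels()`, `fit_gibbs()`). The linear
   random effects models combine main-effect kernels — genomic
   ($Z_g G Z_g'$), environment/site/year block kernels ($ZZ'$), and the
   environmental kernel $\Omega = WW'/q$ — with interaction kernels formed
   as Hadamard products (e.g. $[Z_g G Z_g'] \circ [Z_E Z_E']$ for GxE and
   $[Z_g G Z_g'] \circ \Omega$ for GxW). Schur's product theorem guarantees
   the products remain positive semidefinite.
6. **Machine-learning comparators** (`build_feature_table()`,
   `fit_predict()`, `tune_bayes_gp()`). Elastic net and gradient-boosted
   decision trees on a feature table of marker principal components, EC
   columns, one-hot year indicators and coordinates, with Gaussian-process
   Bayesian hyperparameter tuning under nested cross-validation and fANOVA
   hyperparameter importance.
7. **Evaluation** (`make_cv0_splits()`, `make_cv00_splits()`,
   `weighted_predictive_ability()`). Four forward schemes: CV0-Year,
   CV00-Year, CV0-Site, CV00-Site. CV0 holds out every observation of one
   year (or site); CV00 additionally removes from training every
   observation of a genotype present in the test set. Accuracy is the
   Pearson correlation between predicted and observed values per
   environment; the summary is the inverse-sampling-variance weighted mean
   $r_w = \sum_j r_j/V_j \big/ \sum_j 1/V_j$ with
   $V_j = (1-r_j^2)/(n_j-2)$.
8. **Interpretation** (`gain_importance()`, `partial_dependence()`).
   Gain-based feature importance of the boosted model (shares sum to one)
   and Friedman partial dependence profiles, with a quantile-spaced grid so
   profiles stay inside the observed feature region.

## The Bayesian sampler

`fit_gibbs()` fits $y = \mu + \sum_k u_k + \varepsilon$ with
$u_k \sim N(0, \sigma^2_k K_k)$. Each kernel is eigendecomposed once,
$K_k = U_k D_k U_k'$, and the effect vector is reparameterized as
$u_k = U_k \delta_k$ with independent prior components
$\delta_{kj} \sim N(0, \sigma^2_k d_{kj})$. Because the eigenvectors are
orthonormal, the full conditional of $\delta_k$ is diagonal, so the entire
vector is drawn in one block per iteration — two matrix–vector products per
kernel — which keeps the sampler in vectorized linear algebra. Variance
components take scaled-inverse-chi-square conjugate updates with 5 prior
degrees of freedom; the prior scales split half the phenotypic variance
equally among the kernels, with the other half on the residual, mirroring
common Bayesian-GBLUP defaults. Missing responses are sampled each
iteration, so their posterior-mean linear predictors are the predictions;
this is how masked test sets are predicted (`predict_masked()`).

Numerical policy: eigenvalues in $(-10^{-6}\cdot\lambda_{max}, 0)$ are
clipped to zero, more negative values are a hard error; near-null
eigenvalues (below $10^{-10}\cdot\lambda_{max}$) are dropped from the
sampled basis. The default chain (42 000 iterations, 2 000 burn-in,
thinning 5) mirrors a full-length analysis; tests and the scaled-down
experiment path use 4 000/500/2, which the oracle-equivalence checks show
is adequate at the problem sizes used here.

`blup_oracle()` is the deterministic cross-check and fast path: at fixed
variance components it solves the GLS mean and kernel-wise BLUPs from
$V = \sum_k \sigma^2_k K_k + \sigma^2_\varepsilon I$. The test suite
asserts the sampler matches it (correlation > 0.999 at fixed variances).
The forward-prediction studies use this path with variance components
estimated once per dataset by a short chain, which keeps large
cross-validation grids tractable without changing the model.

## Hyperparameter tuning and fANOVA

`tune_bayes_gp()` evaluates an initial Latin-hypercube design (10 points)
and then 30 expected-improvement acquisitions from a Gaussian-process
surrogate (RBF kernel on the unit-cube encoding of the space,
median-heuristic length scale, small nugget), each configuration scored by
fivefold inner cross-validation with two repeats on the training rows only.
The tuned space covers learning rate (log-uniform $10^{-3}$–0.3), tree
depth (1–12), number of trees (100–2000), minimum child weight (1–20),
per-tree feature fraction (0.3–1) and row subsample (0.5–1); other engine
options stay at defaults. `fanova_importance()` fits a random forest to the
trial log and decomposes each tree's variance exactly over its axis-aligned
leaf partition of the unit cube: main-effect and pairwise marginals of a
piecewise-constant tree are themselves piecewise constant, so their
variances are computed in closed form per tree and averaged. Shares are
nonnegative and sum to at most one (higher-order interactions absorb the
rest).

The two GBDT backend ids (`gbdt_a`, `gbdt_b`) bind to the two
histogram-based split-finding algorithms of the xgboost engine (`hist` and
`approx`) behind a common adapter, so code written against the adapter is
engine-agnostic.

## The synthetic MET generator

`simulate_met()` produces a complete dataset with known ground truth:

* **Genomes.** Inbreds are homozygous mosaics of eight founder haplotypes
  per 20-marker linkage block (strong within-block LD, including duplicate
  columns, so pruning has work to do), with injected heterozygous and
  missing calls and a fraction of markers tagged multi-allelic to exercise
  the filters. Hybrids are planned as unique unordered crosses; their true
  dosages are parent means of the pre-injection matrix.
* **Trial network.** Sites span latitudes 34–45 with climate parameters
  tied to latitude; each site-year gets daily weather from a seasonal
  sinusoid with AR(1) anomalies (temperature), a two-state Markov chain
  with gamma amounts (rain), and bounded noise around seasonal means
  (humidity, wind, radiation). A sub-daily expansion (30-minute cadence,
  diurnal sine temperature, half-sine radiation) with injectable stuck /
  gap / spike sensor faults feeds the QC tests. Hybrids enter in yearly
  cohorts and stay one to three seasons, as in a real network — this is
  what makes CV00 (prediction of never-tested genotypes) a nonempty
  problem.
* **Phenology.** Each hybrid carries a thermal requirement (normal, mean
  750, SD 40 growing degree days base 10 — a typical planting-to-silking
  range for temperate hybrids); silking is the first day the cumulative
  daily growing degrees from planting reach it, so warmer sites flower
  earlier and the growth windows shift with them.
* **Phenotypes.** Plot values follow
  $y = \mu + E + g + w + gw + gE + r + \varepsilon$: environment effects
  split into site, year and environment deviations; $g = X b$ a linear
  combination of markers; $w = W\gamma$ a random regression on the ECs;
  $gw = \sum_q W_q (x \cdot c_q)$ the marker-by-covariate interaction; $gE$
  independent genomic vectors per environment (exactly the
  $G \circ Z_EZ_E'$ covariance); replicate and plot noise. Every realized
  term is rescaled so its sample variance equals the configured component
  exactly, making recovery tests well defined. Sparsity choices reflect
  what field studies report: the EC main effect loads on a quarter of the
  covariates, about 30% of ECs interact with the genome, and the
  interacting marker combinations load on the top five axes of genetic
  variation (in maize, GxE is driven to a large extent by adaptation loci —
  flowering time above all — that co-vary with population structure) plus a
  sparse marker-specific remainder.

What the generator does **not** emulate: spatial field trend within trials,
multi-trait genetic correlations, dominance or epistatic genetic values,
crop-growth-model physiology, irrigation scheduling beyond a fixed
configurable schedule, and real station-network error structure. Passing
tests therefore demonstrate that the pipeline recovers the structure this
generator encodes, not that any particular real dataset will show the same
gains.

## Design choices where the design was open

* **EC standardization within cross-validation.** The ML feature table is
  standardized with training-row statistics only. The kernel models use the
  EC matrix standardized over all observations: evaluation assumes the
  realized weather of the target environment is known (the schemes predict
  new *years/sites*, not unknown future weather), and the covariate values
  of test environments are legitimately available at prediction time.
* **Frequencies as fractions.** The frequency covariates (FreqP5,
  FreqMaxT30/35) are fractions of window days rather than raw counts so
  that windows of different lengths are comparable.
* **LD-prune determinism.** When a pair exceeds the $r^2$ threshold, the
  member with the lower minor allele frequency is dropped, ties to the
  larger column index — a deterministic stand-in for an external tool's
  unspecified rule.
* **Imputation.** Per-marker mode imputation replaces a haplotype-based
  imputer: observed-call preservation, not imputation quality, is what
  downstream results depend on, and the mask-and-restore test shows
  concordance well above the marginal-guessing baseline.
* **Outlier pass runs once.** Whether to iterate the outlier rule is not
  determined by the procedure's description; one pass is deterministic and
  avoids the masking feedback of repeated refits.
* **$\Omega$ scaling.** $WW'$ is divided by the number of EC columns so its
  diagonal averages about one, making variance components comparable across
  kernels; only proportionality is required by the model.
* **Per-EC effects.** The EC main effects $\gamma_q$ are never materialized
  — they exist only through $\Omega$. A back-solve could expose them but is
  deliberately not a default output.
* **Minor-allele coding.** The minor allele is defined on the parent panel
  at first computation and frozen for hybrid coding, preventing allele-flip
  inconsistencies between parents and hybrids.

## Problem sizes and study conditions

The package's studies run at desk scale. The default generator
configuration is 50 inbreds, 800 markers, 120 hybrids, 5 sites × 4 years,
two replicates, ~65% of the active cohort tested per environment, and
grain-yield-like variance components (in trait units²: environment 1.0,
site 0.4, year 0.3, genomic 0.4, EC main 0.35, GxW 0.3, GxE 0.3, replicate
0.05, residual 0.7 around a mean of 7) — GxE of the same order as the
genomic variance, as is typical for yield.

The **recovery study** asks whether the sampler's posterior means find the
generative variance components. It uses the generator's
`effects_from_kernels` mode, in which every term is drawn exactly from its
model covariance (environment effects IID per environment, EC effects IID
per covariate, interactions from the Hadamard kernels), so the configured
variances are the true kernel parameters — the literal generative reading
of the model equations. The condition is the single-environment-effect
structure (site and year variances zero) at 8 sites × 5 years
(~40 environments, ~1450 observations) with a flowering-requirement SD of
100 growing degree days, and five replicate seeds. Both condition choices
are identifiability-driven and worth understanding: when the EC rows are
nearly constant within environments, Ω and the environment block kernel
span an almost flat likelihood direction, and with few environments the
prior redistributes variance between them (the environment component reads
low, the EC component high). A diverse flowering spread — which real
hybrid panels have — and enough environments break the degeneracy; with
materially fewer environments the split is simply not identifiable to
useful precision, and no sampler would rescue it.

The **forward-prediction study** (CV00-Year) isolates the
marker-by-covariate channel: its two conditions differ *only* in the GxW
variance (1.2, dominant, versus 0), with the EC main effect and the
flowering spread both set to zero so the EC columns carry no
genotype-specific signal except through GxW. This isolation matters: with
a nonzero EC main effect the boosted trees gain a small predictive-ability
edge from EC features even without any GxW, because the features absorb
environment means and denoise the genomic fit — a real, but indirect,
benefit that would contaminate a null comparison. A weaker version of the
same channel survives even with all EC signal removed: the EC columns
uniquely fingerprint environments, so boosted trees use them to absorb the
environment-mean variance during training, which denoises the genomic fit
and lifts new-year predictive ability by a few hundredths of a correlation
unit. The null comparison is therefore made against the kernel-model
baseline (no W-including model should beat it beyond noise), not as a
two-sided equality between the two GBDT variants. Ten seeds for the
dominant condition, five for the null. Chains are 4 000 iterations with
500 burn-in in these studies, with variance components for the
cross-validation fits estimated once per dataset on training rows; the
oracle-equivalence tests justify the short chains and the fixed-variance
prediction path at these sizes.

## Known limitations

* Linear kernels only; Gaussian/arc-cosine kernels and dominance effects
  are out of scope.
* Spatio-temporal kriging of weather gaps is not implemented — inverse
  distance weighting only.
* The exact QC thresholds of operational station networks vary; the range
  limits here are configurable defaults.
* CV1/CV2-style incomplete-trial schemes are not implemented.
* The weighted-ability summary inherits the instability of
  per-environment correlations in small environments; environments with
  fewer than 3 observations are excluded.
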