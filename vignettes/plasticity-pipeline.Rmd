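---
title: "Modelling phenotypic plasticity from weather, phenotypes and markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling phenotypic plasticity from weather, phenotypes and markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastinorm)
```

## The model

A multi-environment trial observes each accession $i$ in environments
$e = 1, \dots, E$. plastinorm models the trait value as a linear reaction
norm on a scalar **environmental index** $EI_e$:

$$y_{ie} = \beta_{0i} + \beta_{1i}\,(EI_e - \overline{EI}) + \varepsilon_{ie},$$

where $\beta_{0i}$ (the intercept, reported at the mean index) is the
accession's expected performance and $\beta_{1i}$ (the slope) its
sensitivity to the environmental gradient. Because the index is centered,
the intercept equals the accession's across-environment mean under complete
data, and intercept and slope are orthogonal descriptions of level and
plasticity.

The index itself is not assumed known. It is found by an exhaustive
**window scan** (`scan_windows()`): for each of 14 weather-derived
parameters and every growth window $[s, t]$ (days after planting, closed
interval, minimum length 7 days, search capped at day 250), the window mean
across environments is correlated with the trait's **environmental mean**
(the average over accessions within each environment). The
(parameter, window) pair with the largest $|r|$ is the index. Prefix sums
over days make the scan $O(\text{parameters} \times \text{days}^2)$ with
$O(1)$ per window.

Two caveats are built into the interface rather than hidden:

* With ~10 environments and hundreds of thousands of candidate windows,
  the winning training $|r|$ is upward-biased by selection.
  `loeo_rescan()` quantifies the bias by re-running the scan with each
  environment held out and re-scoring the chosen window on all
  environments.
* Ties in $|r|$ are broken by earlier start then shorter window — a
  convention, stated here because no principled rule exists at this data
  size.

## The 14 environmental parameters

`derive_parameters()` evaluates a registry of daily formulas per
environment: DL (astronomical day length from the solar-declination
formula), GDD ($\max(0, (\min(T_{max}, 30) + \max(T_{min}, 0))/2)$, the
0 °C base / 30 °C cap wheat convention; both configurable), dGDD and dPTT
(day-to-day differences, 0 on day 1), DTR ($T_{max} - T_{min}$), PTT
(GDD × DL), PTR (GDD / DL, 0 when DL = 0), PTD1 (DL × DTR), PTD2
(DL / max(DTR, 0.1)), MMR (Kelvin ratio $T_{min}/T_{max}$, Kelvin so the
ratio stays positive), TSR (MMR²), PR, RH, and PRDTR (PR / max(DTR, 0.1)).
Every entry is a replaceable registry function, so alternative definitions
drop in without touching the pipeline; divisions are guarded so no entry
can return NaN or Inf. A `day_length` column supplied with the weather
(e.g. from a reanalysis product) overrides the computed value.

Days after planting are 1-based and windows are closed intervals, so a
window labelled 147–154 covers eight days.

## Variance partition, heritability and the 3D phenotype space

`partition_variance()` fits the two-way random model
$y = \mu + G + E + G{\times}E + \varepsilon$ at replicate level. Balanced
designs are solved in closed form by expected mean squares; REML (via
lme4, with a high-precision optimizer setting so the two routes agree to
about $10^{-7}$ relative on balanced data) handles everything else.
Negative method-of-moments estimates are truncated at zero and flagged —
the classic two-way ANOVA artefact. Broad-sense heritability uses the two
standard formulas: within an environment
$H^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2 / r)$, and across
environments
$H^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_{ge}^2/e + \sigma_e^2/(re))$.

`tensor_pca()` unfolds the accession × environment × trait array along any
of its three modes and runs a standardized-column PCA. Columns are scaled
to unit variance because traits live on incommensurable scales; this is a
package choice the user can sidestep by pre-scaling. Missing cells must be
imputed first: `impute_missing()` offers chained ridge regression over
trait columns within each environment (the default; preserves multivariate
structure), an index-regression imputer that refits each accession's
reaction norm and predicts the hole (exact on noiseless reaction-norm
data), and trait × environment means as fallback. Observed cells are never
modified, imputation masks are retained, and a trait × environment slab
with no data at all is left missing and flagged rather than fabricated.

## Genomic prediction

`rrblup_fit()` implements ridge-regression BLUP through its GBLUP
equivalent: markers centered by $2p$, kernel $K = M_cM_c^\top / c$ with
$c = \sum 2p(1-p)$, REML by a one-dimensional profile over
$\delta = \sigma_e^2/\sigma_g^2$ on the eigendecomposition of $K$, marker
effects recovered as $\hat\beta = M_c^\top (K + \delta I)^{-1} (y - \mu)/c$
— algebraically identical to the kernel-form breeding values, which the
tests assert to $10^{-8}$. For an inbred panel coded 0/2 the mean diagonal
of $K$ is about 2 (homozygosity doubles the additive variance relative to
the Hardy–Weinberg reference), so the reported $h^2$ multiplies
$\sigma_g^2$ by the realized mean diagonal; without that correction the
genomic variance fraction would be understated by roughly a third.

The three prediction scenarios follow the two-stage scheme — predict the
reaction-norm parameters, then recombine with the index:

* **1to2** (tested genotypes, untested environments): leave-one-environment-out;
  each accession's own line, refit without the held-out environment,
  is evaluated at that environment's index.
* **1to3** (untested genotypes, tested environments): repeated five-fold
  cross-validation over accessions; rrBLUP predicts intercept and slope of
  the held-out fold; predictions are averaged over iterations before
  accuracy is computed.
* **1to4** (both untested): leave-one-environment-out crossed with the
  fold machinery; no model ever sees the test accessions or the held-out
  environment.

Accuracy is the Pearson correlation between predicted and observed,
reported both within each environment and pooled — the per-environment
values are kept because pooling mixes environment means into the
correlation. Folds are stratified by the landrace/cultivar label to avoid
group-confounded splits.

## Locus effects and modes of change

`gwas_scan()` is a deliberately simple stand-in for a full mixed-model
scan: a single-marker linear model with the first three dosage-PCA
principal components as fixed effects, implemented by residualization
(Frisch–Waugh, so the coefficient equals the full-model partial
coefficient exactly), with a Bonferroni threshold. It is adequate for the
synthetic architecture here; its locus counts on real data are not
comparable with multi-locus Bayesian scans.

`effect_trajectory()` follows a marker across environments: the base
allele is the one whose carriers have the lower mean intercept, the
per-environment effect is the carrier-mean difference (alt − base, Welch
test, at least 5 carriers per class), and the effects are regressed on the
index. `classify_dynamics()` maps a trajectory to antagonistic pleiotropy
(significant effects of opposite sign), conditional neutrality
(significant somewhere, not everywhere, no sign reversal among significant
effects), or differential sensitivity (everything else, including
all-non-significant trajectories — magnitude-only variation). The rules
are explicit stand-ins: the literature's operational definitions vary, so
the three-way split is documented and property-tested to be exhaustive and
mutually exclusive, with per-environment tests unadjusted at α = 0.05
because the classification is descriptive.

`mode_table()` compares intercept and |slope| between landraces and
cultivars per trait (two-sided Wilcoxon rank-sum by default, α = 0.05,
unadjusted across traits; t-test and p-adjustment available). "Constant"
means non-significant — the only reading under which a 3 × 3 grid of
modes can be partially occupied. The grid is row-major over intercept ×
slope directions, anchored by a = (decrease, decrease),
c = (decrease, increase), i = (increase, increase);
`summarize_modes()` reports per-mode shares, the share of traits with both
parameters moving together (a + i) and in opposition (c + g). |slope| is
used because the sign of the slope is a property of the trait, not the
accession, whereas its magnitude is the sensitivity being compared.

## The synthetic trial generator

`simulate_study()` exists so every stage has a recoverable target. Its
defaults mirror the design the package is built around: 406 accessions (87
landraces, 319 cultivars), 10 environments from two locations × early
(autumn) and late (winter) plantings over consecutive years, 250 days of
daily weather each, 17 traits in three categories, three replicates, and a
hidden index — dPTT over days 147–154 by default — injected through the
actual weather, not sampled directly, so the window scan has a true
(parameter, window) answer. `paper_scale_config()` additionally blanks
nine traits in one environment, giving the design's
406 × (8×10 + 9×9) = 65,366 observed cells.

Choices that matter when interpreting test results:

* Weather is a seasonal sinusoid plus AR(1) noise. Residual draws are
  standard normals scaled by `residual_sd`, so runs differing only in the
  noise level share the same noise shape under one seed — this is what
  makes "more noise never sharpens the scan" testable per seed.
* Slopes are drawn in standardized-index units (trait units per SD of the
  realized index) and converted by the realized index SD, so the
  G×E signal has the same magnitude whichever parameter and window carry
  the index. The population mean slope is nonzero — slope sign is
  typically consistent within a trait — which is also what makes the
  environmental mean respond to the index at all.
* Intercepts and slopes are QTL-plus-polygenic genetic values (genetic
  scores standardized empirically) mixed with Gaussian deviations at the
  target heritabilities, defaulting to $h^2 = 0.8$ for intercept and 0.6
  for slope.
* Trait categories scale the variance mix qualitatively — developmental
  traits environment-dominant (large slopes, small genetic intercept
  spread), architecture traits genotype-dominant, yield traits mixed.
  Per-trait residual variances are presets, not calibrated values: the
  real study does not report them.

What the generator does **not** emulate: crop physiology (no growth-stage
feedback between weather and development), linkage disequilibrium and
recombination (markers are independent), non-linear reaction norms,
heteroscedastic measurement error, and spatial field effects. Tests that
pass on this generator therefore validate the estimators and the
machinery, not the biology of any particular dataset.

## Numerical choices and problem sizes

Degenerate inputs fail loudly: zero-variance correlations, a flat index, a
window outside the weather range, unimputed missing values in PCA, and
accessions with fewer than three environments (marked missing, never
extrapolated). REML profiles are optimized on $\log\delta$ over
$[10^{-6}, 10^{6}]$; kernel eigenvalues are clipped at zero.

The test suite runs the heavier statistical properties at deliberately
chosen sizes: window recovery over 100 seeded runs of a 50-accession,
10-environment, 250-day trial; REML heritability recovery at n = 400,
p = 500 over a 5-seed batch (asserted on the batch mean); family-wise
error of the null association scan over 200 scans at n = 120, p = 400;
type-I calibration of the group comparison over 1,000 null replicates; and
the scenario-accuracy ordering over a 5-seed batch of 100-accession
trials. The acceptance script (`scripts/acceptance.R`) runs the full
pipeline at the 406-accession design scale with a 400-marker panel and a
150-accession sub-panel for the cross-validated rrBLUP stages.

## Known limitations

The association scan has no kinship correction beyond three PCs; the
imputer is not missForest and will be weaker under strongly non-linear
trait dependencies; the mode classification inherits the power of the
rank-sum test, so modest group shifts are called "constant"; and all
selection-biased quantities (the scan's top $|r|$ above all) should be
read alongside the leave-one-environment-out diagnostic, not instead of
it.
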