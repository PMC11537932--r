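---
title: "Methods: envirotyping-based optimization of multi-environment trial networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: envirotyping-based optimization of multi-environment trial networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A rice breeding program evaluates advanced lines in a multi-environment trial
(MET) network: the same genotypes planted at many locations over several
years. Phenotyping is expensive (here $25 per plot), and much of the network
is environmentally redundant — several locations sample the same conditions.
`enviromet` implements a pipeline that (i) characterizes each trial location
by climate and soil covariates tuned to the crop's development, (ii) selects
the covariates that actually predict yield, (iii) groups locations into
mega-environments, (iv) quantifies what genetic accuracy would be lost by
testing in fewer locations, and (v) weighs trial allocation against the
economic importance of each target population of environments (TPE).

The package ships a synthetic trial-network generator with known ground
truth; every statistical claim made by the pipeline is validated against that
truth in the test suite.

# The two-stage mixed-model analysis

**Stage 1 (single trial).** For each location-year, plot yield is modeled as

\[ y = \mu + G_i + R_j + L_m + C_n + \varepsilon, \]

with genotype fixed and replicate, field row, and field column independent
random effects. The fit returns genotype BLUEs with standard errors. A
two-dimensional spline surface is sometimes used for spatial trend in this
role; here the row and column effects absorb the first-order trend, which is
all the downstream pipeline consumes (only the BLUEs move forward). This is a
deliberate design simplification, stated up front.

**Stage 2 (joint analysis).** Stage-1 BLUEs are modeled as

\[ y = \mu + Y_x + E_j + G_i + GE_{il} + \varepsilon, \]

with year and environment (location nested in year) fixed, genotype random
\(G_i \sim N(0, \sigma^2_g)\), and a genotype-by-environment term whose
covariance is, depending on the scenario, identity, the enviromic kernel
\(\Omega\), or a genotype-by-cluster structure, all built as Hadamard
products of incidence cross-products with the kernel.

One structural choice deserves emphasis: the GxE term is indexed by
**location**, not location-by-year. The enviromic kernel is a similarity
between locations (climate archetypes and soil carry no year subscript), and
with a single BLUE per genotype-environment cell a location-by-year GxE term
is exactly confounded with the residual — REML would split their sum
arbitrarily. Indexing by location makes \(\sigma^2_{ge}\) identifiable
whenever a location is trialed in more than one year, which is the design
this pipeline targets. Location-by-year main effects remain fixed.

The second stage is unweighted by default; stage-1 standard errors can be
carried as residual weights via `stage2_fit(..., weighted = TRUE)`. The
defaults follow the common practice of an unweighted second stage when
stage-1 designs are near-balanced.

## The REML engine

`fit_reml()` is a dense average-information (AI) REML implementation:
\(V(\theta) = \sum_k \theta_k Z_k K_k Z_k' + \theta_\varepsilon R\), the REML
log-likelihood is maximized by AI steps with step halving, a multiplicative
fixed-point fallback, and projection of components onto a feasible box.
Numerical choices that matter:

- Components are floored at \(10^{-6}\,\mathrm{var}(y)\) and capped at
  \(10^{4}\,\mathrm{var}(y)\). The floor is reported as an estimate of zero
  (flagged in `$boundary`). Floor and cap bound the condition number of
  \(V\), which dense double-precision algebra needs; without the cap, exactly
  degenerate inputs (e.g. noise-free data whose response lies in the span of
  the random effects) send the likelihood to a numerical divergence.
- Components pinned at the floor with negative score are excluded from the
  AI system, which removes the slow boundary creep that plagues naive AI
  iterations.
- Convergence requires a relative log-likelihood change below \(10^{-10}\)
  or all free-component scores below \(10^{-8} n\); non-convergence is a
  warning and is flagged on the fit.
- Aliased fixed-effect columns are dropped by pivoted QR (logged), which is
  how the intercept/year/environment aliasing of the nested fixed structure
  resolves.

BLUPs and their full prediction-error variance (PEV) matrices come from the
mixed-model identities at the optimum:
\(\hat u_k = \theta_k K_k Z_k' P y\) and
\(\mathrm{PEV}_k = \theta_k K_k - \theta_k^2 K_k Z_k' P Z_k K_k\).

The engine is validated against closed-form balanced one-way estimators, a
brute-force log-likelihood grid, dense GLS oracles for unbalanced BLUEs, and
`lme4` as an independent implementation on a shared fixture.

## Heritability

Broad-sense heritability per scenario uses the Cullis form

\[ H^2 = 1 - \frac{\bar v_\Delta}{2 \hat\sigma^2_g}, \]

with \(\bar v_\Delta\) the mean variance of a difference between genotype
BLUPs, computed from the full PEV matrix. Some texts describe the
denominator term loosely as an "average standard error of the BLUPs"; the
pairwise-difference definition is the standard and is the default here, with
the mean-PEV reading available as `cullis_h2(method = "mean_pev")`. Values
are clipped to [0, 1] with a message; \(\hat\sigma^2_g = 0\) defines
\(H^2 = 0\) with a warning.

# Envirotyping

Daily weather per location is summarized over six rice development windows
(emergence to maximum tillering 0–44 days after emergence, maximum tillering
to panicle initiation 45–59, panicle initiation to pre-flowering 60–74,
pre-flowering to flowering 75–89, flowering to post-flowering 90–104,
post-flowering to maturity 105–148). Each daily variable contributes its
window mean; two covariates are derived per window — growing degree-days
(GDD), the window sum of daily thermal time, and the diurnal temperature
range. With 17 daily variables this gives the canonical 19 base covariates
per stage and \(19 \times 6 = 114\) weather columns; joining 11 soil
covariates yields 125 before quality control.

GDD uses the capped single-triangle rule: daily extremes are clipped to the
cardinal interval and thermal time is
\(\max(0, (\mathrm{clip}(T_{min}) + \mathrm{clip}(T_{max}))/2 - T_{base})\).
Cardinal temperatures are not universal constants for rice; the defaults
(base 10 °C, optimum 30 °C, maximum 42 °C) sit inside commonly cited ranges
and are configurable. Because the synthetic truth is generated under the
same settings, the pipeline's validation results are invariant to this
choice.

The joined matrix is centered and scaled per column (the scaling record is
retained, so county profiles can be projected into the same space), and
collinear covariates are removed by a greedy filter: while any pair exceeds
|r| ≥ 0.95, drop the involved column with the largest mean absolute
correlation (ties drop the later column). The filter asserts its own
post-condition on every run. The threshold is the only part of this rule
fixed by convention; the greedy mean-correlation heuristic mirrors the
widely used `caret::findCorrelation` logic.

# Covariate selection

`rfe_select()` implements recursive feature elimination with a regression
random forest, under repeated K-fold cross-validation over environments
(5 folds × 5 repeats). Within each resample the forest is fitted on all
candidate covariates, covariates are ranked by impurity importance, and the
forest is refitted at each candidate subset size on the top-ranked set,
scoring held-out environments. R² is pooled per repeat as 1 − SSE/SST (it
can be negative) and averaged over repeats; the chosen size maximizes mean
CV R². Both the CV R² (headline) and the training R² of the final refit are
reported, since small-n cross-validated R² is systematically far below
training R² for forests.

No random-forest package is available in the target environment, so the
learner is implemented in the package (C++): CART variance-reduction splits,
bootstrap resampling, `mtry = p/3` feature subsampling, minimum node size 5,
500 trees by default, driven by R's RNG for reproducibility. It was checked
against scikit-learn's `RandomForestRegressor` on shared fixtures during
development (rankings and accuracy agree); the test suite validates it
against planted signal/noise designs only, keeping the suite free of
network and Python dependencies.

The response for selection is the per-environment mean of stage-1 genotype
BLUEs: the statistic of interest is how much of the yield variation *across
sites* the covariates explain.

# Enviromic kernels and mega-environments

The enviromic relationship kernel is
\(\Omega = W W' / (\mathrm{tr}(W W') / n)\), normalized so its trace equals
the number of environments. The yield-based counterpart \(\Omega_{yield}\)
applies the same normalization to the environment × genotype matrix of
stage-1 BLUEs (averaged over years within location so both kernels live on
the same location set; missing cells imputed by genotype means, columns
centered and scaled). Note a degeneracy worth knowing: with only two
environments, column centering forces the two rows to be exact negatives, so
similarity pattern checks need at least three environments.

Kernels are compared by Pearson correlation over strict upper-triangle
entries (diagonals are normalization artifacts) and by a Gaussian KDE
summary (Silverman bandwidth, 512-point grid) of those entries: peak
location, mean, SD.

Mega-environments are delimited by k-means (Lloyd iterations via
`stats::kmeans`, k-means++ seeding implemented here, best of 50 starts) on
the RFE-selected covariates. The number of clusters is chosen by a
formalized elbow rule on the within-cluster sum of squares: the smallest k
whose drop to k+1 falls below 10% of the 1→2 drop. For TPE delimitation over
counties, a two-step recipe first removes any cluster that is both small
(≤ 15% of counties) and remote (nearest centroid farther than twice the
pooled within-cluster RMS spread of the other clusters), then re-clusters
the remainder — the pattern seen when one production region is
environmentally isolated from the rest of a belt.

Cluster adjusted means come from a mixed model with cluster fixed (cell
means), genotype random, and genotype-by-cluster random. New sites or
counties are assigned to clusters by minimum Euclidean distance to the
centroids in the scaled covariate space, ties to the lowest index (logged).

# Scenarios and economics

Four evaluation scenarios are fitted on the same BLUEs: `MET` (identity
GxE), `MET_EC` (\(\Omega\)-structured GxE), `WC_MET` (the MET model inside
each cluster; aggregate = unweighted mean ± SD over clusters; singleton-
environment clusters are excluded with a warning), and `OPT_MET` (one
location sampled uniformly per cluster, MET on the subset, 10 replicates;
mean ± SD). Costs are genotypes × replicates × price per plot × locations ×
years; the efficiency measure is H² per dollar. Reduction percentages are
100 × (1 − retained/total), rounded half-up to one decimal. A caution for
readers comparing against breeding-program reports: the "reduction" quoted
for an advanced-trial optimization is sometimes the retained-share ratio
(5/18 ≈ 27.8%) rather than its complement; this package uses the complement
consistently, matching the network-wide simulation's definition.

# The synthetic world

The generator's defaults are the stated conditions of the target network: 25
genotypes (9 in year 1, the 9 common to both years), 18 locations in 5
archetype clusters, 2 years, RCBD with 3 blocks, ~9,000 kg/ha mean yield.
Variance components default to (kg/ha)²: genotype 250,000; GxE 80,000; block
40,000; row and column 22,500; plot residual 200,000 — a genotypic SD of
500 kg/ha and residual SD of ~450 kg/ha, magnitudes a rice trial analyst
would call routine. The GxE-to-genotype ratio (0.32) and the residual were
calibrated once so that the default network shows the heritability pattern
reported for advanced rice trial networks of this scale (Cullis H² around
0.96–0.97 over 18 locations, falling to roughly 0.87–0.89 when one location
per cluster is retained); with these values the package's own fits land at
that pattern, and all recovery checks hold with margin.

Structure the generator plants, and what it does not:

- **Archetypes.** Clusters sit on two environmental gradients (a primary
  ladder and an alternating secondary contrast); each of the 8 informative
  covariates — three dew-point windows, minimum temperature and diurnal
  range around panicle initiation, flowering-window GDD, soil TCEQ and
  SILT — loads on the two gradients at its own angle (spread over ±70°).
  Adjacent archetype levels differ by 6 within-cluster location SDs. The
  angle spread keeps every covariate pair below the 0.95 collinearity
  threshold in expectation, and the separation makes the mega-environments
  unambiguous: k-means on the true window means recovers the partition
  exactly, and the elbow rule finds the planted k. The separation is a
  design declaration of "clearly distinct mega-environments", well above
  the ≥ 1 SD floor needed for recoverability.
- **Environment means.** Location main effects are a linear function of the
  scaled informative profile (SD 400 kg/ha) plus unexplained noise (SD 150),
  so environment-level mean yield is genuinely predictable from the planted
  covariates — cross-validated R² of the selection step lands around 0.6–0.8
  on default seeds, the regime the method is meant for.
- **GxE.** A linear reaction norm: genotype-specific sensitivities times the
  scaled informative profile carry 80% of \(\sigma^2_{ge}\); the rest is
  i.i.d. GxE is constant across years within a location (climate-archetype
  driven), matching the stage-2 model's location-indexed GxE term.
- **Weather.** Daily values are independent Gaussians around archetype
  window-mean profiles; `T2M_MAX = T2M_MIN + range` enforces min ≤ mean ≤
  max. No autocorrelation, fronts, or extreme events are emulated — so a
  green test establishes correct *recovery of planted structure*, not
  robustness to realistic weather pathologies.
- **Economics.** County production shares are skewed (log-normal,
  normalized); counties inherit archetype profiles with jitter.

Because the response surface of the planted world is effectively
two-dimensional (two gradients), RFE legitimately prefers small subsets
(often 2–4 covariates); the planted-partition acceptance check therefore
supplies the planted number of clusters to k-means, the standard
planted-partition evaluation, while the elbow rule is validated separately
on the planted profiles.

# Known limitations

- No spatial spline smoothing in stage 1; strong non-linear spatial trend in
  real fields would leak into row/column effects and the residual.
- The stage-2 location-indexed GxE term needs at least two years of trials
  at (some) locations to separate \(\sigma^2_{ge}\) from the residual; with
  one year the two are confounded, as in any single-BLUE-per-cell layout.
- Dense algebra bounds practical problem size to a few thousand stage-2
  rows; ample for breeding-network scale, not for genomic-scale data.
- The random forest is a compact reimplementation, not a drop-in for
  `ranger` at scale (no parallelism, no honest variable-importance p-values).
- Synthetic weather is statistically, not meteorologically, realistic.
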