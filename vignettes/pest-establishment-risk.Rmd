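---
title: "Methods: establishment risk and economic impact assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: establishment risk and economic impact assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pestrisk)
```

`pestrisk` implements a complete desk-scale workflow for assessing the
establishment risk of an invasive agricultural pest and its economic
consequences: habitat-suitability modelling from occurrence records,
threshold classification and crop-area overlay, multidimensional niche
comparison across invaded regions, and stochastic simulation of
economic losses and control benefits. This vignette explains the models,
their assumptions, the tunable parameters, and the design choices made
where the methods literature leaves the details open.

## Occurrence handling

Occurrence records arrive as longitude/latitude tables
(`read_occurrences()`), are validated against the geographic domain, and
are spatially thinned to at most one record per cell of a template
raster (`thin_to_grid()`). Thinning to the modelling grid removes
duplicate sampling of the same environment, the dominant source of
spatial pseudo-replication in presence-background modelling. Two
conventions are ours: cells are half-open intervals
`[west, east) x [south, north)` so boundary points are unambiguous, and
the record retained within a cell is the first in input order — a
deterministic, auditable rule; the thinning literature does not
prescribe one. `split_train_test()` partitions records with
`round(n * fraction)` training rows (default 75/25).

## The maximum-entropy model

The suitability model is a Gibbs density over the landscape,
constrained by presences and a background sample of available
environment. With feature vector $f(x)$ and coefficients $\beta$, the
model is

$$P(x) = \frac{e^{\beta^\top f(x)}}{Z(\beta)}, \qquad
Z(\beta) = \sum_{x \in \text{background}} e^{\beta^\top f(x)},$$

fitted by maximizing the L1-penalized presence log-likelihood

$$\ell(\beta) = \frac{1}{m}\sum_{i=1}^{m} \beta^\top f(x_i) - \ln Z(\beta)
  - \sum_j \lambda_j |\beta_j|, \qquad
  \lambda_j = \mathrm{rm}\cdot \beta_{fc}(m) \cdot \frac{s_j}{\sqrt m},$$

where $m$ is the presence count, $s_j$ the presence standard deviation
of feature $j$, `rm` the user-facing regularization multiplier, and
$\beta_{fc}(m)$ a per-feature-class scale (linear/quadratic/product
classes interpolate $\{10 \to 1.0,\ 30 \to 0.6,\ 100 \to 0.3,\ \ge 200
\to 0.15\}$; hinge features use a constant $0.5$). These constants
follow the de-facto defaults of maximum-entropy SDM software; only
their relative behavior matters for the package's tests, and
`fit_maxent(beta_fc = ...)` accepts alternatives.

### Feature classes

`build_features()` expands covariates into bounded features: **L**
(min-max scaled to $[0,1]$ over the background range), **Q** (square of
the scaled variable), **P** (pairwise products of scaled variables),
and **H** (forward hinges $\max(0, (x-k)/(x_{\max}-k))$ and reverse
hinges at knots $k$ placed at equally spaced background quantiles;
default 20 knots per direction, configurable — fewer than production
Maxent uses, which keeps desk-scale fits fast while preserving the
piecewise-linear flexibility hinges exist for). Threshold features are
deliberately not implemented: the tuning grid this package targets
never includes them. Scalings are frozen on the background table so
presences and projections are expanded identically.

### Optimization

The fitter is cyclic coordinate descent with soft-thresholded Newton
steps. Each proposed update is backtracked until the *penalized*
objective improves, so the objective trace is non-decreasing by
construction — that trace, not the unpenalized gain, is the
monotonicity guarantee, since a shrinkage step can legitimately lower
the unpenalized fit while improving the penalized objective. Stopping
uses a relative objective change below `tolerance` (default `1e-5`)
with a 500-cycle cap.

Single coordinate updates are additionally capped at `max_step = 0.25`.
Unbounded Newton steps let the first of two collinear features absorb
all the objective gain; small interleaved steps distribute gain across
competing features without changing the optimum, which keeps the
per-feature gain ledger — the basis of `variable_contributions()` —
close to symmetric for duplicated or strongly correlated variables.
Features with zero presence variance are never updated: a constant
presence profile carries no usable contrast against the background, and
leaving such coefficients at zero makes the all-equal-presences edge
case well defined.

One check worth singling out: for a single linear feature, the fitted
coefficient matches a brute-force grid search over the same penalized
objective to within $2\times10^{-3}$ — an end-to-end validation of the
gradient, penalty and stopping logic against an implementation-free
oracle.

### Output scales, AUC, tuning

`predict_raw()` returns the Gibbs density normalized over the training
background ($\sum \text{raw} = 1$ to $10^{-6}$ after every fit, an
asserted invariant). `predict_cloglog()` maps raw into $[0,1]$ via
$1 - \exp(-e^{H}\cdot \text{raw})$, with $H$ the Shannon entropy of the
raw distribution — the modern default output of maximum-entropy SDMs; a
null model yields $1 - e^{-1} \approx 0.632$ everywhere. AUC
(`evaluate_auc()`) is the rank-statistic estimate of
$P(\text{presence score} > \text{background score})$ with ties counted
half, invariant under monotone rescaling.

`tune_sdm()` fits every combination of a regularization grid (default
0.5–6 in steps of 0.5) and a feature-class grid (default L, LQ, H, LQH,
LQHP — 60 candidates) and scores each with
$\mathrm{AICc} = 2K - 2\ln L + 2K(K{+}1)/(n{-}K{-}1)$, where $K$ counts
coefficients with $|\beta| > 10^{-8}$ and the likelihood is the
presence probability of the background-normalized raw density.
Candidates with $n \le K+1$ are excluded as invalid. Ties break toward
parsimony (smaller $K$), then smaller `rm`, then grid order.
`bootstrap_replicates()` resamples presences with replacement
(background fixed — "bootstrap" here is a presence resampling scheme),
splits each resample 75/25, fits on the train part, scores the test
part, and averages the replicate cloglog maps.

## Suitability classification and areas

`mtp_threshold()` is the minimum cloglog score among training
presences, so thresholding at it classifies every training presence as
suitable. `classify_suitability()` reclassifies into four codes with
half-open intervals — $[0, \mathrm{mtp})$ unsuitable,
$[\mathrm{mtp}, 0.4)$ low, $[0.4, 0.6)$ moderate, $[0.6, 1]$ high — the
top class closed so a perfect score is classified. Areas
(`class_areas()`) use the spherical cell area
$R^2\,\Delta\lambda\,(\sin\varphi_t - \sin\varphi_b)$ with
$R = 6371.0088$ km; the spherical (rather than ellipsoidal)
approximation errs by under 0.3%, below the rounding of any reported
area table. `overlay_crop()` restricts areas to a crop mask — binary at
$\ge 0.5$ by default, with a fractional mode because real crop-area
layers are fractional. `compare_scenarios()` produces percent changes
($100(\text{future}-\text{ref})/\text{ref}$, rounded half-away-from-zero
to 2 decimals, as printed tables round), the arithmetic mean across
periods as the period-average column, and a gain/loss change map with
"suitable" meaning class $\ge 1$.

## Niche hypervolumes

Groups of occurrence climates are compared in a standardized niche
space: `standardize_niche()` z-scores each axis with moments pooled
across **all** groups, so one unit means one pooled standard deviation
on every axis and centroid distances are comparable between pairs.
Per-axis bandwidths come from leave-one-out cross-validation of the 1-D
Gaussian KDE over a log-spaced grid (`estimate_bandwidth()`), with the
Silverman rule $1.06\,s\,n^{-1/(d+4)}$ as fallback below 10 points.

`build_hypervolume()` estimates the high-density support of a
product-Gaussian KDE: uniform points are drawn over the bounding box
expanded by three bandwidths per axis, the density threshold is set so
the KDE probability mass above it equals `mass` (default 0.95,
configurable — the inclusion quantile is a modelling choice, not a
published constant), and the volume is the box volume times the
acceptance fraction. Overlap (`overlap_sorensen()`) estimates the
intersection volume by mutual inclusion of support points and returns
the Sorensen index $2V_{\cap}/(V_A + V_B)$; centroids default to
support-point means with raw-observation centroids as an option. All
Monte-Carlo estimates carry their seed. On 2-D fixtures both the volume
and the Sorensen index are validated against a dense-grid integration
oracle (within 10% and $\pm 0.05$ respectively).

## Economic loss and control benefit simulation

The economic model is a stochastic scenario calculation over eight
independent inputs, each a PERT distribution — the scaled Beta with
shapes $1 + 4(b-a)/(c-a)$ and $1 + 4(c-b)/(c-a)$ and mean
$(a+4b+c)/6$ — sampled by Latin hypercube (`lhs_sample()`: exactly one
draw per equal-probability stratum per column, order permuted per
column). Per iteration, with shared draws across all formulas:

* $E = C \cdot D / (W \cdot P_a \cdot M)$ — loss level after control,
  a fraction;
* $F_1 = Q\,I\,R\,P_a/(1 - I R)$ — loss without control;
* $F_2 = S\,I\,C$ — management cost;
* $F_3 = Q\,I\,E\,P_a/(1 - I E)$ — residual loss under control;
* $F_4 = F_2 + F_3$, $F_5 = F_1 - F_4$ — total cost and savings.

Inputs: $Q$ rice yield in suitable habitats (t), $I$ damage rate, $R$
yield loss rate, $P_a$ market price (\$/t), $S$ planted area (hm²),
$C$ unit prevention cost (\$/hm²), $W$ unit yield (t/hm²), $M$ control
effect, $D$ a benefit-correction constant (default 2). Percent-valued
inputs are converted to fractions at load. $C$ is treated as a
per-area cost: that is the only unit under which $F_2 = S \cdot I
\cdot C$ is a dollar amount. The packaged default configuration
(`default_scenario_config()`, mirrored in
`inst/extdata/scenario_rice_china.yaml`) parameterizes rice production
in the suitable range of an invasive rice pest in China; 100,000
iterations run in a few seconds.

Summaries report means, standard deviations, medians and
linear-interpolation percentiles (2.5/5/95/97.5); the equal-tailed
95% interval is the headline uncertainty statement. The interval
midpoint is reported *alongside* the sample mean because risk-software
summaries often print the midpoint under the label "mean" — for skewed
outputs like $F_1$ the two differ noticeably, and reporting both keeps
either reading checkable. Sensitivity (`sensitivity_spearman()`) ranks
inputs by the magnitude of their Spearman correlation with each
output; on the default configuration the loss ranking is $R > I > P_a
> Q$ and the top drivers of total management-scenario cost are $C$ and
$I$, with the remaining managed-scenario inputs ($S$, $Q$, $W$, $P_a$,
$M$) contributing so little variance that their relative order is
within Monte-Carlo noise and is not asserted.

## The synthetic-data generators

Every stage is testable offline through generators with known ground
truth:

* `generate_env_stack()` — environmental layers as latitudinal or
  longitudinal gradients or box-smoothed Gaussian noise; target
  pairwise correlations are achieved by mixing a standardized shared
  latent field ($r \cdot z_{\text{ref}} + \sqrt{1-r^2}\cdot z_{\text{own}}$).
* `generate_true_suitability()` — a logistic log-linear/quadratic
  surface over standardized layers, the recovery target for the SDM.
* `sample_presences()` — cell centers drawn with probability
  proportional to suitability (no within-cell jitter, so thinning
  behavior is exactly testable).
* `generate_crop_mask()` — a random binary mask hitting a requested
  coverage within one cell.
* `generate_niche_clouds()` — multivariate-normal groups in niche
  space.

All generators are pure functions of their seed and arguments. What
they deliberately do **not** emulate: the covariance structure of real
bioclimatic variables, spatial sampling bias in occurrence data, or
climate-model anomaly structure. Passing tests therefore demonstrate
the correctness of the algorithms under known conditions, not
predictive skill on real landscapes.

## Problem sizes and numerical conventions

The test suite runs the parameter-recovery experiment at 500 presences
against 2,000 background points on a 40x40 grid (fitted log-density
correlates with the truth at $r \ge 0.9$), the full 60-candidate tuning
grid at 120 presences with 4 hinge knots, hypervolume oracles at 300
observations with 20,000 support draws, and the economic model at its
full 100,000 iterations — sizes chosen so the whole suite exercises
every advertised property in about a minute on a laptop-class core.
Other conventions: coefficients count as nonzero above $10^{-8}$;
degenerate KDE clouds (all points identical) and zero-variance niche
axes are hard errors; constant screening variables are dropped first
with an explicit reason; an undefined percent change (zero reference,
nonzero future) is reported as `NA`, not infinity.

## Known limitations

* Rasters are plain in-memory matrices with an ESRI ASCII text dialect;
  there is no projection engine, and mismatched geotransforms are an
  error rather than an implicit resample.
* The correlation screen's greedy mean-|r| elimination is one of
  several defensible rules; `keep_priority` exists precisely so any
  published variable list can be reproduced exactly.
* Background-normalized AICc model selection is standard but debated;
  it is implemented as specified, not defended.
* The bootstrap scheme resamples presences only; background resampling
  and cross-validation replicate schemes are out of scope.
* Hypervolume set operations beyond the intersection needed for the
  Sorensen index (unions, holes) are not implemented.
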