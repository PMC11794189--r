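# pestrisk

Quantitative establishment-risk assessment for invasive agricultural
pests, in R. The package covers the full workflow a risk analyst runs
when a pest with known occurrences threatens a staple crop:

1. **Habitat suitability** — a maximum-entropy (Maxent-family)
   presence-background model, written from scratch: the Gibbs density
   `P(x) = exp(β·f(x)) / Z` over a background sample, fitted by
   L1-penalized likelihood with per-feature-class penalties
   `λ_j = rm · β_fc(m) · s_j / √m`, with linear/quadratic/hinge/product
   feature expansions, AICc tuning over a regularization × feature-class
   grid (`AICc = 2K − 2 ln L + 2K(K+1)/(n−K−1)`), bootstrap replicates,
   percent-contribution and jackknife diagnostics, and cloglog output
   `1 − exp(−e^H · raw)`.
2. **Suitability mapping** — minimum-training-presence thresholding,
   four-class reclassification (unsuitable / low / moderate / high at
   MTP, 0.4, 0.6), spherical latitude-weighted class areas in 10⁴ km²,
   crop-mask overlay, and percent-change tables across climate
   scenarios.
3. **Niche comparison** — kernel-density n-dimensional hypervolumes on
   pooled z-scored climate axes with cross-validated bandwidths;
   pairwise Sorensen overlap `2V∩/(V_A+V_B)` and centroid Euclidean
   distances in the conventional triangular matrix layout.
4. **Economic impact** — a PERT / Latin-hypercube Monte-Carlo model of
   losses and control benefits (`F1 = Q·I·R·Pa/(1−I·R)`, `F2 = S·I·C`,
   `F3 = Q·I·E·Pa/(1−I·E)` with `E = C·D/(W·Pa·M)`, `F4 = F2+F3`,
   `F5 = F1−F4`), with equal-tailed 95% intervals and Spearman-rank
   sensitivity (tornado) analysis.

A synthetic-data module generates correlated environmental rasters,
presences from a known suitability surface, crop masks and
multivariate-normal niche clouds, so the entire pipeline runs and is
tested without downloading anything. Rasters are lightweight in-memory
grids with a plain-text ESRI ASCII dialect on disk.

All user-facing functions take data frames first and return tibbles;
fitted objects have `tidy()`/`glance()` methods and `autoplot()`
figures.

## Worked example

Simulate a landscape with a known truth, fit and tune the SDM,
classify, overlay a crop mask, and run the economic model:

```r
library(pestrisk)

st <- generate_env_stack(1, 60, 60,
  c(west = 100, east = 130, south = 20, north = 50),
  list(layer_spec("temp_season"), layer_spec("warm_prec"),
       layer_spec("warm_temp", correlation_with = c("temp_season", 0.5))))
truth <- generate_true_suitability(st, intercept = -1,
  linear = c(warm_prec = 2), quadratic = c(temp_season = -1))
occ <- sample_presences(truth, 400, seed = 2) |>
  thin_to_grid(st$layers[[1]])                    # 355 records survive
bg  <- sample_background(st, 2000, seed = 3)

pv <- extract_values(st, occ)
bv <- extract_values(st, bg)
tn <- tune_sdm(pv, bv, rm_grid = c(0.5, 1, 2),
               fc_grid = list(LQ = c("L","Q"), LQH = c("L","Q","H")),
               n_knots = 4)
tn
#> <maxent_tuning> 6 candidate(s); selected fc = LQH, rm = 1 (K = 11, AICc = 5043.36)

variable_contributions(tn$best_model)
#> # A tibble: 3 × 2
#>   variable    contribution
#> 1 warm_prec          81.5
#> 2 temp_season        17.5
#> 3 warm_temp           1.03
```

The model correctly attributes the suitability signal to `warm_prec`
(the linear driver of the truth) and `temp_season` (the quadratic
driver). Classify the predicted map at the minimum training presence
and overlay a 30%-coverage crop mask:

```r
scores <- predict_cloglog(tn$best_model, pv)
cells  <- as_tibble(st)
suit <- st$layers[[1]]
suit$values[cbind(cells$row, cells$col)] <- predict_cloglog(tn$best_model, cells)
cm <- classify_suitability(suit, mtp = mtp_threshold(scores))  # MTP 0.0228
class_areas(cm)
#>   class label      area_1e4_km2
#> 1     0 unsuitable         25.5
#> 2     1 low               502.
#> 3     2 moderate          150.
#> 4     3 high              224.
#> 5    NA total             876.

overlay_crop(cm, generate_crop_mask(st$layers[[1]], 0.3, seed = 4))
#> <crop_overlay> crop area 269.71 x10^4 km^2; 97.2% suitable
```

Run the packaged economic scenario (rice production in the suitable
range of an invasive rice pest in China; 100,000 Latin-hypercube
iterations):

```r
rr <- run_scenario(default_scenario_config(seed = 1))
rr
#> <risk_result> 100000 iterations, seed 1
#>   95% intervals (billion USD):
#>     F1: [5.36, 31.96], midpoint 18.66, mean 15.38
#>     F2: [0.10, 0.82], midpoint 0.46, mean 0.38
#>     F3: [0.26, 2.16], midpoint 1.21, mean 0.99
#>     F4: [0.35, 2.98], midpoint 1.67, mean 1.37
#>     F5: [4.35, 30.14], midpoint 17.25, mean 14.01

rr$sensitivity$F1[1:4, ]
#>   variable     rho  rank
#> 1 R        0.695       1
#> 2 I        0.670       2
#> 3 Pa       0.142       3
#> 4 Q        0.00923     4
```

Read: without control the pest's expected loss to the rice industry is
$5.4–32.0 billion (95% interval), driven chiefly by the yield loss
rate `R` and the damage rate `I`; with control, total costs fall to
$0.35–2.98 billion, for potential savings of $4.4–30.1 billion.
`autoplot(rr)` shows the simulated distributions and
`plot_sensitivity(rr, "F1")` the tornado chart.

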