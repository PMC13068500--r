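# mossar

Quantitative machinery for a recurring montane-biodiversity question:
how do species–area relationships (SARs) change along an elevational
gradient, and how do elevational richness patterns — and the environmental
drivers behind them — shift with the spatial scale of sampling?  The
package grew out of nested-plot moss surveys (56 plots over 1960–3060 m
a.s.l. on Mt Wutai, six nested subplot areas from 0.0001 to 100 m²), but
every stage works on any nested presence/absence survey with plot-level
covariates.

It is aimed at quantitative ecologists who want the full pipeline —
per-plot SAR fits, a mid-domain-effect null model, spatially-aware smooth
trend models, boosted-regression-tree driver analyses, and
scale-dependence regressions — as tested, reusable functions rather than
one-off scripts.

## The models

**Species–area relationship.** Each plot's nested subplots are fitted
with the power law

    S = c · A^z

by nonlinear least squares on the untransformed scale (log–log OLS is a
recorded fallback).  `c` is richness per unit area, `z` the accumulation
exponent; `1/SE` weights carry fit uncertainty into downstream models.

**Mid-domain effect (MDE).** The plots, ordered by elevation, form a
discrete domain of D bands.  Each species observed at a scale contributes
one interpolated range.  The null model keeps the multiset of range sizes
fixed (sampling without replacement) and places each range of size *r*
uniformly over its D − r + 1 feasible positions; Monte Carlo means and
95% CIs per band give the MDE predictor.  `brute_force_mde()` is the
exact closed-form oracle.

**Trends.** Penalized cubic regression splines of each response on
elevation (Gaussian family, basis dimension k = 5, GCV smoothing), with a
Moran's *I* permutation test (k = 5 nearest neighbours, row-standardized
weights, 999 permutations) on the residuals and a documented three-model
decision rule for handling spatial structure.

**Drivers.** Forward-stagewise boosted regression trees (squared-error
loss, bagged subsampling, 10-fold CV tree selection over a 360-point
meta-parameter grid), with permutation-based conditional variable
importance normalized to percentages summing to 100, partial dependence,
Friedman-H-style pairwise interactions, residual spatial checks, and
drop-one / 5%-noise sensitivity analyses.  Importance scores and model R²
are then regressed on log10 area to quantify scale dependence.

A synthetic-data generator with known ground truth (planted c(elev) and
z(elev) surfaces, species elevational ranges, coarse-raster covariates)
makes the whole pipeline testable end to end.

## Worked example

```r
library(mossar)

plots <- generate_environment(n_plots = 56, seed = 42)   # 1960-3060 m transect
truth <- synthetic_truth(seed = 42)                      # c-hump at 2400 m, z: 0.05->0.20
occ   <- generate_community(plots, truth, seed = 42)     # six nested matrices

sar <- fit_all_plots(occ, plots)
head(sar[, c("plot_id", "elevation", "c", "z", "se_z", "r2")], 3)
#>   plot_id elevation        c            z         se_z        r2
#> 1     P01      1960 2.247538 6.891139e-02 1.281961e-02 0.9021383
#> 2     P02      1980 2.698553 9.139903e-02 3.465357e-02 0.6508496
#> 3     P03      2000 3.000000 8.193043e-20 2.220446e-16 1.0000000

g <- fit_elevation_gam(sar$c, sar$elevation, weights = 1/sar$se_c)
#> c-value trend: R2 = 0.69, p(smooth) = 0, peak = 2383 m (strong)

mde <- simulate_mde(extract_ranges(occ[["1"]], plots), n_sims = 20000, seed = 1)
#> MDE expectation at 1 m2: 1.92 (low band) .. 35.09 (mid band)

X <- as.data.frame(plots)[, predictor_names()]
X$MDE <- mde$expected[match(plots$plot_id, mde$plot_id)]
m <- tune_brt(X, as.numeric(richness_by_scale(occ[["1"]])),
              grid = default_brt_grid(reduced = TRUE),
              max_trees = 2000, strata = plots$elevation, seed = 1)
#> BRT (1 m2 richness): tc=1 lr=0.005 bag=0.50, 500 trees, CV r=0.58, R2=0.50

conditional_importance(m, X, as.numeric(richness_by_scale(occ[["1"]])), seed = 1)
#>  predictor        ri
#>        NPP 56.305339
#>        MDE 31.017207
#>         HD  7.393199
#>       Bio1  2.158368
```

The per-plot `z` recover the planted increase with elevation (plot P03's
flat accumulation curve is fitted as z = 0 and flagged); the weighted GAM
localizes the planted c-hump near 2400 m; the MDE null predicts the
classic mid-domain peak; and the BRT importance (summing to 100) picks up
the productivity covariate and the MDE predictor.  With `run_all()` the
same stages run as one pipeline and write tidy CSVs plus a JSON metadata
sidecar; `mossar_cli()` exposes `simulate` and `run` subcommands.

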