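# sivcmscreen

Variable selection for single-index varying coefficient models (SIVCMs) of
spatiotemporal environmental covariates, with the downstream screening
pipeline used in fisheries-environment studies: which environmental
variables predict groundfish catch rates and weights, and whether the
year-to-year pattern of selected variables tracks North Pacific climate
indices.

## The model

The SIVCM is

```
y_i = Σ_{j=0}^{p} g_j(θᵀZ_i) x_{ij} + ε_i ,   x_{0i} ≡ 1,
```

where `Z = (longitude, latitude, year)` is collapsed into a scalar index by
an unknown unit direction `θ` (first component positive, for
identifiability), and each regression coefficient `g_j(·)` is an unknown
smooth function of that index. Setting `X` to lagged seasonal amplitudes of
environmental variables lets every covariate effect vary smoothly over
space and time.

Estimation and selection follow the least-squares spline + group-LASSO
(LSSGLASSO) procedure:

1. expand each `g_j` in a cubic B-spline basis with eight interior knots
   (basis dimension L = 12) on the index values;
2. estimate the spline coefficient blocks by penalized least squares with a
   group-LASSO penalty `λ Σ_{j≥1} √L ‖γ_j‖₂`, zeroing whole coefficient
   functions (the intercept function is never penalized), alternating with
   damped Gauss–Newton updates of `θ`;
3. tune `λ` by a BIC-type criterion `n log(RSS/n) + L(|S|+1) log n` over a
   50-point path from `λ_max`;
4. re-estimate the selected coefficient functions by local linear kernel
   regression (the spline expansion is only used for selection).

Around the estimator the package provides the full pipeline: inverse-
distance-weighted interpolation of monthly station series to survey
locations, summer-minus-winter (physical) and fall-minus-spring
(chemical/biological) seasonal amplitudes, species-specific lags (5 years;
10 for Pacific halibut), VIF backward elimination of collinear candidates,
per-year and all-years selection matrices, logistic likelihood-ratio
screening of selection patterns against climate-index amplitudes with
Benjamini–Hochberg FDR control, and a three-smooth Gaussian additive model
of responses on PDO/MEI/NPGO amplitudes. A synthetic-data module generates
every input with known ground truth.

## Worked example

```r
library(sivcmscreen)

# synthetic SIVCM study: 10 candidate variables, 3 carry signal
truth <- sivcm_truth(p = 10, nonzero = 1:3, n = 400, snr = 5, seed = 1)
dat <- gen_sivcm_data(truth)
fit <- lssglasso_fit(dat$y, dat$X, dat$Z)
print(fit)
#> Single-index varying coefficient model (LSSGLASSO)
#>   n = 400, candidate variables = 10
#>   index direction: (0.9247, -0.3635, -0.1126)
#>   lambda* = 0.0049105 (BIC = -409.29), RSS = 70.0532
#>   selected: x1, x2, x3
direction_angle(fit$theta, truth$theta_true)
#> 1.57   # degrees off the generating direction
```

The fit recovers exactly the three signal-bearing variables and comes
within two degrees of the generating index direction at signal-to-noise 5.
The `refit` element holds the local-linear estimates of each selected
coefficient function on a grid of index values.

Screening a per-year selection series against a climate amplitude:

```r
amps <- setNames(rnorm(29), 1985:2013)
series <- gen_selection_series(list(beta0 = -0.5, beta_k = 2,
                                    years = 1985:2013), amps, seed = 2)
screen <- logistic_lrt(series$selected, series$amplitude)
#> LRT = 8.24 on 1 df, p = 0.0041
```

The end-to-end file pipeline (simulate → preprocess → select → associate)
runs from R via `run_pipeline(pipeline_config(seed = 1), "out/")` or from a
shell via `inst/scripts/sivcm-screen.R`; every stage writes tab-delimited
outputs plus a provenance manifest, and a seeded run is byte-identical when
repeated.

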