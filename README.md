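# sisar

Spatial lag (SAR) models assume one autocorrelation coefficient for
every spatial unit. In many applied settings — pollution diffusion
across city networks, regional economic spillovers — the strength of
dependence varies across space, and a homogeneous fit pushes the
unmodelled heterogeneity into the regression coefficients and the error
variance. `sisar` fits a **single-index varying-coefficient spatial
autoregressive model**,

    y_i = g(u_i' alpha) * sum_j w_ij y_j + x_i' beta + eps_i,
    ||alpha|| = 1,  alpha_1 >= 0,  eps_i ~ N(0, sigma^2),

in which the autocorrelation strength is an unknown smooth function
`g` of a scalar index of unit-level characteristics `u_i` (typically
coordinates). `g` is approximated by a cubic truncated power spline on
order-statistic knots; the index direction is estimated by a
grid-initialized trust-region search on the profiled least-squares
surface; and, because the spatial lag `WY` is endogenous, the spline
and regression coefficients are estimated by two-stage least squares
with the instrument block `[X, WX, W^2X, WU, W^2U]`.

The package is written tidyverse-style — data frames in, tibbles out,
`tidy()`/`glance()` methods and `autoplot()` for every result type —
and also ships:

* spatial weight constructors (rook, bishop, group-interaction,
  k-nearest-neighbour, inverse distance, random) with Matrix Market and
  GAL file I/O,
* a seeded simulator for the model's data-generating process on square
  grids and irregular disks,
* a homogeneous-SAR baseline (QML and IV) and a misspecification
  experiment showing how it fails on heterogeneous dependence,
* spatial diagnostics: Moran's I with 999-permutation inference, Moran
  scatter quadrants, LM-Lag / LM-Error score tests,
* a Monte Carlo driver reporting mean, S.E., bias and MSE per
  parameter,
* a command-line interface (`system.file("cli", "sisar", package =
  "sisar")`) with subcommands `weights`, `simulate`, `fit`, `sar`,
  `diagnose`, `mc`.

## A worked example

```r
library(sisar)

design <- sim_design()              # 15 x 15 grid, n = 225, rook weights,
                                    # alpha = (1/2, sqrt(3)/2), beta = (1, 2),
                                    # g = sin, sigma^2 = 1
sim <- simulate_sisar(design, seed = 1)

fit <- sisar(sim)
fit
#> Single-index varying-coefficient spatial lag model
#>   n = 225, converged after 2 outer iteration(s)
#>   alpha: 0.5145, 0.8575
#>   beta:  x1 = 0.8710, x2 = 2.0118
#>   sigma^2 = 0.8954, fitted g range [-1.630, 2.024]
```

On this draw the index direction (truth `(0.5, 0.866)`) is recovered to
two decimals and the regression coefficients are close to `(1, 2)`;
`sigma^2` estimates the unit error variance. `autoplot(fit)` plots the
fitted `g` against the index, which traces the sine used to generate
the data. The homogeneous baseline on the same draw lands on a
compromise:

```r
tidy(fit_sar(sim))
#> # A tibble: 3 × 2
#>   term  estimate
#> 1 rho      0.343
#> 2 x1       0.998
#> 3 x2       2.72
```

and the dependence diagnostic confirms strong positive autocorrelation
(smallest attainable permutation p-value):

```r
tidy(moran_permutation(sim$data$y, sim$W, seed = 1))
#> # A tibble: 1 × 7
#>   moran_i expected_i variance     z p_value n_perm alternative
#> 1   0.245   -0.00446  0.00237  5.12   0.001    999 greater
```

A replication study of the estimator (this is the package's reference
experiment; ~100 fits take about ten seconds):

```r
mc <- run_experiment(design, estimator = "sisar", nmc = 100, base_seed = 1)
tidy(mc)     # per-parameter mean, S.E., bias, MSE
autoplot(mc) # histograms of the replicated estimates
```

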