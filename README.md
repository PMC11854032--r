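# nlwdist

Parametric lifetime modeling with the **new Lomax-G family** and its
flagship member, the **new Lomax–Weibull (NLW) distribution** — for
reliability engineers, biostatisticians and anyone fitting flexible
hazard shapes to univariate failure-time data.

The family composes a baseline distribution G with the exponentiated
reciprocal hazard (Mills ratio) of the Lomax distribution,
m^c(x) = ((x+λ)/θ)^c, giving F(x) = G(m^c(x)). With a Weibull baseline
this yields the five-parameter NLW law

    F(x) = 1 − exp{ −α ((x+λ)/θ)^(cβ) },   x ≥ −λ,
    h(x) = (αβc/θ) ((x+λ)/θ)^(cβ−1),

whose density covers symmetric, skewed and inverted-J shapes and whose
hazard is increasing, constant or decreasing as cβ ⋛ 1. Only the triple
(λ, k = cβ, s = α/θ^k) is identifiable — the package is built around
that fact (see the methods vignette in `vignettes/nlw-methods.Rmd`).

The package provides:

* `dnlw`, `pnlw`, `qnlw`, `rnlw`, `snlw`, `hnlw`, `nlw_median` — the
  full distribution toolkit, log-space stable, with inverse-transform
  sampling; `pnlg`/`dnlg` for the general family over any
  `nlg_baseline()`;
* moments, MGF/CF, probability-weighted moments, order-statistic
  densities, Rényi and Shannon entropies, quantile skewness/kurtosis
  (`nlw_moment`, `nlw_pwm`, `nlw_renyi`, ...), quadrature-first with the
  printed series as cross-checks;
* five estimators behind `nlw_fit()`: maximum likelihood (analytic
  score), percentile, least squares, weighted least squares and
  Cramér–von Mises minimum distance;
* a Monte Carlo harness (`nlw_scenario()`, `run_scenario()`) for
  bias/MSE comparison of the estimators on the four standard parameter
  sets;
* a goodness-of-fit engine (`gof_report()`): −ℓ, AIC, BIC, CAIC, HQIC,
  K-S with asymptotic p-value, Anderson–Darling, and the Lomax, TWPL,
  OILW and EGMW competitors;
* four classical datasets (`load_dataset()`): 84 aircraft-windshield
  failure times, 63 carbon-fibre gauge lengths, 63 strength values, 48
  student grades;
* a CLI (`inst/cli/nlw-cli.R` / `nlw_cli()`) with `fit`, `gof`,
  `simulate` and `dist` commands.

## Worked example

Evaluate the NLW at published estimates on the windshield failure
times, compare with a Lomax fit, and refit by maximum likelihood:

```r
library(nlwdist)
x <- load_dataset("failure_times")

gof_report(x, models = c("nlw", "lomax"),
           params = list(nlw = c(0.0636, 0.6008, 1.4638, 1.5414, 2.0284)),
           seed = 1)
#>   model negloglik   AIC   BIC  CAIC  HQIC      KS KS_pvalue      AD k  n converged
#> 1   nlw     127.5 265.0 277.1 265.7 269.8 0.08304 6.086e-01  0.5198 5 84      TRUE
#> 2 lomax     162.9 329.8 334.6 329.9 331.7 0.30280 4.084e-07 11.5422 2 84      TRUE
```

The NLW dominates the Lomax on every criterion: 70 points of AIC, a
K-S statistic of 0.083 (p = 0.61, no evidence against the fit) versus
0.303 (p ≈ 4e-7). Refitting instead of fixing the parameters:

```r
nlw_fit(x, method = "mle", n_starts = 8, seed = 1)
#> NLW fit (MLE), n = 84
#>              alpha lambda   theta    beta       c
#> estimate  884.1389 0.6038 30.8906  1.2929  2.4210
#> se          0.1076 0.5715  9.6373  9.7508 18.2625
#> ci_length   0.4219 2.2403 37.7776 38.2226 71.5876
#> objective: 127.4758 (negative log-likelihood)
#> converged: TRUE
#> note: Hessian rank-deficient (1 flat ridge direction(s)); pseudo-inverse used
#> identifiable: lambda = 0.6038  k = 3.13  s = 0.0192
```

This is the identifiability ridge in action: the raw parameters look
nothing like the fixed ones above, yet the negative log-likelihood
(127.4758) and the identifiable triple (λ ≈ 0.60, k ≈ 3.13, s ≈ 0.019)
are the same — both points describe the identical distribution. Read
fits through `$functionals`, not raw coefficients.

Distributional summaries come from the parameter object:

```r
p <- nlw_params(alpha = 1.9, beta = 1.2, lambda = 0.07, theta = 2.5, c = 1.9)
nlw_mean_variance(p)
#>      mean  variance
#> 1.6012104 0.6031426
nlw_shannon(p)
#> [1] 1.134651
```

The same analyses from a shell:

```sh
Rscript inst/cli/nlw-cli.R gof --dataset failure_times --models nlw \
    --params 0.0636,0.6008,1.4638,1.5414,2.0284 --out report.csv
Rscript inst/cli/nlw-cli.R simulate --set II --n 20,100 --reps 50 \
    --methods mle,wls --seed 7 --out sim.csv
```

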