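---
title: "The new Lomax-Weibull distribution: model, estimation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The new Lomax-Weibull distribution: model, estimation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlwdist)
```

## The model

Lifetime data in reliability, engineering and biostatistics routinely
defeat the classical two-parameter families: empirical densities can be
symmetric, left- or right-skewed or inverted-J, and hazards can rise,
fall, or bend in either direction. One productive way to build richer
families is to push a baseline distribution $G$ through a monotone
transform derived from another distribution's hazard structure. This
package implements the family obtained from the *exponentiated
reciprocal hazard* of the Lomax (Pareto II) distribution. The Lomax
hazard is $\theta/(x+\lambda)$, so its reciprocal — its Mills ratio — is
$m(x) = (x+\lambda)/\theta$, and raising it to a power $c > 0$ gives the
transform

$$W(x) = m^c(x) = \left(\frac{x+\lambda}{\theta}\right)^{c}.$$

The family member generated from baseline CDF $G$ is $F(x) = G(W(x))$
with density $f(x) = W'(x)\, g(W(x))$. In code this is
`pnlg()`/`dnlg()` over an `nlg_baseline()` contract — a paired,
validated CDF/PDF; no symbolic differentiation is attempted. Only the
baselines the package itself needs are shipped (Weibull, uniform,
exponential): the family constructor is the extension point, not a
catalogue.

With a Weibull baseline $G(t) = 1 - e^{-\alpha t^{\beta}}$ the family
yields the **new Lomax–Weibull (NLW)** distribution:

$$F_{\mathrm{NLW}}(x) = 1 - \exp\left\{-\alpha
  \left(\frac{x+\lambda}{\theta}\right)^{c\beta}\right\},
  \qquad x \ge -\lambda,$$

with hazard $h(x) = (\alpha\beta c/\theta)\,((x+\lambda)/\theta)^{c\beta-1}$:
increasing for $c\beta > 1$, constant for $c\beta = 1$, decreasing (from
an infinite density at the support endpoint) for $c\beta < 1$. Setting
$(\alpha,\beta,c) = (\tfrac12, 2, 1)$ gives a Rayleigh law in
$(x+\lambda)/\theta$; $\beta = c = \theta = 1$ an exponential in
$x+\lambda$; $c = \theta = 1$ a Weibull in $x+\lambda$. These reductions
are pinned down by tests.

### Support convention

The family's support is taken as $[-\lambda,\infty)$ uniformly, which is
what the NLW quantile function implies and what fitted location
parameters demand (real-data fits can and do produce negative
$\hat\lambda$). Below the support, `pnlw()` and `dnlw()` return 0 rather
than erroring, so empirical-CDF comparisons on shifted data never crash.
At $x = -\lambda$ exactly, the density is $+\infty$ when $c\beta < 1$
(returned as `Inf`), finite when $c\beta = 1$, and 0 when $c\beta > 1$;
likelihood code guards against observations landing exactly on the
estimated endpoint.

### Identifiability

Writing $k = c\beta$ and $s = \alpha/\theta^{k}$,

$$F(x) = 1 - \exp\{-s\,(x+\lambda)^{k}\}:$$

the five raw parameters enter only through the triple $(\lambda, k, s)$.
The model is a three-parameter location–power–rate Weibull wearing five
coats. Consequences drawn throughout the package:

* `nlw_functionals()` extracts $(\lambda, k, s)$, and every fit object
  carries it alongside the raw estimates;
* raw parameter estimates are one point on a ridge of equal fit —
  different optimizers, starts, or machines may land elsewhere on the
  ridge with identical likelihood. Reproducing a published *likelihood*
  is meaningful; reproducing published raw parameter values is not, and
  the package's acceptance checks are anchored accordingly;
* maximum-likelihood standard errors invert the Hessian by Moore–Penrose
  pseudo-inverse and flag rank-deficiency (`se_note`) instead of
  reporting spuriously finite uncertainties along flat directions;
* the Monte Carlo harness aggregates bias and MSE both for raw
  parameters (for comparability with published tables) and for the
  identifiable triple (where consistency statements are actually
  well-posed).

## Numerical policy for moments and entropies

All expectations use adaptive quadrature after the substitution
$w = \alpha((x+\lambda)/\theta)^{c\beta}$, under which $w \sim
\mathrm{Exp}(1)$ and $x(w) = \theta (w/\alpha)^{1/c\beta} - \lambda$.
This removes the endpoint singularity and makes every integrand
light-tailed regardless of parameters. Integrands combining an
exponential factor with the weight (MGF, Rényi) are evaluated as a
single `exp()` of the combined exponent so neither factor overflows
alone.

The distribution's printed series representations (raw moments, PWMs)
expand $(1+x/\lambda)^{c\beta-1}$ binomially and are retained as
secondary, truncation-controlled cross-checks (`method = "series"`).
Two caveats, both established empirically during development and
reflected in the tests:

* the expansion converges only when the distribution is concentrated
  well inside $|x| < \lambda$;
* even there, the inner alternating binomial sums cancel
  catastrophically in double precision once the outer index grows
  (terms of order $10^{17}$ summing to order 1), so achievable accuracy
  is a few significant digits, not machine precision.

Terms are computed in log space with explicit sign tracking, and a
Cauchy criterion on successive partial sums raises an error instead of
returning a silently wrong value. Quadrature is authoritative wherever
the two paths disagree.

The Rényi entropy's closed form was re-derived from the same
substitution,

$$\mathrm{RE}(u) = \frac{1}{1-u}\left[u\log\frac{\alpha\beta c}{\theta}
 + \log\frac{\theta}{c\beta} - k_u \log(u\alpha)
 + \log\Gamma(k_u)\right],
 \qquad k_u = \frac{uc\beta - u + 1}{c\beta},$$

and validated against direct quadrature of $\int f^u$ before being made
the default; it requires $k_u > 0$, otherwise the integral diverges and
the function says so. The Shannon entropy's quadrature path is the
default, with the closed form
$-\log(\alpha\beta c/\theta) + (c\beta-1)(\gamma_E + \log\alpha)/c\beta + 1$
available as a cross-check ($\gamma_E$ the Euler–Mascheroni constant).

Order-statistic densities use the standard normalization
$n!/((r-1)!\,(n-r)!)\,F^{r-1}(1-F)^{n-r}f$; the quantile-based shape
measures default to the model's published half-spread denominator
$x_{0.75}-x_{0.5}$ with `standard = TRUE` switching to the conventional
Galton/Moors coefficients, so figures are reproducible either way.

The MGF exists for all $t \le 0$; for $t > 0$ it requires $c\beta > 1$,
or in the boundary case $c\beta = 1$ (exponential-type tail)
$t < \alpha/\theta$. Requests outside this region are errors, not
numbers.

## Estimation

Five estimators are implemented behind one interface, `nlw_fit(x,
method = ...)`:

| method | objective |
|---|---|
| `mle` | $-\ell$, with $\ell = n\log\frac{\alpha\beta c}{\theta} + (c\beta-1)\sum_i \log y_i - \alpha \sum_i y_i^{c\beta}$, $y_i = \frac{x_i+\lambda}{\theta}$ |
| `pe` | $\sum_i (x_{(i)} - Q(\tfrac{i}{n+1}))^2$ |
| `lse` | $\sum_i (F(x_{(i)}) - \tfrac{i}{n+1})^2$ |
| `wls` | as `lse`, weights $\frac{(n+1)^2(n+2)}{i\,(n-i+1)}$ |
| `cvm` | $\frac{1}{12n} + \sum_i (F(x_{(i)}) - \tfrac{2i-1}{2n})^2$ |

The score was derived by differentiating the log-likelihood directly
(the package's test suite arbitrates it against central finite
differences at $10^{-5}$ relative tolerance); the $\alpha$ component has
the closed-form root $\hat\alpha = n / \sum y_i^{c\beta}$, which the
tests also pin.

Design choices a user should know:

* **Constraints by reparameterization, not penalties.** Optimization
  runs in logs of the positive parameters and
  $\lambda = -\min(x) + e^{\eta}$, so the box never binds and gradient
  methods stay usable. Ties in the data are allowed; plotting positions
  use stable sorting by original index.
* **Initialization is data-driven, never the truth.**
  $\lambda_0 = -\min(x) + 0.1\,\mathrm{IQR}$; the product $k_0 = c_0\beta_0$
  and the scale come from a Weibull probability-plot regression of the
  shifted sample, with the split $c_0 = \beta_0 = \sqrt{k_0}$ arbitrary
  by construction (only the product is identified); `n_starts - 1`
  seeded random perturbations are added. The same defaults are used
  inside the simulation harness so recovery studies are not
  trivialized.
* **Optimizers.** Maximum likelihood: BFGS with the analytic gradient,
  then a Nelder–Mead polish; distance criteria: restarted Nelder–Mead.
  Inadmissible parameter vectors return `+Inf` so the optimizer
  retreats. All-starts failure returns a flagged non-convergent result,
  never an exception — degenerate inputs (e.g. a constant sample, whose
  likelihood is unbounded) end in a flag, not a crash.
* **Uncertainty.** 95% interval lengths are $2 \times 1.96 \times
  \mathrm{SE}$ with SEs from the pseudo-inverted numerical Hessian (see
  identifiability above).

A practical note on the distance estimators: their $\hat\lambda$ often
sits near the boundary $-\min(x)$. This is the usual threshold-parameter
behaviour of location-shifted Weibull-type models; since
$\min(x) \to -\lambda$, the estimator remains consistent, but its
small-sample bias in $\lambda$ is visible in the simulation output.

## The simulation harness

`nlw_scenario()` + `run_scenario()` reproduce the standard
estimator-comparison design: four truth vectors —

* Set I: $(\alpha,\lambda,\theta,\beta,c) = (1.65, 0.055, 0.59, 1.98, 2.5)$
* Set II: $(1.9, 0.07, 2.5, 1.2, 1.9)$
* Set III: $(1.4, 0.117, 1.27, 1.2, 1.45)$
* Set IV: $(26.4, 11.7, 12.77, 15.2, 33.45)$

— sample sizes $\{20, 50, 100, 200, 300, 500\}$ and, in the full
design, 1000 repetitions of inverse-transform sampling through the
closed-form quantile function. Replicates are fitted with each
requested method; failures are counted and excluded from aggregates.
Bias and MSE are averaged **over Monte Carlo replicates** — the
formulas' "$n$" is read as the replicate count, since dividing by the
sample size would make tabulated cells dimensionally incoherent — and a
median squared error column is kept alongside, being far more robust to
the occasional wild small-$n$ fit. Everything is deterministic given
the scenario seed.

`reps` is configurable because the full 1000-replicate design is a
batch job, not a desk check. The package's own acceptance suite runs a
scaled design — 200 replicates, Sets I–II, $n \in \{20, 100, 500\}$ —
and checks the qualitative conclusions that survive scaling: the
identifiable functionals' $|$bias$|$ falls monotonically in $n$ for ML
and WLS, and ML/WLS beat PE/LSE/CVM in median squared error of $s$ at
$n = 500$ (Set II). Cell-by-cell replication of published raw-parameter
tables is deliberately out of scope: those cells depend on optimizer
details and on where each fit lands on the identifiability ridge.

### What the generator does and does not emulate

The generator *is* the model: i.i.d. draws from the NLW by inversion.
It reproduces exactly the conditions of the published design — no
censoring, no measurement rounding, no covariates, no model
misspecification. Passing recovery tests therefore demonstrates
internal consistency of estimator + sampler, not robustness on real
data, where all four of those complications are present (the packaged
datasets, for instance, are recorded to 3–4 digits and the grades data
are integers).

## Goodness of fit

`gof_report()` compares models on one dataset by $-\ell$, AIC
($2k - 2\ell$), BIC ($k\log n - 2\ell$), CAIC — implemented as the
small-sample corrected AIC, $\mathrm{AIC} + 2k(k+1)/(n-k-1)$ — and HQIC
($2k\log\log n - 2\ell$), plus the one-sample two-sided
Kolmogorov–Smirnov statistic with asymptotic Kolmogorov p-value
(plug-in parameters, no Lilliefors correction) and the plug-in
Anderson–Darling statistic without small-sample modification. These are
exactly the conventions that reproduce the published comparison tables
for this model; the CAIC and HQIC forms were fixed by reverse-engineering
that arithmetic, since several inequivalent definitions circulate under
those names. Degenerate CDF values in the A-D sum are clipped to
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-12}$ — kept
safely above machine epsilon so the upper clip actually bites — with a
warning.

Competing models: Lomax (exact), and one documented parse each of the
truncated Weibull power Lomax, odd Lomax inverse Weibull and
exponentiated generalized modified Weibull families, whose published
formulas are typographically flattened; their fitted rows are offered
as-is and deliberately excluded from the package's acceptance checks.
The Lomax likelihood on increasing-hazard data is nearly flat along its
exponential limit ($\theta \to \infty$, $\lambda/\theta \to \bar x$),
so its fitter walks multistarts along that ridge; the attained optimum
is stable even though the fitted $(\theta, \lambda)$ pair is essentially
arbitrary along it.

Fixed-parameter evaluation (`params =` in `gof_report()`, `--params` in
the CLI) reproduces published rows from published estimates without
refitting; refitting is available but may land elsewhere on the NLW
ridge with equal likelihood.

## Problem sizes used by the checks

The test suite and acceptance script choose sizes that make each check
informative at desk scale: sampling-oracle comparisons use $2\times10^5$
draws (three-standard-error bands), recovery checks $n$ between 500 and
2000, the estimator-comparison study 200 replicates, and the K-S
large-sample check 5000 draws against the 1% critical value. The
published 1000-replicate, six-sample-size design remains available
through `nlw_scenario()` defaults.

## Known limitations

* No censoring, truncation, covariates or Bayesian machinery — the
  likelihood is for complete i.i.d. samples.
* The series representations are cross-checks, not workhorses; treat
  `method = "series"` as a diagnostic of the printed expansions.
* Raw-parameter standard errors on ridge-afflicted fits are
  pseudo-inverse artifacts along the flat directions; read the
  identifiable triple instead.
* The three non-Lomax competitor families implement one reading of
  ambiguous printed formulas; their absolute fit values should be used
  with that caveat.
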