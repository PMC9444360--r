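# lomaxshape

Shape-parameter estimation for the Lomax (Pareto type II) distribution with
known scale, for statisticians and reliability/biostatistics practitioners
comparing classical and Bayesian point estimators on heavy-tailed
failure-time data.

The Lomax law has density and survival function

    f(x) = (ϑ/δ)(1 + x/δ)^-(ϑ+1),    R(t) = (1 + t/δ)^-ϑ,    x, t ≥ 0,

with shape ϑ > 0 (the tail index, the estimation target) and known scale
δ > 0. All likelihood-based inference runs through the complete sufficient
statistic T = Σ log(1 + xᵢ/δ), which is Gamma(n, rate ϑ).

The package provides:

* **Distribution primitives** — `dlomax`, `plomax`, `slomax`, `qlomax`,
  `rlomax` (inverse-CDF sampling via x = δ[(1−U)^(−1/ϑ) − 1]), and
  `lomax_suffstat`.
* **Five classical estimators** — MLE `n/T`, UMVUE `(n−1)/T`, ordinary
  least squares and ridge regression on the linearized CDF
  (log(1−F̂ᵢ) regressed on log(δ+x₍ᵢ₎), slope = −ϑ), and a median-based
  estimator log 2 / log(1 + x_med/δ).
* **Twelve Bayes estimators** — four priors (extended Jeffreys,
  chi-squared, inverted Levy, gamma), each conjugate to a Gamma(A, rate B)
  posterior, under squared-error (posterior mean A/B), LINEX
  ((A/a)·log(1+a/B)) and composite-LINEX ((A/2a)·log((B+a)/(B−a))) losses.
* **An exact risk oracle** — `risk_closed_form` (MSE of the MLE is
  ϑ²(n+2)/((n−1)(n−2)), of the UMVUE ϑ²/(n−2)) and `risk_quadrature` for
  every estimator that is a function of T.
* **A Monte Carlo study engine** — `study_design` / `run_study` /
  `write_mse_tables` compare all estimators by mean squared error over a
  grid of true shapes and sample sizes.

A thin command-line front end is installed as `exec/lomaxtool`
(subcommands `estimate`, `estimate-bayes`, `oracle`, `study`).

## Worked example

```r
library(lomaxshape)
set.seed(42)
x <- rlomax(40, shape = 2, scale = 2)   # failure times, true shape 2
s <- lomax_suffstat(x, scale = 2)
s
#> Lomax sufficient statistic: n = 40, T = 26.3082

est_mle(s); est_umvue(s)                   # 1.5204, 1.4824
est_ols(x, 2); est_ridge(x, 2, lambda = 0.75)  # 1.6481, 1.5541
est_median(x, 2)                           # 1.3223

post <- lomax_posterior(lomax_prior("gamma", k = 0.6, d = 0.2), s)
post
#> Gamma posterior: shape A = 40.6, rate B = 26.5082 (mean 1.5316)
bayes_self(post)                           # 1.5316  (posterior mean)
bayes_linex(post, a = 1.5)                 # 1.4898  (asymmetric, shrinks down)
bayes_clinex(post, a = 1.5)                # 1.5332  (symmetrized, sits above)

risk_closed_form("umvue", n = 40, shape = 2)
#> 0.1053   # exact MSE of the UMVUE under these conditions
```

This particular sample is light in the tail, so every estimator lands below
the true shape 2; the exact-risk line says the UMVUE's typical squared error
at n = 40 is about 0.105, i.e. deviations of ±0.32 are ordinary.

The full estimator comparison (three true-shape cases × five sample sizes ×
33 estimator columns, 10,000 replicates each) runs in seconds:

```r
tab <- run_study(study_design(seed = 1))
write_mse_tables(tab, "results")   # per-prior CSVs + a Markdown report
```

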