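# msldiff

Inference and first-passage-time analysis for the **multisigmoidal
logistic lognormal diffusion** — a stochastic growth model for
populations that saturate only after several distinct growth stages
(multi-wave epidemics, staged fruit growth, software fault counts).

## The model

The deterministic skeleton is the logistic curve with a polynomial
exponent,

```
l(t) = l0 (eta + exp(-Q(t0))) / (eta + exp(-Q(t))),
Q(t) = beta_1 t + ... + beta_p t^p,   beta_p > 0,
```

which can have several inflection points before saturating at the
carrying capacity `l0 (eta + exp(-Q(t0))) / eta`. Adding multiplicative
noise gives the Itô diffusion

```
dX(t) = h(t) X(t) dt + sigma X(t) dW(t),
h(t)  = P(t) exp(-Q(t)) / (eta + exp(-Q(t))),   P = Q',
```

whose transition laws are lognormal in closed form. The package
provides:

* exact-transition simulation of sample-path panels (`simulate_paths()`,
  `make_case_panel()`);
* maximum likelihood estimation of `(eta, beta, sigma^2)` from
  longitudinal panels by a damped Newton–Raphson solve of the score
  system (`fit_newton_raphson()`) or by simulated annealing over a
  data-driven bounded parameter space (`fit_simulated_annealing()`);
* Fisher-information and delta-method confidence intervals
  (`asymptotic_ci()`, `delta_method_ci()`, `initial_law_ci()`);
* polynomial-degree selection by AIC/BIC and the resistor-average
  Kullback–Leibler distance (`select_degree()`);
* the first-passage-time density through a constant boundary, via the
  FPTL localisation function and a second-kind Volterra integral
  equation solved by the composite trapezoid rule (`fpt_density()`,
  `fpt_summaries()`).

Everything is tidyverse-shaped: panels are long tibbles
(`path_id, time, value`), fits have `tidy()`/`glance()` methods, result
objects have `autoplot()` methods.

## Worked example

Simulate a 50-path panel from a cubic model, refit it, and compute the
first-passage-time density through the boundary `S = 15`:

```r
library(msldiff)

params <- msl_params(eta = exp(-1), beta = c(0.1, -0.009, 0.0002), sigma2 = 1e-4)
panel  <- make_case_panel(1, n_paths = 50, n_times = 201, seed = 101)

fit <- fit_newton_raphson(panel, p = 3)
tidy(fit, conf.int = TRUE, panel = panel)
#> # A tibble: 7 × 5
#>   term       estimate   std.error   conf.low conf.high
#>   <chr>         <dbl>       <dbl>      <dbl>     <dbl>
#> 1 eta       0.367      0.00478     0.358      0.377
#> 2 beta_1    0.102      0.00102     0.0996     0.104
#> 3 beta_2   -0.00909    0.0000722  -0.00923   -0.00895
#> 4 beta_3    0.000201   0.00000134  0.000199   0.000204
#> 5 sigma2    0.0000977  0.00000138  0.0000950  0.000100
#> 6 mu1       1.61      NA          NA         NA
#> 7 sigma1sq  0         NA          NA         NA
```

The generating values `(0.368, 0.1, -0.009, 0.0002, 1e-4)` are
recovered to within a couple of percent. The first-passage-time density
of the generating process through `S = 15`:

```r
dens <- fpt_density(params, boundary_spec(S = 15, x0 = 5), horizon = 100)
fpt_summaries(dens)
#> # A tibble: 1 × 7
#>    mean    sd  mode   d10   d50   d90 total_mass
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>      <dbl>
#> 1  40.2  1.09  39.9  39.0  40.1  41.6      0.999
```

Read: crossings of the threshold concentrate around t ≈ 40 (mode 39.9),
with 80% of the passage probability between t ≈ 39.0 and t ≈ 41.6, and
99.9% of the total mass captured inside the localised window.

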