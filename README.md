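# hiercdm

Statistical validation of attribute hierarchies in cognitive diagnosis
models (CDMs).

## The problem

CDMs classify examinees into binary attribute mastery patterns
`α ∈ {0,1}^K` from `J` dichotomous item responses, via a Q-matrix that says
which attributes each item measures. Attributes often obey prerequisite
relations — an *attribute hierarchy* — under which some of the `L = 2^K`
patterns are impermissible and their mixing (structural) probabilities
`π_l` are zero. Whether an a-priori hierarchy is supported by data is a
testable hypothesis: in the saturated model, the structural probabilities
of the impermissible patterns should not be significantly larger than
zero.

`hiercdm` implements, for psychometricians and methodologists:

* saturated identity-link **G-DINA** and hierarchy-restricted **HDCM**
  estimation by marginal maximum likelihood EM (`fit_cdm()`);
* **XPD** (empirical cross-product) and **Obs** (observed, i.e. negative
  Hessian) information matrices and the covariance of the free parameters
  (`score_matrix()`, `information_matrix()`, `cdm_vcov()`);
* the constraint-matrix **Wald test**
  `W = (Rπ̂)ᵀ (R Σ̂ππ Rᵀ)⁻¹ (Rπ̂) ~ χ²(m)` with either covariance
  estimator, and the **likelihood-ratio test**
  `LR = 2(ℓ_s − ℓ_r) ~ χ²(Δnpar)` against the restricted fit
  (`wald_hierarchy_test()`, `lr_hierarchy_test()`, `hierarchy_test()`);
* a **simulation layer** for hierarchy-constrained attribute patterns,
  structured Q-matrices, equal-increment item parameters and binary
  responses (`sim_cdm_data()` and friends);
* a **replication harness** measuring empirical Type I error and power of
  the three methods over a factorial design (`run_condition()`,
  `hierarchy_study()`), with Monte Carlo rate intervals (`rate_ci()`) and
  MAP classification accuracy (`classification_accuracy()`).

Results are tibbles or objects with broom-style `tidy()`/`glance()` and
`autoplot()` methods.

## A worked example

Generate responses from an HDCM with a true linear hierarchy
`1 → 2 → 3`, then validate that hierarchy:

```r
library(hiercdm)

h   <- hierarchy_preset("linear", 3)
sim <- sim_cdm_data(N = 500, qmatrix = sim_qmatrix(30, 3, seed = 1),
                    quality = "high", hierarchy = h, seed = 1)
fit <- fit_cdm(sim$responses, sim$qmatrix)
glance(fit)
#> # A tibble: 1 x 8
#>   logLik  npar     n    AIC    BIC iterations converged restricted
#>    <dbl> <int> <int>  <dbl>  <dbl>      <int> <lgl>     <lgl>
#> 1 -6338.   103   500 12882. 13316.         23 TRUE      FALSE

suppressWarnings(hierarchy_test(sim$responses, sim$qmatrix, h))
#> # A tibble: 3 x 5
#>   method   statistic    df p.value reject
#>   <chr>        <dbl> <int>   <dbl> <lgl>
#> 1 Wald-XPD   0.00295     4   1.000 FALSE
#> 2 Wald-Obs   2.19        4   0.701 FALSE
#> 3 LR         2.72       24   1.000 FALSE
```

All three methods fail to reject: the impermissible-pattern probabilities
(here estimated at or near zero) are consistent with the hierarchy that
actually generated the data. Rejection would be evidence *against* the
hierarchy. (The suppressed warnings flag the rank deficiency of the full
information matrix that is inherent to fitting a saturated model to
hierarchy-constrained data; see the vignette.)

A Type I error cell of the replication study:

```r
st <- run_condition(N = 200, hierarchy = h, quality = "high",
                    reps = 100, seed = 7)
tidy(st)[, c("method", "rate", "ci_lower", "ci_upper")]
autoplot(st)
```

The ECPE grammar dataset (2,922 x 28, distributed in the CRAN packages
`CDM`/`GDINA`, not bundled here) is the standard real-data illustration;
`ecpe_qmatrix()` and `ecpe_linear_hierarchy()` provide its published
Q-matrix and the lexical → cohesive → morphosyntactic linear hierarchy, so
`hierarchy_test(ecpe_responses, ecpe_qmatrix(), ecpe_linear_hierarchy())`
reproduces the standard analysis once the responses are supplied.

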