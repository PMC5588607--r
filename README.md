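# rrmi — multiple imputation for relative risk estimation

`rrmi` is a Monte Carlo laboratory for a question that matters to anyone
estimating adjusted relative risks from incomplete epidemiologic data:
**when the binary outcome and an exposure are missing at random, how much
does standard multiple imputation bias the relative risk?**

Relative risks are modelled on the log scale,

    log P(Y = 1 | X1, X2) = b0 + b1*X1 + b2*X2,

with the coefficients `b1`, `b2` interpreted as conditional log relative
risks, fitted by a log binomial GLM (or modified Poisson regression with a
robust HC0 variance when the log link will not converge). The standard
imputation engines, however, model missing binary outcomes with logistic
regression (fully conditional specification, FCS) or as jointly normal
(multivariate normal imputation, MVNI) — both misspecified relative to the
log binomial analysis model. `rrmi` generates data from the analysis model
itself, imposes logistic MAR missingness on `Y` and `X2` driven by the
fully observed `X1`, imputes with from-scratch implementations of FCS and
MVNI (data augmentation with EM starting values and adaptive rounding of
binary variables), optionally deletes imputed outcomes before analysis
("MI, then deletion"), pools with Rubin's rules, and reports bias, average
and empirical standard errors, coverage, and MSE with Monte Carlo
standard errors — for MVNI, MVNI + deletion, FCS, FCS + deletion, and
complete case analysis.

The package is written for biostatisticians who want to reproduce,
stress-test, or extend this evaluation: every scenario knob (prevalence,
effect sizes, exposure association, mechanism shape and strength, sample
size, imputation settings, seeds) is a field of `scenario_spec()`.

## Worked example

The headline scenario: binary exposures with RR(X1, X2) = 2, conditional
relative risks of 3, outcome prevalence 0.30, and a strong coordinated
mechanism (30% of `Y` and `X2` missing, more often for `X1 = 1`):

```r
library(rrmi)

spec <- scenario_spec("binary", prevalence = 0.30, beta1 = log(3), beta2 = log(3),
                      assoc = 2, mechanism = "coordinated", lambda = 2,
                      reps = 50, seed = 2024)
calibrate(spec)[c("beta0", "alpha")]
#> $beta0: -2.6703   $alpha: -2.0544

raw <- run_scenario(spec, methods = c("MVNI", "FCS", "CCA"))
summarize_replicates(raw, c(x1 = log(3), x2 = log(3)))
#> # A tibble: 6 x 7
#>   method term     bias avg_se emp_se coverage    mse
#> 1 CCA    x1     0.0154  0.171  0.180     0.94 0.0320
#> 2 CCA    x2     0.0172  0.212  0.249     0.9  0.0609
#> 3 FCS    x1     0.0433  0.158  0.165     0.94 0.0285
#> 4 FCS    x2    -0.111   0.206  0.233     0.86 0.0657
#> 5 MVNI   x1     0.0422  0.155  0.164     0.92 0.0280
#> 6 MVNI   x2    -0.322   0.174  0.183     0.54 0.137
```

Read the `x2` rows: complete case analysis is nearly unbiased here
(missingness depends only on the fully observed `X1`), FCS attenuates the
log relative risk of the incompletely observed exposure by about 0.11
(RR 2.7 instead of 3), and MVNI attenuates it by about 0.32 — an
estimated RR of 2.2 instead of 3 — with 95% intervals covering the truth
barely half the time. `autoplot()` on the summary draws the bias
comparison; `run_grid(scenario_grid("binary"))` runs all 32 scenarios of
the factorial design. A YAML-driven command-line wrapper lives in
`inst/scripts/rrmi-sim.R`.

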