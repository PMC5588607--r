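---
title: "Evaluating multiple imputation for relative risk estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating multiple imputation for relative risk estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrmi)
```

## The problem

The relative risk (RR) is the preferred effect measure for common binary
outcomes in epidemiology: unlike the odds ratio it is collapsible and
directly interpretable. Adjusted relative risks are usually estimated from a
log binomial model,

$$\log P(Y = 1 \mid X_1, X_2) = \beta_0 + \beta_1 X_1 + \beta_2 X_2,$$

whose coefficients are conditional log relative risks, or — when the
unbounded log link causes non-convergence — from modified Poisson
regression (a Poisson GLM with log link and a robust sandwich variance).

When both the outcome $Y$ and an exposure $X_2$ are missing at random
(MAR), standard multiple imputation (MI) machinery imputes them from models
that are *not* the log binomial analysis model: fully conditional
specification (FCS) uses a logistic model for binary variables, and
multivariate normal imputation (MVNI) assumes joint normality. Both
imputation models are therefore misspecified relative to the analysis
model, and the question this package quantifies is how much that
misspecification biases the pooled relative risk, whether coverage
suffers, and whether deleting imputed outcomes before analysis (MID)
helps. The package is a self-contained Monte Carlo laboratory: a
data-generating module, two imputers written from first principles, the
analysis and pooling layer, and a harness that turns replicates into bias,
standard error, coverage, and mean square error summaries.

## Data-generating model

A scenario (`scenario_spec()`) fixes:

* **Exposures.** Either binary with marginal prevalence 0.50 each and a
  confounding association expressed as a risk ratio
  $RR(X_1, X_2) \in \{2, 3\}$, or bivariate normal with mean 0, variance
  0.20 and correlation $\rho \in \{0.30, 0.70\}$. For the binary case the
  conditional prevalences of $X_2$ solve $p_1/p_0 = RR$ with
  $\tfrac12 p_0 + \tfrac12 p_1 = \tfrac12$, i.e. $p_0 = 1/(1+RR)$,
  $p_1 = RR/(1+RR)$; this is the unique construction that preserves the
  stated 0.50 margins.
* **Outcome.** $Y \sim \text{Bernoulli}(\exp(\beta_0 + \beta_1 X_1 +
  \beta_2 X_2))$ with $\beta_1 = \beta_2 \in \{\log 2, \log 3\}$ (or 0 in
  null cases), and $\beta_0$ calibrated so the marginal prevalence is 0.10
  or 0.30.
* **Missingness.** Logistic MAR mechanisms driven by the fully observed
  $X_1$ (standardised to $Z_1 = X_1/\sqrt{0.20}$ in the continuous case):
  *coordinated* ($\text{logit}\,P(\text{miss}) = \alpha + \lambda s$ for
  both $Y$ and $X_2$) and *opposite* (the $X_2$ equation flips the sign of
  the dependence). Restricted variants (`y_only`, `x2_only`) and MCAR
  ($\lambda = 0$) support the sensitivity analyses. $\alpha$ is calibrated
  to 30% missingness per variable. $\lambda \in \{1, 2\}$ indexes a
  moderate or strong mechanism.

### Calibration

For binary exposures the prevalence is a four-cell sum, so $\beta_0$ has a
closed form. For continuous exposures the linear predictor
$S = \beta_1 X_1 + \beta_2 X_2$ is normal with variance
$v = (\beta_1^2 + \beta_2^2 + 2\rho\beta_1\beta_2)\cdot 0.20$, but rows
with $\exp(\beta_0 + S) > 1$ are redrawn, which truncates the effective
exposure law to $\{S \le -\beta_0\}$. The prevalence of the truncated
model,

$$E\!\left[e^{\beta_0 + S}\,\middle|\,S \le -\beta_0\right]
 = e^{\beta_0 + v/2}\,
 \frac{\Phi\!\big((-\beta_0 - v)/\sqrt{v}\big)}{\Phi\!\big(-\beta_0/\sqrt{v}\big)},$$

is solved for $\beta_0$ by `uniroot` to machine precision. We use this
exact expression rather than Monte Carlo calibration: it is deterministic,
and the test suite verifies it against a large simulated sample. The
missingness intercept solves $E[\text{expit}(\alpha + \lambda s)] =$ 0.30
over the two-point (binary) or standard normal (continuous) law of $s$;
by symmetry the same $\alpha$ calibrates both equations of the opposite
mechanism.

In the most extreme generating cell (prevalence 0.30, conditional RRs
of 3) invalid first-draw success probabilities are not rare: the closed
form above implies 6.65% of draws exceed one at $\rho = 0.70$ and 4.20%
at $\rho = 0.30$ (5.4% pooled over the two correlation settings of that
cell — the scale the acceptance script reports). The generator records
each dataset's first-draw invalid fraction as an attribute.

## The imputers

Both imputers produce `m = 20` completed datasets by default and never
alter observed cells — an invariant the test suite asserts bitwise.

### Fully conditional specification

`fcs_impute()` runs an independent chain per imputation. Missing cells are
first filled by resampling observed values of the same variable (random
fills rather than means, to avoid degenerate first-cycle logistic fits);
then 20 cycles re-impute $X_2$ from $(Y, X_1)$ and $Y$ from $(X_1, X_2)$,
outcome last by default (`order = "outcome_first"` reverses the sweep for
the sensitivity analysis). Each univariate model is refitted to the rows
observed for its response, conditioning on current completed values of the
other variables:

* binary responses: logistic MLE, with the parameter vector drawn from the
  asymptotic normal approximation to its posterior (mean at the MLE,
  covariance the inverse observed information) — the standard device in
  chained-equations software — followed by Bernoulli imputation;
* continuous responses: exact Bayesian linear regression under the
  Jeffreys prior, drawing $\sigma^{2*} = \text{RSS}/\chi^2_{n-p}$, then
  coefficients from $N(\hat\beta, \sigma^{2*}(X'X)^{-1})$, then the
  posterior predictive.

Separation or non-convergence in a univariate fit triggers one retry with
a small ridge added to the information matrix; persistent failure raises a
classed condition and the harness flags (and reports) the replicate
instead of aborting the scenario. At $n = 1000$ and prevalence $\ge 0.10$
this is rare.

### Multivariate normal imputation

`mvni_impute()` treats $(Y, X_1, X_2)$ as jointly normal with binary
variables entering as raw 0/1 values. Starting values come from an EM
algorithm on the sufficient statistics (`em_start()`, converged when the
observed-data log-likelihood moves by less than $10^{-8}$). Data
augmentation then alternates an I-step (each row's missing coordinates
drawn from their conditional normal) and a P-step ($\Sigma$ from its
inverse-Wishart posterior and $\mu \mid \Sigma$ normal, under the Jeffreys
prior). The first imputation is taken after a burn-in of 200 iterations;
subsequent imputations are spaced `between = 100` iterations apart. The
spacing is a package default — chain thinning is rarely reported in
applied work — and a test verifies that consecutive imputations of the
missing cells are essentially uncorrelated (lag-1 correlation below 0.2)
at this spacing. The I/P iteration is implemented in compiled code with
all randomness drawn through R's RNG, so runs are reproducible from
`set.seed()` alone.

Continuously imputed binary cells are rounded back to 0/1: the outcome
always, and $X_2$ too in binary-exposure scenarios (without which the log
binomial analysis routinely fails). The default is *adaptive rounding*:
with $\bar\omega$ the mean of the completed column (computed per imputed
dataset), the threshold is
$c = \bar\omega - \Phi^{-1}(\bar\omega)\sqrt{\bar\omega(1-\bar\omega)}$
and values $\ge c$ become 1; ties round up, and a degenerate
$\bar\omega \notin (0,1)$ yields the constant column. *Simple rounding* at
0.5 is available as a sensitivity option (`rounding = "simple"`).

## Analysis and pooling

Binary-exposure scenarios are analysed with the log binomial model (IRLS,
deviance tolerance $10^{-8}$, 100 iterations, starting at
$(\log\bar y, 0, 0)$); fits reaching the probability boundary or failing
IRLS are declared non-converged and fall back, per completed dataset, to
modified Poisson regression, with the count of fallbacks reported.
Continuous-exposure scenarios always use modified Poisson regression —
log binomial non-convergence is endemic there. The sandwich is plain HC0
($A^{-1}BA^{-1}$); at $n = 1000$ small-sample corrections are immaterial.

Rubin's rules pool the $m$ fits: $\bar Q = \text{mean}$,
$\bar W = \text{mean}(SE^2)$, $B = \text{var}(\text{estimates})$,
$T = \bar W + (1 + 1/m)B$, with large-sample degrees of freedom
$(m-1)\big(1 + \bar W/((1+1/m)B)\big)^2$ (infinite when $B = 0$). The
Barnard–Rubin small-sample adjustment is available through
`pool_rubin(dof_complete = )` but is not the default: at $n = 1000$ and
$m = 20$ the two agree to well past the reported precision. Deletion of
imputed outcomes (`delete_imputed_outcomes()`) removes the imputed-$Y$
rows from every completed dataset while keeping imputed covariate values
in the retained rows; complete case analysis drops every row missing
$Y$ or $X_2$.

## The harness

`run_replicate()` executes the whole pipeline for one dataset and returns
a tidy tibble of per-method estimates and intervals; `run_scenario()`
replicates it with deterministic per-replicate child seeds derived from
one master seed, so any single replicate can be reproduced in isolation;
`run_grid()` iterates a 32-scenario factorial grid built by
`scenario_grid()` or read from YAML (`read_scenario_config()`; a
fully-commented example ships in `inst/extdata/grid-binary.yaml`).
`summarize_replicates()` reduces replicates to bias, average and empirical
standard errors, coverage of nominal 95% intervals, and MSE, each with
Monte Carlo standard errors; failed replicates are excluded and counted.
`autoplot()` and `plot_coverage()` display a summary. A thin command-line
driver (`inst/scripts/rrmi-sim.R`, subcommands `calibrate`, `run`,
`tables`) wraps these functions for shell use.

## Design choices on open points

* **Coordinated mechanism coupling.** The two missingness indicators share
  a per-row probability but are drawn with independent uniforms; this
  makes rows *often*, not always, missing both variables, which is the
  behaviour the mechanism's description implies. A `coupled_masks` switch
  provides perfectly coupled draws for comparison.
* **Invalid-probability resampling** redraws the whole exposure pair for
  offending rows (capped at $10^4$ rounds) rather than truncating
  per-coordinate, and $\beta_0$ is calibrated on the resulting truncated
  law (see above).
* **Rounding reference set.** Adaptive-rounding thresholds use each
  completed dataset's own column; pooling the reference set across
  imputations would couple the chains.
* **Posterior machinery.** Normal approximation at the MLE for logistic
  imputation, Jeffreys priors for the linear and multivariate normal
  models — the standard choices in chained-equations and data-augmentation
  software, adopted because the evaluated procedures are defined by
  common practice rather than by a particular prior.

## What the generator does and does not emulate

The synthetic data match the study conditions exactly: two exposures, a
correctly specified log binomial outcome model, logistic MAR missingness
driven by a fully observed covariate, 30% missingness per variable. Real
epidemiologic data differ in ways that matter: more variables (including
auxiliary predictors of missingness), non-normal continuous exposures,
MNAR mechanisms, and missingness in more than two variables. Passing
results here certify the *methods pipeline* — calibration, imputation,
rounding, pooling, metrics — under the stated conditions; they do not
certify MI performance beyond them. In particular, CCA is nearly unbiased
here only because missingness depends solely on the fully observed $X_1$;
that is a property of the design, used as a pipeline sanity check, not a
general endorsement of complete case analysis.

## Problem sizes and numerical tolerances

Headline simulations use $n = 1000$ rows, $m = 20$ imputations, 20 FCS
cycles, a 200-iteration burn-in, and 2000 replicates per scenario
($n = 250$ available as a sensitivity setting). The test suite and the
acceptance script reproduce the reference results at 200–500 replicates
(2000 for the cheap complete-data checks), comparing against published
values within three Monte Carlo standard errors computed from the
published empirical standard errors; full-replication grids are
reproducible with `run_grid()` at `reps = 2000`. Calibration roots are
found to $10^{-12}$; EM stops at $10^{-8}$ log-likelihood change; IRLS at
$10^{-8}$ relative deviance change. Degenerate inputs (constant outcome,
all-missing columns, fully imputed outcomes, fewer than 10 complete
cases) raise informative errors rather than propagating silently.

## Known limitations

* The imputation model for $X_2$ conditions only on $(Y, X_1)$; no
  auxiliary variables are supported, by design.
* FCS convergence is assessed implicitly through cycle count (20), not by
  chain diagnostics; this mirrors common software defaults.
* Modified Poisson is applied to all completed datasets of a continuous
  scenario, not only the non-converged ones — the simpler and more
  conventional of the two options.
* Only two exposures, binary outcomes, and logistic MAR mechanisms are
  supported; survival and count outcomes, MNAR, inverse probability
  weighting, the general location model, and hot-deck imputation are out
  of scope.
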