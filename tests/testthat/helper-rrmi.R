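# Shared fixtures, all generated in code.

# the headline binary-exposure scenario: coordinated mechanism, outcome
# prevalence 0.30, strong mechanism, RR(X1,X2) = 2, conditional RRs of 3
headline_binary_spec <- function(...) {
  scenario_spec("binary", prevalence = 0.30, beta1 = log(3), beta2 = log(3),
                assoc = 2, mechanism = "coordinated", lambda = 2, ...)
}

# its continuous-exposure analogue (correlation 0.70)
headline_continuous_spec <- function(...) {
  scenario_spec("continuous", prevalence = 0.30, beta1 = log(3), beta2 = log(3),
                assoc = 0.7, mechanism = "coordinated", lambda = 2, ...)
}

# a small incomplete dataset for imputer unit tests
small_mar_data <- function(spec, n = spec$n, seed = 1) {
  calib <- calibrate(spec)
  set.seed(seed)
  complete <- generate_complete(spec, calib$beta0, n = n)
  list(complete = complete,
       data = apply_missingness(complete, spec, calib$alpha),
       calib = calib)
}

# quick fabricated rrmi_fit for pooling tests
fake_fit <- function(est, se, estimator = "log_binomial") {
  structure(
    list(estimates = est, std_errors = se, converged = TRUE,
         estimator = estimator, n_used = 100L),
    class = "rrmi_fit"
  )
}
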