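# Analysis models, fallback routing, MID deletion and Rubin pooling.

test_that("log binomial fits reproduce closed-form risk ratios", {
  # intercept-only: estimate is log of the outcome prevalence
  set.seed(301)
  d0 <- tibble::tibble(y = rbinom(500, 1, 0.3))
  f0 <- fit_log_binomial(d0)
  expect_equal(unname(f0$estimates), log(mean(d0$y)), tolerance = 1e-8)

  # single binary covariate: the saturated model's slope is the sample log
  # risk ratio of the 2x2 table
  d1 <- tibble::tibble(y = rbinom(800, 1, 0.25), x1 = rbinom(800, 1, 0.5))
  f1 <- fit_log_binomial(d1)
  rr <- mean(d1$y[d1$x1 == 1]) / mean(d1$y[d1$x1 == 0])
  expect_equal(unname(f1$estimates["x1"]), log(rr), tolerance = 1e-8)
  expect_true(f1$converged)
  expect_true(all(f1$std_errors > 0))

  # constant outcome: no MLE
  expect_error(fit_log_binomial(tibble::tibble(y = rep(1, 20), x1 = rnorm(20))),
               "constant")
})

test_that("modified Poisson matches closed-form sandwich algebra", {
  # intercept-only: estimate log(ybar), sandwich variance (1 - ybar)/(n ybar)
  set.seed(302)
  d0 <- tibble::tibble(y = rbinom(600, 1, 0.4))
  f0 <- fit_modified_poisson(d0)
  ybar <- mean(d0$y)
  expect_equal(unname(f0$estimates), log(ybar), tolerance = 1e-8)
  expect_equal(unname(f0$std_errors)^2, (1 - ybar) / (600 * ybar),
               tolerance = 1e-8)

  # saturated binary design: point estimates identical to log binomial, and
  # the sandwich variance of the slope equals the delta-method variance of
  # a log risk ratio, (1-p1)/(n1 p1) + (1-p0)/(n0 p0)
  d1 <- tibble::tibble(y = rbinom(800, 1, 0.25), x1 = rbinom(800, 1, 0.5))
  fp <- fit_modified_poisson(d1)
  fl <- fit_log_binomial(d1)
  expect_equal(unname(fp$estimates), unname(fl$estimates), tolerance = 1e-6)
  n1 <- sum(d1$x1 == 1); n0 <- sum(d1$x1 == 0)
  p1 <- mean(d1$y[d1$x1 == 1]); p0 <- mean(d1$y[d1$x1 == 0])
  expect_equal(unname(fp$std_errors["x1"])^2,
               (1 - p1) / (n1 * p1) + (1 - p0) / (n0 * p0), tolerance = 1e-8)
})

test_that("sandwich variance agrees with an independent HC0 implementation", {
  skip_if_not_installed("sandwich")
  set.seed(303)
  d <- tibble::tibble(x1 = rnorm(400), x2 = rbinom(400, 1, 0.5))
  d$y <- rbinom(400, 1, pmin(exp(-1.5 + 0.4 * d$x1 + 0.3 * d$x2), 1))
  f <- fit_modified_poisson(d)
  g <- glm(y ~ x1 + x2, data = d, family = poisson())
  v <- sandwich::vcovHC(g, type = "HC0")
  # agreement at IRLS convergence precision of the two fitting paths
  expect_equal(unname(f$std_errors), unname(sqrt(diag(v))), tolerance = 1e-4)
  expect_equal(unname(f$estimates), unname(coef(g)), tolerance = 1e-6)
})

test_that("analysis-model routing follows the exposure type and convergence", {
  set.seed(304)
  d <- tibble::tibble(x1 = rbinom(500, 1, 0.5), x2 = rbinom(500, 1, 0.5))
  d$y <- rbinom(500, 1, exp(-2 + 0.5 * d$x1 + 0.5 * d$x2))
  # converged log binomial fit is returned unchanged in binary scenarios
  expect_identical(choose_analysis(d, "binary")$estimator, "log_binomial")
  # continuous scenarios always use modified Poisson
  expect_identical(choose_analysis(d, "continuous")$estimator, "modified_poisson")
  # a non-converged log binomial fit routes to modified Poisson
  broken <- fake_fit(rep(NA_real_, 3), rep(NA_real_, 3))
  broken$converged <- FALSE
  expect_identical(choose_analysis(d, "binary", fit_lb = broken)$estimator,
                   "modified_poisson")
})

test_that("deleting imputed outcomes removes exactly the right rows", {
  spec <- headline_binary_spec(n = 300, m = 3, cycles = 3)
  md <- small_mar_data(spec, seed = 305)
  set.seed(306)
  imp <- fcs_impute(md$data, spec)
  mid <- delete_imputed_outcomes(imp)
  n_keep <- sum(!md$data$miss_y)
  for (k in 1:3) {
    expect_equal(nrow(mid$completed[[k]]), n_keep)
    # imputed covariate values in retained rows are kept
    kept_x2 <- imp$completed[[k]]$x2[!md$data$miss_y]
    expect_identical(mid$completed[[k]]$x2, kept_x2)
  }
  expect_identical(mid$method, "FCS_MID")
  # with no imputed outcomes the operation is the identity on rows
  no_y <- imp
  no_y$imputed_y_mask <- rep(FALSE, 300)
  expect_equal(nrow(delete_imputed_outcomes(no_y)$completed[[1]]), 300)
  # deleting everything is refused
  all_y <- imp
  all_y$imputed_y_mask <- rep(TRUE, 300)
  expect_error(delete_imputed_outcomes(all_y), "all rows")
})

test_that("Rubin pooling reproduces hand-computed arithmetic", {
  # m = 2, estimates (0, 2), within-variances (1, 1):
  # pooled 1, W = 1, B = 2, T = 4, dof = (m-1)(1 + W/((1+1/m)B))^2 = 16/9
  fits <- list(fake_fit(c(b = 0), c(b = 1)), fake_fit(c(b = 2), c(b = 1)))
  p <- pool_rubin(fits)
  expect_equal(unname(p$estimates), 1)
  expect_equal(unname(p$within), 1)
  expect_equal(unname(p$between), 2)
  expect_equal(unname(p$total_variance), 4)
  expect_equal(unname(p$dof), 16 / 9)
  expect_equal(unname(p$ci_low), 1 - qt(0.975, 16 / 9) * 2)

  # identical estimates: B = 0, T = W, normal-quantile interval
  fits0 <- list(fake_fit(c(b = 1.3), c(b = 0.5)), fake_fit(c(b = 1.3), c(b = 0.5)))
  p0 <- pool_rubin(fits0)
  expect_equal(unname(p0$total_variance), 0.25)
  expect_equal(unname(p0$ci_high), 1.3 + qnorm(0.975) * 0.5)

  expect_error(pool_rubin(fits[1]), "at least 2")
})

test_that("pooling is order-invariant and total variance dominates within", {
  set.seed(307)
  fits <- lapply(1:8, function(i) {
    fake_fit(c(a = rnorm(1), b = rnorm(1)), c(a = runif(1, 0.5, 1), b = runif(1, 0.5, 1)))
  })
  p1 <- pool_rubin(fits)
  p2 <- pool_rubin(rev(fits))
  expect_equal(p1$estimates, p2$estimates)
  expect_equal(p1$total_variance, p2$total_variance)
  expect_true(all(p1$total_variance >= p1$within))
})

test_that("complete case analysis drops exactly the incomplete rows", {
  spec <- headline_binary_spec(n = 1000)
  md <- small_mar_data(spec, seed = 308)
  f <- cca_fit(md$data, "binary")
  expect_equal(f$n_used, sum(!(md$data$miss_y | md$data$miss_x2)))
  # without missingness, CCA equals the full-data fit
  cd <- md$complete |> dplyr::mutate(miss_y = FALSE, miss_x2 = FALSE)
  expect_equal(cca_fit(cd, "binary")$estimates,
               fit_log_binomial(md$complete)$estimates)
  tiny <- md$data[1:5, ]
  expect_error(cca_fit(tiny, "binary"), "complete cases")
})

test_that("tidiers return well-formed tibbles", {
  set.seed(309)
  d <- tibble::tibble(x1 = rbinom(300, 1, 0.5), x2 = rbinom(300, 1, 0.5))
  d$y <- rbinom(300, 1, exp(-2 + 0.4 * d$x1 + 0.4 * d$x2))
  f <- fit_log_binomial(d)
  td <- generics::tidy(f, conf.int = TRUE)
  expect_named(td, c("term", "estimate", "std.error", "conf.low", "conf.high"))
  expect_equal(nrow(td), 3)
  p <- pool_rubin(list(f, fit_modified_poisson(d)))
  tp <- generics::tidy(p)
  expect_true(all(tp$conf.low < tp$conf.high))
  expect_named(generics::glance(p), c("m_used", "confidence", "n_fallback"))
})
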