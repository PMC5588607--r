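# Data generation: intercept calibration, exposure models, missingness
# mechanisms.

test_that("beta0 calibration is exact for binary exposures", {
  # intercept-only model: prevalence is just exp(beta0)
  spec0 <- scenario_spec("binary", prevalence = 0.30, beta1 = 0, beta2 = 0,
                         assoc = 1, mechanism = "mcar")
  expect_equal(solve_beta0(spec0)$beta0, log(0.30), tolerance = 1e-12)

  # RR(X1,X2) = 2 puts X2 conditional prevalences at 1/3 and 2/3; summing
  # exp(b0 + b1 x1 + b2 x2) over the four cells gives b0 = log(p * 3/13)
  # for b1 = b2 = log 3 and p = 0.10
  spec <- scenario_spec("binary", prevalence = 0.10, beta1 = log(3),
                        beta2 = log(3), assoc = 2, mechanism = "coordinated")
  expect_equal(solve_beta0(spec)$beta0, log(0.10 * 3 / 13), tolerance = 1e-12)

  # an infeasible prevalence (cell probability above one) must be refused
  bad <- scenario_spec("binary", prevalence = 0.9, beta1 = log(3),
                       beta2 = log(3), assoc = 2, mechanism = "coordinated")
  expect_error(solve_beta0(bad), "infeasible")
})

test_that("beta0 calibration for continuous exposures matches a Monte Carlo oracle", {
  spec <- headline_continuous_spec()
  cal <- solve_beta0(spec)
  expect_lt(abs(cal$achieved_prevalence - 0.30), 1e-6)
  # oracle: regenerate a large sample with the returned intercept (the
  # generator applies invalid-probability resampling) and check prevalence
  set.seed(401)
  big <- generate_complete(spec, cal$beta0, n = 4e5)
  expect_lt(abs(mean(big$y) - 0.30), 0.0035) # ~3 binomial MC SEs + margin
})

test_that("alpha calibration hits the target missingness proportion", {
  # lambda = 0 is MCAR: alpha is just the logit of the target
  spec0 <- scenario_spec("binary", prevalence = 0.3, mechanism = "mcar")
  expect_equal(solve_alpha(spec0), qlogis(0.30), tolerance = 1e-12)

  # binary X1, lambda = 2: root of 0.5 plogis(a) + 0.5 plogis(a + 2) = 0.30,
  # solved independently and frozen
  spec_b <- headline_binary_spec()
  a_b <- solve_alpha(spec_b)
  expect_equal(a_b, -2.05443393046, tolerance = 1e-8)

  # continuous X1, lambda = 2: E over standard normal Z of plogis(a + 2Z),
  # frozen from an independent quadrature solve; verified against Monte Carlo
  spec_c <- headline_continuous_spec()
  a_c <- solve_alpha(spec_c)
  expect_equal(a_c, -1.38422626073, tolerance = 1e-8)
  set.seed(402)
  z <- rnorm(2e6)
  expect_lt(abs(mean(plogis(a_c + 2 * z)) - 0.30), 0.0012)

  # calibrate() reports achieved targets consistent with the spec
  cal <- calibrate(spec_b)
  expect_lt(abs(cal$achieved_prevalence - 0.30), 1e-6)
  expect_lt(abs(cal$achieved_missing_prop - 0.30), 1e-9)
})

test_that("generated exposures match their specified joint distribution", {
  spec <- headline_binary_spec()
  cal <- solve_beta0(spec)
  set.seed(403)
  d <- generate_complete(spec, cal$beta0, n = 2e5)
  # X2 marginal prevalence 0.50 regardless of the confounding association
  expect_lt(abs(mean(d$x2) - 0.5), 0.005)
  # conditional-prevalence ratio reproduces RR(X1, X2) = 2
  rr <- mean(d$x2[d$x1 == 1]) / mean(d$x2[d$x1 == 0])
  expect_lt(abs(rr - 2), 0.05)
  # no invalid success probability survives
  eta <- cal$beta0 + spec$beta1 * d$x1 + spec$beta2 * d$x2
  expect_true(all(exp(eta) <= 1 + 1e-12))

  # null model: outcome prevalence equals the target within 3 MC SEs
  spec0 <- scenario_spec("binary", prevalence = 0.30, beta1 = 0, beta2 = 0,
                         assoc = 1, mechanism = "mcar", n = 20000)
  d0 <- generate_complete(spec0, solve_beta0(spec0)$beta0)
  expect_lt(abs(mean(d0$y) - 0.30), 3 * sqrt(0.3 * 0.7 / 20000))
})

test_that("continuous generation resamples invalid probabilities and records their rate", {
  spec <- headline_continuous_spec()
  cal <- solve_beta0(spec)
  set.seed(404)
  d <- generate_complete(spec, cal$beta0, n = 2e5)
  eta <- cal$beta0 + spec$beta1 * d$x1 + spec$beta2 * d$x2
  expect_true(all(eta <= 0))
  # closed-form first-draw invalid rate for this calibration is 6.65%
  rate <- attr(d, "invalid_first_draw")
  expect_lt(abs(rate - 0.0665), 3 * sqrt(0.0665 * 0.9335 / 2e5) + 0.001)
})

test_that("missingness mechanisms produce the specified per-row probabilities", {
  spec <- headline_binary_spec(n = 2e5)
  alpha <- solve_alpha(spec)
  cal <- solve_beta0(spec)
  set.seed(405)
  d <- generate_complete(spec, cal$beta0)
  dm <- apply_missingness(d, spec, alpha)
  tol <- 3 * sqrt(0.3 * 0.7 / 2e5)
  expect_lt(abs(mean(dm$miss_y) - 0.30), tol)
  expect_lt(abs(mean(dm$miss_x2) - 0.30), tol)
  expect_false(anyNA(dm$x1))
  # coordinated, independent draws: P(both missing | X1 = 1) = plogis(a + 2)^2
  p_both <- plogis(alpha + 2)^2
  obs <- mean(dm$miss_y[d$x1 == 1] & dm$miss_x2[d$x1 == 1])
  expect_lt(abs(obs - p_both), 3 * sqrt(p_both * (1 - p_both) / sum(d$x1 == 1)))

  # coupled masks: identical indicators under the coordinated mechanism
  spec_cp <- headline_binary_spec(n = 5000, coupled_masks = TRUE)
  set.seed(406)
  dcp <- apply_missingness(generate_complete(spec_cp, cal$beta0, n = 5000),
                           spec_cp, alpha)
  expect_identical(dcp$miss_y, dcp$miss_x2)

  # opposite mechanism, strong lambda: missingness splits by X1, so no row
  # loses both variables
  spec_op <- scenario_spec("binary", prevalence = 0.3, beta1 = log(2),
                           beta2 = log(2), assoc = 2, mechanism = "opposite",
                           lambda = 20, missing_prop = 0.5, n = 5000)
  a_op <- solve_alpha(spec_op)
  set.seed(407)
  dop <- apply_missingness(generate_complete(spec_op, solve_beta0(spec_op)$beta0,
                                             n = 5000), spec_op, a_op)
  expect_equal(sum(dop$miss_y & dop$miss_x2), 0)

  # restricted mechanisms touch exactly one variable
  for (mech in c("y_only", "x2_only")) {
    spec_r <- headline_binary_spec(n = 2000)
    spec_r$mechanism <- mech
    set.seed(408)
    dr <- apply_missingness(generate_complete(spec_r, cal$beta0, n = 2000),
                            spec_r, alpha)
    expect_equal(any(dr$miss_y), mech == "y_only")
    expect_equal(any(dr$miss_x2), mech == "x2_only")
  }
})

test_that("CSV round trip preserves values and missingness", {
  spec <- headline_binary_spec(n = 200)
  md <- small_mar_data(spec, seed = 409)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sim_csv(md$data, path)
  back <- read_sim_csv(path)
  expect_equal(back$y, md$data$y)
  expect_equal(back$x2, md$data$x2)
  expect_equal(back$miss_y, md$data$miss_y)
  expect_equal(back$miss_x2, md$data$miss_x2)
})
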