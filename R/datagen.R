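#' Calibrate the outcome-model intercept to a target prevalence
#'
#' Solves for `b0` in `log P(Y = 1 | X1, X2) = b0 + beta1*X1 + beta2*X2`
#' such that the marginal outcome prevalence equals `spec$prevalence`.
#'
#' For binary exposures the marginal prevalence is a finite sum over the four
#' exposure cells, so `b0` is available in closed form. For continuous
#' exposures the linear predictor `S = beta1*X1 + beta2*X2` is normal with
#' variance `v = (beta1^2 + beta2^2 + 2*rho*beta1*beta2) * 0.20`; because
#' exposure pairs yielding success probabilities above one are resampled
#' during generation, the effective exposure law is truncated to
#' `{S <= -b0}`, and the prevalence under that law,
#' `exp(b0 + v/2) * pnorm((-b0 - v)/sqrt(v)) / pnorm(-b0/sqrt(v))`,
#' is solved for `b0` by root-finding. The truncation makes the equation
#' depend on `b0` on both sides, which is why no closed form exists.
#'
#' @param spec An [scenario_spec()] object.
#' @return A list with `beta0` and `achieved_prevalence`.
#' @export
solve_beta0 <- function(spec) {
  p <- spec$prevalence
  if (spec$exposure_type == "binary") {
    cells <- exposure_cells(spec$assoc)
    denom <- sum(exp(spec$beta1 * cells$x1 + spec$beta2 * cells$x2) * cells$prob)
    beta0 <- log(p / denom)
    pmax_cell <- exp(beta0 + max(spec$beta1 * cells$x1 + spec$beta2 * cells$x2))
    if (pmax_cell > 1 + 1e-12) {
      stop("infeasible scenario: calibrated model implies a success probability above one (",
           format(pmax_cell), ") in some exposure cell", call. = FALSE)
    }
    return(list(beta0 = beta0, achieved_prevalence = p))
  }
  v <- lp_variance(spec)
  if (v < .Machine$double.eps) {
    return(list(beta0 = log(p), achieved_prevalence = p))
  }
  # prevalence of the resampling-truncated model as a function of b0
  g <- function(b0) {
    exp(b0 + v / 2) * stats::pnorm((-b0 - v) / sqrt(v)) /
      stats::pnorm(-b0 / sqrt(v)) - p
  }
  lo <- log(p) - v / 2 - 10
  if (g(lo) >= 0 || g(-1e-10) <= 0) {
    stop("no root for beta0 in the search interval; prevalence ",
         p, " is infeasible for these slopes", call. = FALSE)
  }
  beta0 <- stats::uniroot(g, c(lo, -1e-10), tol = 1e-12)$root
  list(beta0 = beta0, achieved_prevalence = g(beta0) + p)
}

# Joint distribution of two binary exposures with 0.5 marginals and
# conditional-prevalence ratio p1/p0 = assoc: p0 = 1/(1+a), p1 = a/(1+a).
exposure_cells <- function(assoc) {
  p0 <- 1 / (1 + assoc)
  p1 <- assoc / (1 + assoc)
  list(
    x1 = c(0, 0, 1, 1),
    x2 = c(0, 1, 0, 1),
    prob = c(0.5 * (1 - p0), 0.5 * p0, 0.5 * (1 - p1), 0.5 * p1),
    p0 = p0, p1 = p1
  )
}

# Variance of beta1*X1 + beta2*X2 under the bivariate normal exposure model
# (variance 0.20, correlation spec$assoc).
lp_variance <- function(spec) {
  (spec$beta1^2 + spec$beta2^2 + 2 * spec$assoc * spec$beta1 * spec$beta2) * 0.20
}

#' Calibrate the missingness intercept to a target missingness proportion
#'
#' Solves `E[plogis(alpha + lambda * S1)] = spec$missing_prop`, where `S1`
#' is `X1` for binary exposures (a fair Bernoulli variable) and the
#' standardised exposure `Z1 = X1 / sqrt(0.20)` (standard normal) for
#' continuous exposures. By the symmetry of the mechanisms the same `alpha`
#' also calibrates the second equation of the opposite mechanism
#' (`alpha + lambda*(1 - X1)` or `alpha - lambda*Z1`).
#'
#' @param spec An [scenario_spec()] object.
#' @return The calibrated intercept `alpha` (logit scale).
#' @export
solve_alpha <- function(spec) {
  p <- spec$missing_prop
  l <- spec$lambda
  if (l == 0 || spec$mechanism == "mcar") {
    return(stats::qlogis(p))
  }
  f <- if (spec$exposure_type == "binary") {
    function(a) 0.5 * stats::plogis(a) + 0.5 * stats::plogis(a + l) - p
  } else {
    function(a) {
      stats::integrate(function(z) stats::plogis(a + l * z) * stats::dnorm(z),
                       -Inf, Inf, rel.tol = 1e-12)$value - p
    }
  }
  stats::uniroot(f, c(-40, 40), tol = 1e-12)$root
}

#' Calibrate a scenario
#'
#' Runs [solve_beta0()] and [solve_alpha()] and returns both intercepts with
#' their achieved targets; done once per scenario before replication.
#'
#' @param spec An [scenario_spec()] object.
#' @return A list with `beta0`, `alpha`, `achieved_prevalence` and
#'   `achieved_missing_prop`.
#' @export
calibrate <- function(spec) {
  b <- solve_beta0(spec)
  alpha <- solve_alpha(spec)
  achieved_miss <- if (spec$lambda == 0 || spec$mechanism == "mcar") {
    stats::plogis(alpha)
  } else if (spec$exposure_type == "binary") {
    0.5 * stats::plogis(alpha) + 0.5 * stats::plogis(alpha + spec$lambda)
  } else {
    stats::integrate(function(z) stats::plogis(alpha + spec$lambda * z) * stats::dnorm(z),
                     -Inf, Inf, rel.tol = 1e-12)$value
  }
  list(beta0 = b$beta0, alpha = alpha,
       achieved_prevalence = b$achieved_prevalence,
       achieved_missing_prop = achieved_miss)
}

#' Generate one complete dataset from the log binomial model
#'
#' Draws exposures (binary with 0.50 marginals and confounding risk ratio
#' `assoc`, or bivariate normal with variance 0.20 and correlation `assoc`),
#' then the outcome `Y ~ Bernoulli(exp(b0 + beta1*X1 + beta2*X2))`. For
#' continuous exposures, rows whose success probability exceeds one have
#' their exposure pair redrawn until valid (capped at `max_attempts`
#' redraw rounds); the fraction of invalid first draws is recorded in the
#' `invalid_first_draw` attribute.
#'
#' @param spec An [scenario_spec()] object.
#' @param beta0 The calibrated intercept from [solve_beta0()].
#' @param n Number of rows (defaults to `spec$n`).
#' @param max_attempts Cap on redraw rounds for invalid success
#'   probabilities.
#' @return A tibble with columns `y`, `x1`, `x2` and attribute
#'   `invalid_first_draw`.
#' @export
generate_complete <- function(spec, beta0, n = spec$n, max_attempts = 1e4) {
  if (spec$exposure_type == "binary") {
    cells <- exposure_cells(spec$assoc)
    x1 <- stats::rbinom(n, 1, 0.5)
    x2 <- stats::rbinom(n, 1, ifelse(x1 == 1, cells$p1, cells$p0))
    pr <- exp(beta0 + spec$beta1 * x1 + spec$beta2 * x2)
    if (any(pr > 1 + 1e-12)) {
      stop("invalid success probability in a binary-exposure scenario; beta0 miscalibrated",
           call. = FALSE)
    }
    invalid_first <- 0
  } else {
    sd1 <- sqrt(0.20)
    sd2c <- sqrt(0.20 * (1 - spec$assoc^2))
    x1 <- stats::rnorm(n, 0, sd1)
    x2 <- spec$assoc * x1 + stats::rnorm(n, 0, sd2c)
    eta <- beta0 + spec$beta1 * x1 + spec$beta2 * x2
    bad <- eta > 0
    invalid_first <- mean(bad)
    attempt <- 0
    while (any(bad)) {
      attempt <- attempt + 1
      if (attempt > max_attempts) {
        stop("exposure resampling did not terminate within ", max_attempts,
             " rounds", call. = FALSE)
      }
      k <- sum(bad)
      x1[bad] <- stats::rnorm(k, 0, sd1)
      x2[bad] <- spec$assoc * x1[bad] + stats::rnorm(k, 0, sd2c)
      eta[bad] <- beta0 + spec$beta1 * x1[bad] + spec$beta2 * x2[bad]
      bad[bad] <- eta[bad] > 0
    }
    pr <- exp(eta)
  }
  y <- stats::rbinom(n, 1, pmin(pr, 1))
  out <- tibble::tibble(y = y, x1 = x1, x2 = x2)
  attr(out, "invalid_first_draw") <- invalid_first
  out
}

#' Impose MAR missingness on the outcome and second exposure
#'
#' Per-row missingness probabilities depend on the fully observed exposure
#' `X1` through a logistic model. With `s` equal to `X1` (binary) or
#' `Z1 = X1/sqrt(0.20)` (continuous):
#' * coordinated: `logit P(Y miss) = logit P(X2 miss) = alpha + lambda*s`;
#' * opposite: `logit P(Y miss) = alpha + lambda*s` and
#'   `logit P(X2 miss) = alpha + lambda*(1 - X1)` (binary) or
#'   `alpha - lambda*Z1` (continuous);
#' * y_only / x2_only: only the named variable is subject to missingness,
#'   with `logit P(miss) = alpha + lambda*s`;
#' * mcar: both probabilities equal `plogis(alpha)`.
#'
#' Under the coordinated mechanism the two indicators share a per-row
#' probability but are drawn with independent uniforms unless
#' `spec$coupled_masks` is set, in which case one uniform drives both.
#'
#' @param data A complete tibble from [generate_complete()].
#' @param spec An [scenario_spec()] object.
#' @param alpha Calibrated missingness intercept from [solve_alpha()].
#' @return The tibble with masked cells set to `NA` and logical columns
#'   `miss_y`, `miss_x2` appended.
#' @export
apply_missingness <- function(data, spec, alpha) {
  n <- nrow(data)
  s <- if (spec$exposure_type == "binary") data$x1 else data$x1 / sqrt(0.20)
  p_y <- p_x2 <- rep(0, n)
  if (spec$mechanism %in% c("coordinated", "opposite", "y_only", "mcar")) {
    p_y <- stats::plogis(alpha + spec$lambda * s)
  }
  p_x2 <- switch(spec$mechanism,
    coordinated = p_y,
    opposite = if (spec$exposure_type == "binary") {
      stats::plogis(alpha + spec$lambda * (1 - data$x1))
    } else {
      stats::plogis(alpha - spec$lambda * s)
    },
    x2_only = stats::plogis(alpha + spec$lambda * s),
    y_only = rep(0, n),
    mcar = p_y
  )
  if (spec$mechanism == "coordinated" && isTRUE(spec$coupled_masks)) {
    u <- stats::runif(n)
    miss_y <- u < p_y
    miss_x2 <- u < p_x2
  } else {
    miss_y <- stats::runif(n) < p_y
    miss_x2 <- stats::runif(n) < p_x2
  }
  data |>
    dplyr::mutate(
      y = replace(.data$y, miss_y, NA),
      x2 = replace(.data$x2, miss_x2, NA),
      miss_y = miss_y,
      miss_x2 = miss_x2
    )
}

#' Write a simulated dataset as CSV
#'
#' Columns `y`, `x1`, `x2`; missing cells are written as empty fields.
#'
#' @param data A tibble with columns `y`, `x1`, `x2`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_csv <- function(data, path) {
  utils::write.csv(data[, c("y", "x1", "x2")], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a simulated dataset from CSV
#'
#' Inverse of [write_sim_csv()]: empty fields become `NA` and the mask
#' columns are reconstructed.
#'
#' @param path CSV path.
#' @return A tibble with columns `y`, `x1`, `x2`, `miss_y`, `miss_x2`.
#' @export
read_sim_csv <- function(path) {
  d <- utils::read.csv(path, na.strings = "")
  tibble::as_tibble(d) |>
    dplyr::mutate(miss_y = is.na(.data$y), miss_x2 = is.na(.data$x2))
}
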