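#' Posterior-draw logistic imputation
#'
#' Fits a logistic regression of the observed responses on the design,
#' draws a coefficient vector from the asymptotic normal approximation to
#' its posterior (mean at the MLE, covariance the inverse observed
#' information), and imputes each missing response as a Bernoulli draw with
#' probability `plogis(x * theta*)`.
#'
#' If the fit fails to converge or the information matrix is numerically
#' singular (separation), one retry is made with a small ridge term added
#' to the information; persistent failure signals a condition of class
#' `rrmi_imputation_error` so callers can flag the replicate.
#'
#' @param x_obs Design matrix (including intercept column) for rows with an
#'   observed response.
#' @param y_obs Observed binary responses.
#' @param x_mis Design matrix for rows to impute; may have zero rows.
#' @return Integer vector of imputed 0/1 values, one per row of `x_mis`.
#' @export
draw_logistic_imputation <- function(x_obs, y_obs, x_mis) {
  if (NROW(x_mis) == 0L) return(integer(0))
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(x_obs, y_obs, family = fam_logit,
                                    control = stats::glm.control(maxit = 50))),
    error = function(e) NULL
  )
  if (is.null(fit) || !all(is.finite(fit$coefficients))) {
    imp_fail("logistic imputation model could not be fitted")
  }
  beta <- fit$coefficients
  info <- crossprod(x_obs * sqrt(fit$weights))
  ch <- tryCatch(chol(info), error = function(e) NULL)
  if (is.null(ch) || !fit$converged || max(abs(beta)) > 20) {
    # separation / near-singular information: ridge the information for the draw
    info <- info + diag(1e-4 * max(diag(info)), ncol(info))
    ch <- tryCatch(chol(info), error = function(e) NULL)
    if (is.null(ch)) imp_fail("singular information in logistic imputation model")
  }
  # theta* = beta + R^{-1} z with info = R'R gives covariance info^{-1}
  theta <- beta + backsolve(ch, stats::rnorm(ncol(x_obs)))
  p <- stats::plogis(drop(x_mis %*% theta))
  stats::rbinom(NROW(x_mis), 1L, p)
}

#' Posterior-draw Bayesian linear imputation
#'
#' Under the Jeffreys prior (flat on coefficients, 1/sigma^2 on the
#' variance), draws `sigma^2* = RSS / chi^2_{n-p}`, then coefficients from
#' `N(beta_hat, sigma^2* (X'X)^{-1})`, and imputes missing responses as
#' `x * theta* + sigma* * epsilon` with standard normal noise.
#'
#' @param x_obs Design matrix for rows with an observed response
#'   (needs at least `ncol(x_obs) + 2` rows).
#' @param y_obs Observed continuous responses.
#' @param x_mis Design matrix for rows to impute; may have zero rows.
#' @return Numeric vector of imputed values, one per row of `x_mis`.
#' @export
draw_linear_imputation <- function(x_obs, y_obs, x_mis) {
  if (NROW(x_mis) == 0L) return(numeric(0))
  p <- ncol(x_obs)
  n <- NROW(x_obs)
  if (n < p + 2) imp_fail("too few observed rows for linear imputation model")
  qr_x <- qr(x_obs)
  if (qr_x$rank < p) imp_fail("singular design in linear imputation model")
  beta <- qr.coef(qr_x, y_obs)
  rss <- sum(qr.resid(qr_x, y_obs)^2)
  sigma2 <- rss / stats::rchisq(1, df = n - p)
  r_inv_z <- backsolve(qr.R(qr_x), stats::rnorm(p))
  theta <- beta + sqrt(sigma2) * r_inv_z
  drop(x_mis %*% theta) + sqrt(sigma2) * stats::rnorm(NROW(x_mis))
}

#' Multiple imputation by fully conditional specification
#'
#' Chained-equations imputation of the missing cells in `Y` and `X2`. Each
#' of the `m` imputations runs an independent chain: missing cells are first
#' filled with values resampled from the observed margin of the same
#' variable, then `spec$cycles` sweeps are run, each re-imputing `X2` from
#' `(Y, X1)` and `Y` from `(X1, X2)` - in that order when
#' `spec$order = "outcome_last"` (the default), reversed for
#' `"outcome_first"`. `Y` (and `X2` when binary) uses the posterior-draw
#' logistic model; continuous `X2` uses the Bayesian linear model. The final
#' state of each chain is one completed dataset.
#'
#' @param data A tibble from [apply_missingness()] (columns `y`, `x1`, `x2`,
#'   `miss_y`, `miss_x2`; masked cells `NA`).
#' @param spec An [scenario_spec()] object (uses `m`, `cycles`, `order`,
#'   `exposure_type`).
#' @return An object of class `rrmi_impset`: list with `completed` (list of
#'   `m` complete tibbles), `imputed_y_mask`, `imputed_x2_mask`, `method`.
#' @export
fcs_impute <- function(data, spec) {
  miss_y <- data$miss_y
  miss_x2 <- data$miss_x2
  x1 <- data$x1
  y_observed <- data$y[!miss_y]
  x2_observed <- data$x2[!miss_x2]
  x2_binary <- spec$exposure_type == "binary"
  one <- rep(1, nrow(data))

  impute_once <- function() {
    y <- data$y
    x2 <- data$x2
    if (any(miss_y)) y[miss_y] <- sample(y_observed, sum(miss_y), replace = TRUE)
    if (any(miss_x2)) x2[miss_x2] <- sample(x2_observed, sum(miss_x2), replace = TRUE)
    sweep_x2 <- function() {
      if (!any(miss_x2)) return()
      des <- cbind(one, y, x1)
      if (x2_binary) {
        x2[miss_x2] <<- draw_logistic_imputation(des[!miss_x2, , drop = FALSE],
                                                 x2[!miss_x2],
                                                 des[miss_x2, , drop = FALSE])
      } else {
        x2[miss_x2] <<- draw_linear_imputation(des[!miss_x2, , drop = FALSE],
                                               x2[!miss_x2],
                                               des[miss_x2, , drop = FALSE])
      }
    }
    sweep_y <- function() {
      if (!any(miss_y)) return()
      des <- cbind(one, x1, x2)
      y[miss_y] <<- draw_logistic_imputation(des[!miss_y, , drop = FALSE],
                                             y[!miss_y],
                                             des[miss_y, , drop = FALSE])
    }
    for (cyc in seq_len(spec$cycles)) {
      if (spec$order == "outcome_last") {
        sweep_x2(); sweep_y()
      } else {
        sweep_y(); sweep_x2()
      }
    }
    tibble::tibble(y = y, x1 = x1, x2 = x2)
  }

  completed <- lapply(seq_len(spec$m), function(k) impute_once())
  new_impset(completed, miss_y, miss_x2, "FCS")
}

new_impset <- function(completed, imputed_y_mask, imputed_x2_mask, method) {
  structure(
    list(completed = completed, imputed_y_mask = imputed_y_mask,
         imputed_x2_mask = imputed_x2_mask, method = method),
    class = "rrmi_impset"
  )
}

#' @export
print.rrmi_impset <- function(x, ...) {
  cat(sprintf("<rrmi_impset> %s: %d imputations of %d rows (%d Y, %d X2 imputed)\n",
              x$method, length(x$completed), nrow(x$completed[[1]]),
              sum(x$imputed_y_mask), sum(x$imputed_x2_mask)))
  invisible(x)
}

imp_fail <- function(msg) {
  stop(structure(class = c("rrmi_imputation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
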