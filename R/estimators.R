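# Analysis-model layer: log binomial GLM, modified Poisson with robust
# variance, complete case analysis, deletion of imputed outcomes, and
# Rubin's-rules pooling.

new_fit <- function(estimates, std_errors, converged, estimator, n_used) {
  structure(
    list(estimates = estimates,
         std_errors = stats::setNames(std_errors, names(estimates)),
         converged = converged, estimator = estimator, n_used = n_used),
    class = "rrmi_fit"
  )
}

#' @export
print.rrmi_fit <- function(x, ...) {
  cat(sprintf("<rrmi_fit> %s (n = %d, converged = %s)\n",
              x$estimator, x$n_used, x$converged))
  print(cbind(estimate = x$estimates, std.error = x$std_errors))
  invisible(x)
}

# Build (y, X) from whichever of x1, x2 are present; the full analysis
# model is y ~ x1 + x2, but reduced designs support closed-form checks.
fit_design <- function(data) {
  vars <- intersect(c("x1", "x2"), names(data))
  x <- cbind(`(Intercept)` = rep(1, nrow(data)),
             as.matrix(data[vars]))
  y <- data$y
  if (anyNA(y) || anyNA(x)) {
    stop("analysis models require complete data; drop or impute missing cells first",
         call. = FALSE)
  }
  list(y = y, x = x)
}

#' Log binomial regression
#'
#' Binomial GLM with log link of `Y` on `(1, X1, X2)`, fitted by IRLS with
#' starting values `(log(mean(y)), 0, 0)` (deviance tolerance 1e-8, at most
#' 100 iterations). Coefficients are adjusted log relative risks; standard
#' errors come from the inverse observed information. Because the log link
#' does not bound fitted probabilities below one, the fit is declared
#' non-converged when IRLS fails or any fitted probability reaches the
#' boundary; the estimates (when available) are retained so callers can
#' apply fallback logic.
#'
#' @param data A complete dataset with columns `y` (binary), `x1`, `x2`.
#' @return An `rrmi_fit` with `estimator = "log_binomial"`.
#' @export
fit_log_binomial <- function(data) {
  d <- fit_design(data)
  if (stats::var(d$y) == 0) {
    stop("outcome is constant; the log binomial MLE does not exist", call. = FALSE)
  }
  start <- c(log(mean(d$y)), rep(0, ncol(d$x) - 1))
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(
      d$x, d$y, family = fam_log, start = start,
      control = stats::glm.control(epsilon = 1e-8, maxit = 100)
    )),
    error = function(e) NULL
  )
  if (is.null(fit) || !all(is.finite(fit$coefficients))) {
    p <- ncol(d$x)
    return(new_fit(rep(NA_real_, p), rep(NA_real_, p), FALSE,
                   "log_binomial", length(d$y)))
  }
  boundary <- max(fit$fitted.values) > 1 - 1e-10
  converged <- fit$converged && !boundary
  se <- rep(NA_real_, ncol(d$x))
  ch <- tryCatch(chol(crossprod(d$x * sqrt(fit$weights))), error = function(e) NULL)
  if (!is.null(ch)) se <- sqrt(diag(chol2inv(ch)))
  new_fit(stats::setNames(fit$coefficients, colnames(d$x)), se, converged,
          "log_binomial", length(d$y))
}

#' Modified Poisson regression with robust variance
#'
#' Poisson GLM with log link applied to the binary outcome, with standard
#' errors from the HC0 sandwich estimator `A^{-1} B A^{-1}` (`A` the Fisher
#' information `X'WX` with `W = mu`, `B` the outer-product-of-scores sum
#' `sum (y - mu)^2 x x'`). The Poisson working model misstates the Bernoulli
#' variance, which the sandwich corrects; point estimates remain consistent
#' for log relative risks.
#'
#' @param data A complete dataset with columns `y` (binary), `x1`, `x2`.
#' @return An `rrmi_fit` with `estimator = "modified_poisson"`.
#' @export
fit_modified_poisson <- function(data) {
  d <- fit_design(data)
  fit <- suppressWarnings(stats::glm.fit(d$x, d$y, family = fam_pois,
                                         control = stats::glm.control(epsilon = 1e-12, maxit = 50)))
  mu <- fit$fitted.values
  a <- crossprod(d$x * sqrt(mu))
  ch <- tryCatch(chol(a), error = function(e) NULL)
  if (is.null(ch)) stop("singular information in modified Poisson fit", call. = FALSE)
  a_inv <- chol2inv(ch)
  b <- crossprod(d$x * (d$y - mu))
  vcov <- a_inv %*% b %*% a_inv
  new_fit(stats::setNames(fit$coefficients, colnames(d$x)), sqrt(diag(vcov)),
          fit$converged, "modified_poisson", length(d$y))
}

#' Choose the analysis model for one complete dataset
#'
#' Binary-exposure scenarios are analysed with the log binomial model,
#' falling back to modified Poisson regression when it fails to converge;
#' continuous-exposure scenarios are always analysed with modified Poisson
#' regression, where log binomial non-convergence is endemic.
#'
#' @param data A complete dataset.
#' @param exposure_type `"binary"` or `"continuous"`.
#' @param fit_lb Optionally, an already-computed log binomial `rrmi_fit`
#'   for `data` (avoids refitting).
#' @return An `rrmi_fit`.
#' @export
choose_analysis <- function(data, exposure_type, fit_lb = NULL) {
  if (exposure_type == "continuous") {
    return(fit_modified_poisson(data))
  }
  if (is.null(fit_lb)) fit_lb <- fit_log_binomial(data)
  if (fit_lb$converged && all(is.finite(fit_lb$std_errors))) {
    return(fit_lb)
  }
  fit_modified_poisson(data)
}

#' Delete rows whose outcome was imputed (MID)
#'
#' "Multiple imputation, then deletion": every completed dataset loses the
#' rows whose `Y` value was imputed, while imputed covariate values in the
#' retained rows are kept.
#'
#' @param imp An `rrmi_impset`.
#' @return An `rrmi_impset` whose completed datasets exclude imputed-outcome
#'   rows (`imputed_y_mask` becomes all-`FALSE` on the retained rows).
#' @export
delete_imputed_outcomes <- function(imp) {
  keep <- !imp$imputed_y_mask
  if (!any(keep)) stop("all rows have imputed outcomes; nothing to analyse", call. = FALSE)
  imp$completed <- lapply(imp$completed, function(d) d[keep, , drop = FALSE])
  imp$imputed_x2_mask <- imp$imputed_x2_mask[keep]
  imp$imputed_y_mask <- rep(FALSE, sum(keep))
  imp$method <- paste0(imp$method, "_MID")
  imp
}

#' Pool per-imputation fits by Rubin's rules
#'
#' Combines `m` completed-data fits: pooled estimate = mean of estimates;
#' within-imputation variance `W = mean(se^2)`; between-imputation variance
#' `B = var(estimates)`; total variance `T = W + (1 + 1/m) B`; degrees of
#' freedom `(m - 1) (1 + W / ((1 + 1/m) B))^2` (infinite when `B = 0`),
#' optionally replaced by the Barnard-Rubin small-sample value when the
#' complete-data degrees of freedom are supplied; confidence intervals use
#' the t distribution on those degrees of freedom.
#'
#' @param fits List of `rrmi_fit` objects with a common coefficient order
#'   (at least 2).
#' @param confidence Interval coverage level (default 0.95).
#' @param dof_complete Optional complete-data degrees of freedom; when
#'   given, the Barnard-Rubin adjusted degrees of freedom are used instead
#'   of the classical large-sample formula.
#' @return An object of class `rrmi_pooled`.
#' @export
pool_rubin <- function(fits, confidence = 0.95, dof_complete = NULL) {
  m <- length(fits)
  if (m < 2) stop("Rubin's rules need at least 2 fits (between-variance undefined)",
                  call. = FALSE)
  est <- do.call(rbind, lapply(fits, function(f) f$estimates))
  se2 <- do.call(rbind, lapply(fits, function(f) f$std_errors^2))
  qbar <- colMeans(est)
  w <- colMeans(se2)
  b <- apply(est, 2, stats::var)
  total <- w + (1 + 1 / m) * b
  r <- (1 + 1 / m) * b / w
  dof <- ifelse(b > 0, (m - 1) * (1 + 1 / r)^2, Inf)
  if (!is.null(dof_complete)) {
    lam <- (1 + 1 / m) * b / total
    dof_obs <- (dof_complete + 1) / (dof_complete + 3) * dof_complete * (1 - lam)
    dof <- ifelse(b > 0, 1 / (1 / dof + 1 / dof_obs), dof_obs)
  }
  tq <- stats::qt(1 - (1 - confidence) / 2, dof)
  tq[!is.finite(dof)] <- stats::qnorm(1 - (1 - confidence) / 2)
  structure(
    list(estimates = qbar, within = w, between = b, total_variance = total,
         dof = dof, ci_low = qbar - tq * sqrt(total),
         ci_high = qbar + tq * sqrt(total), m_used = m,
         confidence = confidence,
         estimators = vapply(fits, function(f) f$estimator, character(1)),
         n_fallback = 0L),
    class = "rrmi_pooled"
  )
}

#' @export
print.rrmi_pooled <- function(x, ...) {
  cat(sprintf("<rrmi_pooled> m = %d, %.0f%% intervals\n", x$m_used, 100 * x$confidence))
  print(cbind(estimate = x$estimates, total.var = x$total_variance, df = x$dof,
              ci.low = x$ci_low, ci.high = x$ci_high))
  invisible(x)
}

#' Analyse an imputation set and pool
#'
#' Fits the scenario's analysis model ([choose_analysis()]) to each
#' completed dataset of an imputation set and pools with Rubin's rules.
#' Datasets where both estimators fail are dropped (their count is recorded
#' in `m_failed`).
#'
#' @param imp An `rrmi_impset`.
#' @param exposure_type `"binary"` or `"continuous"`.
#' @param confidence Interval coverage level.
#' @return An `rrmi_pooled` (with attribute `m_failed`).
#' @export
analyse_imputations <- function(imp, exposure_type, confidence = 0.95) {
  fits <- lapply(imp$completed, function(d) {
    tryCatch(choose_analysis(d, exposure_type), error = function(e) NULL)
  })
  failed <- vapply(fits, is.null, logical(1))
  pooled <- pool_rubin(fits[!failed], confidence = confidence)
  if (exposure_type == "binary") {
    pooled$n_fallback <- sum(pooled$estimators == "modified_poisson")
  }
  attr(pooled, "m_failed") <- sum(failed)
  pooled
}

#' Complete case analysis
#'
#' Drops rows with missing `Y` or `X2` and applies the scenario's analysis
#' model to the remainder.
#'
#' @param data A tibble from [apply_missingness()].
#' @param exposure_type `"binary"` or `"continuous"`.
#' @param min_rows Minimum number of complete rows required.
#' @return An `rrmi_fit`.
#' @export
cca_fit <- function(data, exposure_type, min_rows = 10) {
  keep <- !(data$miss_y | data$miss_x2)
  if (sum(keep) < min_rows) {
    stop("fewer than ", min_rows, " complete cases", call. = FALSE)
  }
  choose_analysis(data[keep, , drop = FALSE], exposure_type)
}

#' @rdname rrmi_tidiers
#' @exportS3Method generics::tidy
tidy.rrmi_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  out <- tibble::tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = unname(x$std_errors)
  )
  if (conf.int) {
    zq <- stats::qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - zq * out$std.error
    out$conf.high <- out$estimate + zq * out$std.error
  }
  out
}

#' Tidiers for fitted and pooled results
#'
#' [generics::tidy()] returns one row per coefficient;
#' [generics::glance()] returns a one-row summary.
#'
#' @param x An `rrmi_fit` or `rrmi_pooled` object.
#' @param conf.int Add confidence bounds (`rrmi_fit` only; `rrmi_pooled`
#'   always carries its pooled interval).
#' @param conf.level Level for `rrmi_fit` intervals.
#' @param ... Unused.
#' @return A tibble.
#' @name rrmi_tidiers
#' @exportS3Method generics::tidy
tidy.rrmi_pooled <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = unname(sqrt(x$total_variance)),
    df = unname(x$dof),
    conf.low = unname(x$ci_low),
    conf.high = unname(x$ci_high)
  )
}

#' @rdname rrmi_tidiers
#' @exportS3Method generics::glance
glance.rrmi_fit <- function(x, ...) {
  tibble::tibble(estimator = x$estimator, converged = x$converged, n_used = x$n_used)
}

#' @rdname rrmi_tidiers
#' @exportS3Method generics::glance
glance.rrmi_pooled <- function(x, ...) {
  tibble::tibble(m_used = x$m_used, confidence = x$confidence,
                 n_fallback = x$n_fallback)
}
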