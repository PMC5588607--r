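# Multivariate normal imputation: EM starting values, data augmentation,
# and rounding of binary variables. The imputation model treats (Y, X1, X2)
# as jointly normal with binary variables entering as raw 0/1 values.

# Missingness-pattern bookkeeping shared by EM and DA. Returns, per distinct
# pattern, the row indices and the observed/missing coordinate sets.
mvn_patterns <- function(z) {
  miss <- is.na(z)
  id <- miss %*% (2^(seq_len(ncol(z)) - 1))
  lapply(split(seq_len(nrow(z)), id), function(rows) {
    mis <- which(miss[rows[1], ])
    list(rows = rows, obs = setdiff(seq_len(ncol(z)), mis), mis = mis)
  })
}

#' EM starting values for the multivariate normal imputation model
#'
#' Maximum likelihood estimation of the mean and covariance of a
#' multivariate normal from incompletely observed rows (ignorable
#' missingness), by EM on the sufficient statistics. Convergence is declared
#' when successive observed-data log-likelihoods differ by less than `tol`.
#'
#' @param data A tibble/data frame whose numeric columns (`y`, `x1`, `x2`)
#'   may contain `NA`, or a numeric matrix.
#' @param tol Log-likelihood convergence tolerance.
#' @param maxit Iteration cap.
#' @return A list with `mu`, `sigma` (MLE, denominator `n`), `loglik`,
#'   `iterations`, `converged`.
#' @export
em_start <- function(data, tol = 1e-8, maxit = 5000) {
  z <- as_z_matrix(data)
  n <- nrow(z)
  d <- ncol(z)
  if (any(colSums(!is.na(z)) < 2)) {
    stop("each variable must be observed at least twice", call. = FALSE)
  }
  pats <- mvn_patterns(z)
  mu <- colMeans(z, na.rm = TRUE)
  sigma <- diag(apply(z, 2, stats::var, na.rm = TRUE), d)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    t1 <- numeric(d)
    t2 <- matrix(0, d, d)
    ll <- 0
    for (p in pats) {
      zo <- z[p$rows, p$obs, drop = FALSE]
      k <- length(p$rows)
      if (length(p$mis) == 0L) {
        t1 <- t1 + colSums(zo)
        t2 <- t2 + crossprod(zo)
        ll <- ll + mvn_ll(zo, mu[p$obs], sigma[p$obs, p$obs, drop = FALSE])
        next
      }
      if (length(p$obs) == 0L) {
        # nothing observed in these rows: they contribute the current
        # parameters directly and nothing to the observed-data likelihood
        t1 <- t1 + k * mu
        t2 <- t2 + k * (sigma + tcrossprod(mu))
        next
      }
      soo <- sigma[p$obs, p$obs, drop = FALSE]
      b <- sigma[p$mis, p$obs, drop = FALSE] %*% solve(soo)
      cond_cov <- sigma[p$mis, p$mis, drop = FALSE] -
        b %*% sigma[p$obs, p$mis, drop = FALSE]
      zm <- matrix(mu[p$mis], k, length(p$mis), byrow = TRUE) +
        sweep(zo, 2, mu[p$obs]) %*% t(b)
      zfull <- matrix(0, k, d)
      zfull[, p$obs] <- zo
      zfull[, p$mis] <- zm
      t1 <- t1 + colSums(zfull)
      cc <- crossprod(zfull)
      cc[p$mis, p$mis] <- cc[p$mis, p$mis, drop = FALSE] + k * cond_cov
      t2 <- t2 + cc
      ll <- ll + mvn_ll(zo, mu[p$obs], soo)
    }
    mu <- t1 / n
    sigma_new <- t2 / n - tcrossprod(mu)
    sigma_new <- (sigma_new + t(sigma_new)) / 2
    if (inherits(tryCatch(chol(sigma_new), error = identity), "error")) {
      sigma_new <- sigma_new + diag(1e-6 * mean(diag(sigma_new)), d)
    }
    sigma <- sigma_new
    if (abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma, loglik = ll, iterations = it, converged = converged)
}

# Observed-data log-likelihood contribution of one pattern block.
mvn_ll <- function(zo, mu, sigma) {
  k <- nrow(zo)
  d <- ncol(zo)
  ch <- chol(sigma)
  dev <- sweep(zo, 2, mu)
  q <- forwardsolve(t(ch), t(dev))
  -0.5 * (k * d * log(2 * pi) + 2 * k * sum(log(diag(ch))) + sum(q^2))
}

as_z_matrix <- function(data) {
  if (is.matrix(data)) return(data)
  as.matrix(data[, intersect(c("y", "x1", "x2"), names(data)), drop = FALSE])
}

#' Multivariate normal imputation by data augmentation
#'
#' Alternates an I-step (draw each row's missing coordinates from their
#' conditional normal given the observed coordinates and the current
#' parameters) and a P-step (draw the covariance from its inverse-Wishart
#' posterior and the mean from its conditional normal, under the Jeffreys
#' prior, given the completed data). The first imputation is recorded after
#' `spec$burn_in` iterations and subsequent ones every `spec$between`
#' iterations, yielding `spec$m` completed datasets whose originally missing
#' cells hold continuous draws.
#'
#' @param data A tibble from [apply_missingness()].
#' @param spec An [scenario_spec()] object (uses `m`, `burn_in`, `between`).
#' @param start Optional starting parameters (list with `mu`, `sigma`);
#'   defaults to [em_start()] on `data`.
#' @return An `rrmi_impset` whose completed datasets are continuous-valued
#'   in the originally missing cells; `method = "MVNI"`.
#' @export
da_impute <- function(data, spec, start = NULL) {
  z <- as_z_matrix(data)
  n <- nrow(z)
  d <- ncol(z)
  if (n <= d) stop("data augmentation requires n > number of variables", call. = FALSE)
  if (is.null(start)) start <- em_start(data)
  pats <- mvn_patterns(z)
  pats <- pats[vapply(pats, function(p) length(p$mis) > 0L, logical(1))]
  take_at <- spec$burn_in + (seq_len(spec$m) - 1L) * spec$between
  z[is.na(z)] <- 0 # overwritten in the first I-step before any read
  snaps <- da_chain_cpp(z, pats, start$mu, start$sigma, as.integer(take_at))
  completed <- lapply(snaps, function(zz) {
    tibble::tibble(y = zz[, 1], x1 = zz[, 2], x2 = zz[, 3])
  })
  new_impset(completed, data$miss_y, data$miss_x2, "MVNI")
}

#' Adaptive rounding of continuously imputed binary values
#'
#' Rounds continuous imputations of a binary variable using the threshold
#' derived from the normal approximation to a proportion: with
#' `w = mean(completed_variable)`, the cut-point is
#' `c = w - qnorm(w) * sqrt(w * (1 - w))` and values at or above `c` round
#' to 1. If `w` lies outside (0, 1) the column is constant and that constant
#' is returned for every value.
#'
#' @param values Continuous imputed values to round.
#' @param completed_variable The full completed column (observed 0/1 plus
#'   continuous imputations) from which the rounding threshold is computed.
#' @return A 0/1 vector the length of `values`.
#' @export
adaptive_round <- function(values, completed_variable) {
  w <- mean(completed_variable)
  if (w <= 0) return(rep(0, length(values)))
  if (w >= 1) return(rep(1, length(values)))
  cut <- w - stats::qnorm(w) * sqrt(w * (1 - w))
  as.numeric(values >= cut)
}

#' Simple rounding at one half
#'
#' Values at or above 0.5 round to 1, all others to 0 (ties round up).
#'
#' @param values Continuous imputed values.
#' @return A 0/1 vector.
#' @export
simple_round <- function(values) {
  as.numeric(values >= 0.5)
}

#' Multivariate normal imputation with rounding of binary variables
#'
#' Runs [da_impute()] and then rounds the continuously imputed cells of the
#' binary variables back to 0/1: always the outcome `Y`, and also `X2` when
#' the exposures are binary (without which downstream log binomial fits
#' fail). The rounding rule is `spec$rounding` (`"adaptive"` by default,
#' `"simple"` as a sensitivity option); adaptive thresholds are computed
#' from each completed dataset's own column. Observed cells are never
#' altered.
#'
#' @inheritParams da_impute
#' @return An `rrmi_impset` with analysis-ready completed datasets.
#' @export
mvni_impute <- function(data, spec, start = NULL) {
  imp <- da_impute(data, spec, start = start)
  rounder <- switch(spec$rounding,
    adaptive = function(v, col) adaptive_round(v, col),
    simple = function(v, col) simple_round(v)
  )
  imp$completed <- lapply(imp$completed, function(dd) {
    if (any(imp$imputed_y_mask)) {
      dd$y[imp$imputed_y_mask] <- rounder(dd$y[imp$imputed_y_mask], dd$y)
    }
    if (spec$exposure_type == "binary" && any(imp$imputed_x2_mask)) {
      dd$x2[imp$imputed_x2_mask] <- rounder(dd$x2[imp$imputed_x2_mask], dd$x2)
    }
    dd
  })
  imp
}
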