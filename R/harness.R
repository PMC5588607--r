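# Simulation harness: per-replicate pipeline, replicate-level bookkeeping,
# performance metrics and grid orchestration.

#' Derive per-replicate random seeds from a master seed
#'
#' One master seed per run; child seeds are drawn deterministically so any
#' single replicate can be reproduced in isolation by re-seeding with its
#' child seed.
#'
#' @param master Master integer seed.
#' @param reps Number of replicates.
#' @param scenario_id Optional scenario index mixed into the stream so
#'   scenarios in a grid get distinct seed sequences.
#' @return Integer vector of `reps` seeds.
#' @export
replicate_seeds <- function(master, reps, scenario_id = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((as.numeric(master) + 7919 * (as.numeric(scenario_id) - 1)) %%
             .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, reps)
}

rr_methods <- c("MVNI", "MVNI_MID", "FCS", "FCS_MID", "CCA")

#' Run one simulation replicate
#'
#' Generates one complete dataset, imposes missingness, and computes the
#' requested method results: `"COMPLETE"` (the analysis model on the
#' pre-missingness data, the verification reference), `"CCA"`, and pooled
#' `"FCS"`, `"FCS_MID"`, `"MVNI"`, `"MVNI_MID"`. Failures within a method
#' (e.g. persistent imputation-model breakdown) flag that method's rows
#' rather than aborting the replicate.
#'
#' @param spec An [scenario_spec()] object.
#' @param calib Calibration from [calibrate()].
#' @param methods Character vector of methods to run.
#' @param seed Optional integer seed set before generation.
#' @return A tibble with columns `method`, `term`, `estimate`, `std_error`,
#'   `ci_low`, `ci_high`, `estimator`, `ok`.
#' @export
run_replicate <- function(spec, calib, methods = rr_methods, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  complete <- generate_complete(spec, calib$beta0)
  needs_missingness <- any(methods != "COMPLETE")
  data <- if (needs_missingness) {
    apply_missingness(complete, spec, calib$alpha)
  }

  zq <- stats::qnorm(0.975)
  row_block <- function(method, term, estimate, std_error, ci_low, ci_high,
                        estimator, ok) {
    tibble::new_tibble(
      list(method = rep(method, length(term)), term = term,
           estimate = estimate, std_error = std_error, ci_low = ci_low,
           ci_high = ci_high, estimator = rep(estimator, length(term)),
           ok = rep_len(ok, length(term))),
      nrow = length(term)
    )
  }
  fit_rows <- function(method, fit) {
    est <- unname(fit$estimates)
    se <- unname(fit$std_errors)
    row_block(method, names(fit$estimates), est, se,
              est - zq * se, est + zq * se, fit$estimator,
              fit$converged & is.finite(se))
  }
  pooled_rows <- function(method, pooled) {
    row_block(method, names(pooled$estimates), unname(pooled$estimates),
              unname(sqrt(pooled$total_variance)), unname(pooled$ci_low),
              unname(pooled$ci_high),
              paste(unique(pooled$estimators), collapse = "+"), TRUE)
  }
  failed_rows <- function(method) {
    row_block(method, c("(Intercept)", "x1", "x2"), rep(NA_real_, 3),
              rep(NA_real_, 3), rep(NA_real_, 3), rep(NA_real_, 3),
              NA_character_, FALSE)
  }
  run_method <- function(method, fun) {
    tryCatch(fun(), error = function(e) failed_rows(method))
  }

  out <- list()
  if ("COMPLETE" %in% methods) {
    out$complete <- run_method("COMPLETE", function() {
      fit_rows("COMPLETE", choose_analysis(complete, spec$exposure_type))
    })
  }
  if ("CCA" %in% methods) {
    out$cca <- run_method("CCA", function() {
      fit_rows("CCA", cca_fit(data, spec$exposure_type))
    })
  }
  if (any(c("FCS", "FCS_MID") %in% methods)) {
    imp <- tryCatch(fcs_impute(data, spec), error = function(e) NULL)
    if ("FCS" %in% methods) {
      out$fcs <- if (is.null(imp)) failed_rows("FCS") else {
        run_method("FCS", function() {
          pooled_rows("FCS", analyse_imputations(imp, spec$exposure_type))
        })
      }
    }
    if ("FCS_MID" %in% methods) {
      out$fcs_mid <- if (is.null(imp)) failed_rows("FCS_MID") else {
        run_method("FCS_MID", function() {
          pooled_rows("FCS_MID",
                      analyse_imputations(delete_imputed_outcomes(imp),
                                          spec$exposure_type))
        })
      }
    }
  }
  if (any(c("MVNI", "MVNI_MID") %in% methods)) {
    imp <- tryCatch(mvni_impute(data, spec), error = function(e) NULL)
    if ("MVNI" %in% methods) {
      out$mvni <- if (is.null(imp)) failed_rows("MVNI") else {
        run_method("MVNI", function() {
          pooled_rows("MVNI", analyse_imputations(imp, spec$exposure_type))
        })
      }
    }
    if ("MVNI_MID" %in% methods) {
      out$mvni_mid <- if (is.null(imp)) failed_rows("MVNI_MID") else {
        run_method("MVNI_MID", function() {
          pooled_rows("MVNI_MID",
                      analyse_imputations(delete_imputed_outcomes(imp),
                                          spec$exposure_type))
        })
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Run all replicates of one scenario
#'
#' Calibrates the scenario once, then runs `reps` independent replicates
#' with deterministic per-replicate seeds derived from the master seed.
#'
#' @param spec An [scenario_spec()] object.
#' @param reps Number of replicates (defaults to `spec$reps`).
#' @param methods Methods to run (see [run_replicate()]).
#' @param seed Master seed (defaults to `spec$seed`).
#' @param scenario_id Index mixed into the seed stream (for grids).
#' @param progress Emit a progress message to stderr every `progress`
#'   replicates (0 = silent).
#' @return A tibble of per-replicate results with a `rep` column; the
#'   calibration is attached as attribute `calibration`.
#' @export
run_scenario <- function(spec, reps = spec$reps, methods = rr_methods,
                         seed = spec$seed, scenario_id = 1L, progress = 0) {
  calib <- calibrate(spec)
  seeds <- replicate_seeds(seed, reps, scenario_id)
  res <- purrr::map(seq_len(reps), function(r) {
    if (progress > 0 && r %% progress == 0) {
      message(sprintf("scenario %s: replicate %d/%d", scenario_id, r, reps))
    }
    out_r <- run_replicate(spec, calib, methods = methods, seed = seeds[r])
    out_r$rep <- r
    out_r
  })
  out <- dplyr::bind_rows(res)
  attr(out, "calibration") <- calib
  out
}

#' Summarise replicate-level results into performance metrics
#'
#' Per method and parameter: bias (mean estimate minus truth), average
#' model-based standard error, empirical standard error (SD of estimates
#' across replicates), coverage of the 95% intervals, and mean square
#' error, with Monte Carlo standard errors for bias
#' (`emp_se / sqrt(reps)`) and coverage (`sqrt(c(1 - c)/reps)`). Replicates
#' flagged as failed for a method are excluded from that method's metrics
#' and counted in `reps_flagged`.
#'
#' @param results Replicate-level tibble from [run_scenario()].
#' @param true_beta Named vector of true coefficient values, e.g.
#'   `c(x1 = log(2), x2 = log(2))`; terms absent from it are dropped.
#' @return A tibble of class `rrmi_summary`.
#' @export
summarize_replicates <- function(results, true_beta) {
  truth <- tibble::tibble(term = names(true_beta), true = unname(true_beta))
  out <- results |>
    dplyr::inner_join(truth, by = "term") |>
    dplyr::group_by(.data$method, .data$term) |>
    dplyr::summarise(
      reps_completed = sum(.data$ok),
      reps_flagged = sum(!.data$ok),
      bias = mean(.data$estimate[.data$ok]) - .data$true[1],
      avg_se = mean(.data$std_error[.data$ok]),
      emp_se = stats::sd(.data$estimate[.data$ok]),
      coverage = mean(.data$ci_low[.data$ok] <= .data$true[1] &
                        .data$ci_high[.data$ok] >= .data$true[1]),
      mse = mean((.data$estimate[.data$ok] - .data$true[1])^2),
      mc_se_bias = .data$emp_se / sqrt(.data$reps_completed),
      mc_se_coverage = sqrt(.data$coverage * (1 - .data$coverage) /
                              .data$reps_completed),
      .groups = "drop"
    )
  class(out) <- c("rrmi_summary", class(out))
  out
}

#' Run a grid of scenarios
#'
#' Iterates over a scenario grid (from [scenario_grid()] or
#' [read_scenario_config()]), running and summarising each scenario.
#' Per-scenario failures are logged to stderr and skipped.
#'
#' @param grid A tibble with columns `scenario_id` and `spec`.
#' @param reps Replicates per scenario (default: each spec's own `reps`).
#' @param methods Methods to run.
#' @param seed Master seed shared by the grid (default: each spec's own).
#' @param progress Per-scenario progress messages (see [run_scenario()]).
#' @return A tidy tibble: scenario descriptors + method + term + metrics,
#'   of class `rrmi_summary`.
#' @export
run_grid <- function(grid, reps = NULL, methods = rr_methods, seed = NULL,
                     progress = 0) {
  rows <- purrr::pmap(list(grid$scenario_id, grid$spec), function(id, spec) {
    res <- tryCatch({
      raw <- run_scenario(spec, reps = reps %||% spec$reps, methods = methods,
                          seed = seed %||% spec$seed, scenario_id = id,
                          progress = progress)
      summarize_replicates(raw, c(x1 = spec$beta1, x2 = spec$beta2))
    }, error = function(e) {
      message(sprintf("scenario %s failed: %s", id, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) return(NULL)
    dplyr::bind_cols(
      tibble::tibble(
        scenario_id = id, exposure_type = spec$exposure_type,
        prevalence = spec$prevalence, assoc = spec$assoc,
        beta1 = spec$beta1, beta2 = spec$beta2,
        mechanism = spec$mechanism, lambda = spec$lambda
      )[rep(1, nrow(res)), ],
      res
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rrmi_summary", class(out))
  out
}
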