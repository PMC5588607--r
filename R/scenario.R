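#' Define a simulation scenario
#'
#' A scenario fully parameterises one cell of the simulation study: the
#' data-generating log binomial model `log P(Y = 1) = b0 + b1*X1 + b2*X2`,
#' the joint distribution of the two exposures, the missing-data mechanism
#' imposed on `Y` and `X2`, and the multiple-imputation settings used to
#' handle it.
#'
#' Exposures are either binary (each with marginal prevalence 0.50 and a
#' confounding association expressed as the risk ratio `RR(X1, X2)`) or
#' bivariate normal with mean 0, variance 0.20 and correlation `assoc`.
#' The intercept `b0` and the missingness intercept `alpha` are not part of
#' the scenario: they are calibrated from it by [calibrate()] so that the
#' outcome prevalence and the per-variable missingness proportion hit their
#' targets.
#'
#' @param exposure_type `"binary"` or `"continuous"`.
#' @param prevalence Target marginal outcome prevalence, in (0, 1).
#' @param beta1,beta2 Conditional log relative risks for `X1` and `X2`.
#' @param assoc Exposure association: for binary exposures the risk ratio
#'   `P(X2 = 1 | X1 = 1) / P(X2 = 1 | X1 = 0)` (>= 1); for continuous
#'   exposures the correlation (|assoc| < 1).
#' @param mechanism Missing-data mechanism for `Y` and `X2`:
#'   `"coordinated"` (both depend on `X1` in the same direction),
#'   `"opposite"` (opposing directions), `"y_only"` / `"x2_only"`
#'   (missingness restricted to one variable), or `"mcar"`.
#' @param lambda Strength of the dependence of missingness on `X1`
#'   (0 = MCAR, 1 = moderate, 2 = strong).
#' @param missing_prop Target per-variable missingness proportion, in (0, 1).
#' @param n Sample size per simulated dataset.
#' @param reps Number of simulation replicates.
#' @param m Number of imputations per incomplete dataset.
#' @param cycles Chained-equation cycles per imputation (FCS).
#' @param order Order of the univariate models within an FCS cycle:
#'   `"outcome_last"` (default) imputes `X2` then `Y`; `"outcome_first"`
#'   reverses this.
#' @param burn_in Data-augmentation burn-in iterations before the first
#'   imputation is taken (MVNI).
#' @param between Data-augmentation iterations between successive
#'   imputations (MVNI).
#' @param rounding Rounding rule applied to continuously imputed binary
#'   variables after MVNI: `"adaptive"` (default) or `"simple"`.
#' @param coupled_masks If `TRUE`, the coordinated mechanism uses a single
#'   uniform draw per row so that `Y` and `X2` are missing together;
#'   the default draws the two indicators independently with equal
#'   probabilities.
#' @param seed Master random seed for the scenario.
#'
#' @return An object of class `rrmi_scenario` (a named list).
#' @examples
#' spec <- scenario_spec("binary", prevalence = 0.3, beta1 = log(3),
#'                       beta2 = log(3), assoc = 2,
#'                       mechanism = "coordinated", lambda = 2)
#' @export
scenario_spec <- function(exposure_type = c("binary", "continuous"),
                          prevalence = 0.30,
                          beta1 = log(2),
                          beta2 = log(2),
                          assoc = if (match.arg(exposure_type) == "binary") 2 else 0.3,
                          mechanism = c("coordinated", "opposite", "y_only",
                                        "x2_only", "mcar"),
                          lambda = 1,
                          missing_prop = 0.30,
                          n = 1000,
                          reps = 2000,
                          m = 20,
                          cycles = 20,
                          order = c("outcome_last", "outcome_first"),
                          burn_in = 200,
                          between = 100,
                          rounding = c("adaptive", "simple"),
                          coupled_masks = FALSE,
                          seed = 20170906L) {
  exposure_type <- match.arg(exposure_type)
  mechanism <- match.arg(mechanism)
  order <- match.arg(order)
  rounding <- match.arg(rounding)
  stopifnot(
    prevalence > 0, prevalence < 1,
    missing_prop > 0, missing_prop < 1,
    n >= 4, m >= 2, reps >= 1,
    lambda >= 0, cycles >= 0, burn_in >= 1, between >= 1
  )
  if (exposure_type == "binary" && assoc < 1) {
    stop("for binary exposures `assoc` is a risk ratio and must be >= 1",
         call. = FALSE)
  }
  if (exposure_type == "continuous" && abs(assoc) >= 1) {
    stop("for continuous exposures `assoc` is a correlation and must satisfy |assoc| < 1",
         call. = FALSE)
  }
  if (mechanism == "mcar") lambda <- 0
  structure(
    list(
      exposure_type = exposure_type, prevalence = prevalence,
      beta1 = beta1, beta2 = beta2, assoc = assoc,
      mechanism = mechanism, lambda = lambda, missing_prop = missing_prop,
      n = as.integer(n), reps = as.integer(reps), m = as.integer(m),
      cycles = as.integer(cycles), order = order,
      burn_in = as.integer(burn_in), between = as.integer(between),
      rounding = rounding, coupled_masks = coupled_masks,
      seed = as.integer(seed)
    ),
    class = "rrmi_scenario"
  )
}

#' @export
print.rrmi_scenario <- function(x, ...) {
  cat("<rrmi_scenario>\n")
  cat(sprintf("  exposures: %s (assoc = %s)\n", x$exposure_type, format(x$assoc)))
  cat(sprintf("  model: log P(Y=1) = b0 + %.4f*X1 + %.4f*X2, prevalence %.2f\n",
              x$beta1, x$beta2, x$prevalence))
  cat(sprintf("  missingness: %s, lambda = %s, target %.0f%% per variable\n",
              x$mechanism, format(x$lambda), 100 * x$missing_prop))
  cat(sprintf("  n = %d, reps = %d, m = %d, cycles = %d (%s), burn-in = %d, between = %d\n",
              x$n, x$reps, x$m, x$cycles, x$order, x$burn_in, x$between))
  invisible(x)
}

#' Scenario grids for the two simulation studies
#'
#' Build the full factorial grid of simulation scenarios: outcome prevalence
#' {0.10, 0.30} x exposure association {2, 3} (binary risk ratio) or
#' {0.30, 0.70} (continuous correlation) x effect size {log 2, log 3}
#' (applied to both exposures) x mechanism {coordinated, opposite} x
#' lambda {1, 2} - 32 scenarios per exposure type.
#'
#' @param exposure_type `"binary"` or `"continuous"`.
#' @param ... Scenario fields (e.g. `n`, `reps`, `m`, `seed`) passed on to
#'   [scenario_spec()], overriding its defaults for every row.
#' @return A tibble with one row per scenario, a `scenario_id` column, and a
#'   list-column `spec` of `rrmi_scenario` objects.
#' @export
scenario_grid <- function(exposure_type = c("binary", "continuous"), ...) {
  exposure_type <- match.arg(exposure_type)
  assoc_vals <- if (exposure_type == "binary") c(2, 3) else c(0.3, 0.7)
  grid <- tidyr::expand_grid(
    prevalence = c(0.10, 0.30),
    assoc = assoc_vals,
    beta = c(log(2), log(3)),
    mechanism = c("coordinated", "opposite"),
    lambda = c(1, 2)
  )
  dots <- list(...)
  grid |>
    dplyr::mutate(
      scenario_id = dplyr::row_number(),
      spec = purrr::pmap(
        list(.data$prevalence, .data$assoc, .data$beta, .data$mechanism, .data$lambda),
        function(p, a, b, mech, l) {
          do.call(scenario_spec, c(
            list(exposure_type = exposure_type, prevalence = p, beta1 = b,
                 beta2 = b, assoc = a, mechanism = mech, lambda = l),
            dots
          ))
        }
      )
    ) |>
    dplyr::relocate("scenario_id")
}

#' Read a scenario grid from a YAML configuration file
#'
#' The file lists the levels of each factor plus shared settings; the
#' Cartesian product of the factor levels defines the grid. Recognised keys:
#' `exposure_type`, `prevalence`, `assoc`, `beta`, `mechanism`, `lambda`
#' (each scalar or list), and scalar overrides for `missing_prop`, `n`,
#' `reps`, `m`, `cycles`, `order`, `burn_in`, `between`, `rounding`, `seed`.
#'
#' @param path Path to a YAML file.
#' @return A tibble like [scenario_grid()]'s.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$exposure_type))
  factors <- tidyr::expand_grid(
    prevalence = as.numeric(cfg$prevalence %||% 0.30),
    assoc = as.numeric(cfg$assoc %||% if (cfg$exposure_type == "binary") 2 else 0.3),
    beta = as.numeric(cfg$beta %||% log(2)),
    mechanism = as.character(cfg$mechanism %||% "coordinated"),
    lambda = as.numeric(cfg$lambda %||% 1)
  )
  scalars <- cfg[intersect(names(cfg),
                           c("missing_prop", "n", "reps", "m", "cycles", "order",
                             "burn_in", "between", "rounding", "seed"))]
  factors |>
    dplyr::mutate(
      scenario_id = dplyr::row_number(),
      spec = purrr::pmap(
        list(.data$prevalence, .data$assoc, .data$beta, .data$mechanism, .data$lambda),
        function(p, a, b, mech, l) {
          do.call(scenario_spec, c(
            list(exposure_type = cfg$exposure_type, prevalence = p,
                 beta1 = b, beta2 = b, assoc = a, mechanism = mech, lambda = l),
            scalars
          ))
        }
      )
    ) |>
    dplyr::relocate("scenario_id")
}
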