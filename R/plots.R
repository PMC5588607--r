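# ggplot2 displays for scenario summaries.

#' Plot bias by method and parameter
#'
#' Dot-and-error-bar display of Monte Carlo bias with +/- 2 Monte Carlo
#' standard error bars, faceted by parameter (and scenario when a grid
#' summary is supplied).
#'
#' @param object An `rrmi_summary` tibble (from [summarize_replicates()] or
#'   [run_grid()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rrmi_summary <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$method, y = .data$bias)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$bias - 2 * .data$mc_se_bias,
      ymax = .data$bias + 2 * .data$mc_se_bias
    )) +
    ggplot2::labs(x = NULL, y = "bias (log relative risk scale)") +
    ggplot2::theme_minimal()
  if ("scenario_id" %in% names(object)) {
    p + ggplot2::facet_grid(scenario_id ~ term)
  } else {
    p + ggplot2::facet_wrap(~term)
  }
}

#' Plot coverage by method and parameter
#'
#' Coverage of nominal 95% intervals with +/- 2 Monte Carlo standard error
#' bars and the nominal level marked.
#'
#' @param summary An `rrmi_summary` tibble.
#' @return A ggplot object.
#' @export
plot_coverage <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$method, y = .data$coverage)) +
    ggplot2::geom_hline(yintercept = 0.95, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$coverage - 2 * .data$mc_se_coverage,
      ymax = .data$coverage + 2 * .data$mc_se_coverage
    )) +
    ggplot2::facet_wrap(~term) +
    ggplot2::labs(x = NULL, y = "coverage of nominal 95% intervals") +
    ggplot2::theme_minimal()
}
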