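# ggplot2 visualisations for fits and studies.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot fitted item response probabilities
#'
#' Tile map of the class-conditional success probability of every item for
#' every latent group, a quick visual check of monotonicity and item
#' quality.
#'
#' @param object A [fit_cdm()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cdm_fit
#' @export
autoplot.cdm_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mastered, y = .data$item,
                                  fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 limits = c(0, 1)) +
    ggplot2::facet_grid(cols = ggplot2::vars(nchar(.data$mastered)),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "mastered required attributes (latent group)",
                  y = NULL, fill = "P(correct)",
                  title = "Fitted item response probabilities")
}

#' Plot rejection rates of a study
#'
#' Rejection rate per method with its Monte Carlo confidence interval; the
#' dashed line marks the nominal significance level, the reference under a
#' true hierarchy (Type I error) but not for power.
#'
#' @param object A `cdm_study` from [run_condition()], or a combined
#'   results tibble from [hierarchy_study()] passed through
#'   `plot_rejection_rates()`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cdm_study
#' @export
autoplot.cdm_study <- function(object, ...) {
  plot_rejection_rates(object$results, alpha = object$design$alpha)
}

#' @rdname autoplot.cdm_study
#' @param results Long results tibble (one row per condition x method).
#' @param alpha Nominal level drawn as a reference line.
#' @export
plot_rejection_rates <- function(results, alpha = 0.05) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = factor(.data$N), y = .data$rate,
                               colour = .data$method, group = .data$method)) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lower,
                                          ymax = .data$ci_upper),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$quality),
                        cols = ggplot2::vars(.data$hierarchy)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "sample size N", y = "rejection rate",
                  colour = "method")
}
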