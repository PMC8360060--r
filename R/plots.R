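# ggplot2 diagnostics: trace/density panels for fits, posterior
# predictive check panels, and CPO comparison plots.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot posterior draws of a fitted model
#'
#' Trace plots (one panel per parameter, colored by chain) or marginal
#' posterior densities.
#'
#' @param object an [fbb_fit()] object.
#' @param type `"trace"` or `"density"`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot fbb_fit
#' @export
autoplot.fbb_fit <- function(object, type = c("trace", "density"), ...) {
  type <- match.arg(type)
  long <- tidyr::pivot_longer(object$draws, cols = -c(".chain", ".iter"),
                              names_to = "term", values_to = "value")
  long$.chain <- factor(long$.chain)
  if (type == "trace") {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$.iter, y = .data$value,
                                       color = .data$.chain)) +
      ggplot2::geom_line(linewidth = 0.2) +
      ggplot2::facet_wrap(~term, scales = "free_y") +
      ggplot2::labs(x = "retained iteration", y = NULL, color = "chain")
  } else {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$value, color = .data$.chain)) +
      ggplot2::geom_density() +
      ggplot2::facet_wrap(~term, scales = "free") +
      ggplot2::labs(x = NULL, color = "chain")
  }
}

#' Plot posterior predictive check results
#'
#' One panel per discrepancy measure: the distribution of the replicated
#' statistic with the observed value marked, annotated with the
#' posterior predictive p-value.
#'
#' @param ppc a tibble from [ppc_check()].
#' @return a ggplot object.
#' @export
plot_ppc <- function(ppc) {
  long <- tidyr::unnest(ppc, "replicates")
  lab <- ppc |>
    dplyr::mutate(stat = sprintf("%s (p = %.2f)", .data$stat, .data$p_value))
  long <- dplyr::left_join(long,
    dplyr::transmute(ppc, .data$stat, label = lab$stat), by = "stat")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$replicates)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$observed),
                        color = "red3", linewidth = 0.6) +
    ggplot2::facet_wrap(~label, scales = "free") +
    ggplot2::labs(x = "replicated statistic", y = "count")
}

#' Compare conditional predictive ordinates across models
#'
#' Plots log CPO per observation for several fitted models, typically to
#' compare how each family accommodates flagged or contaminated
#' observations (higher is better).
#'
#' @param ... named [fbb_fit()] objects.
#' @param observations optional integer vector restricting the plot to
#'   specific observations (e.g. known contaminated units).
#' @return a ggplot object.
#' @export
plot_cpo <- function(..., observations = NULL) {
  fits <- list(...)
  stopifnot(length(fits) >= 1, !is.null(names(fits)), all(nzchar(names(fits))))
  long <- purrr::imap_dfr(fits, function(f, nm) {
    dplyr::mutate(cpo(f), model = nm)
  })
  if (!is.null(observations)) {
    long <- dplyr::filter(long, .data$observation %in% observations)
  }
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$observation),
                                     y = .data$log_cpo,
                                     color = .data$model,
                                     shape = .data$model)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "observation", y = "log CPO", color = NULL, shape = NULL)
}
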