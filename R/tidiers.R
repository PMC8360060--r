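# broom-style tidiers for fitted models and replication tables.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted count-regression model
#'
#' One row per parameter: posterior mean, posterior standard deviation,
#' equal-tailed credible bounds and a flag for credible sets excluding
#' zero.
#'
#' @param x an [fbb_fit()] object.
#' @param conf.level credible level (default 0.95).
#' @param ... unused.
#' @return a tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `significant`.
#' @method tidy fbb_fit
#' @export
tidy.fbb_fit <- function(x, conf.level = 0.95, ...) {
  ps <- posterior_summary(x, level = conf.level)
  tibble::tibble(term = ps$term, estimate = ps$mean, std.error = ps$sd,
                 conf.low = ps$lower, conf.high = ps$upper,
                 significant = ps$significant)
}

#' Glance at a fitted count-regression model
#'
#' One-row fit summary: sample size, retained draws, WAIC decomposition,
#' the CPO-based leave-one-out criterion, and the mean post-warmup
#' acceptance rate.
#'
#' @inheritParams tidy.fbb_fit
#' @return a one-row tibble with columns `nobs`, `n_draws`, `lppd`,
#'   `p_waic`, `waic`, `looic`, `accept_rate`.
#' @method glance fbb_fit
#' @export
glance.fbb_fit <- function(x, ...) {
  w <- waic(x)
  lo <- loo_estimate(x)
  tibble::tibble(nobs = length(x$data$y), n_draws = nrow(x$draws),
                 lppd = w$lppd, p_waic = w$p_waic, waic = w$waic,
                 looic = lo$looic, accept_rate = mean(x$accept_rate))
}

#' Tidy a replication study
#'
#' Returns the per-model, per-parameter bias/MSE/coverage summary of a
#' [run_replications()] result as a tibble.
#'
#' @param x an `fbb_replication` object.
#' @param ... unused.
#' @method tidy fbb_replication
#' @export
tidy.fbb_replication <- function(x, ...) x$summary

#' @rdname tidy.fbb_replication
#' @method glance fbb_replication
#' @export
glance.fbb_replication <- function(x, ...) {
  x$summary |>
    dplyr::distinct(.data$model, .data$mean_waic) |>
    dplyr::mutate(R = x$config$R, failures = nrow(x$failures))
}
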