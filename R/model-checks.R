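# Bayesian model comparison and checking: WAIC, leave-one-out style CPO,
# and posterior predictive checks with discrepancy measures. All of them
# work off the B x N per-draw per-observation log-likelihood matrix that
# every fbb_fit stores.

.col_log_mean_exp <- function(mat) {
  # log of column means of exp(mat), stable
  M <- apply(mat, 2, max)
  log(colMeans(exp(sweep(mat, 2, M)))) + M
}

.as_loglik <- function(x) {
  if (inherits(x, "fbb_fit")) x$loglik
  else if (is.matrix(x)) x
  else stop("`x` must be an fbb_fit or a B x N log-likelihood matrix", call. = FALSE)
}

#' Widely applicable information criterion
#'
#' Computes the log pointwise posterior predictive density
#' `lppd = sum_i log mean_b f(y_i | eta^(b))` (column-wise log-sum-exp),
#' the effective number of parameters
#' `p_waic = sum_i Var_b log f(y_i | eta^(b))` (unbiased sample
#' variance), and `WAIC = -2 (lppd - p_waic)` on the deviance scale
#' (lower is better).
#'
#' @param x an `fbb_fit` or a B x N matrix of per-draw per-observation
#'   log-likelihoods (B >= 2 draws).
#' @return a tibble with columns `lppd`, `p_waic`, `waic`.
#' @examples
#' ll <- matrix(log(c(0.2, 0.8)), 2, 1)
#' waic(ll)
#' @export
waic <- function(x) {
  ll <- .as_loglik(x)
  if (!all(is.finite(ll))) stop("log-likelihood matrix has non-finite entries", call. = FALSE)
  if (nrow(ll) < 2) stop("WAIC needs at least 2 draws", call. = FALSE)
  lppd <- sum(.col_log_mean_exp(ll))
  p_waic <- sum(apply(ll, 2, stats::var))
  tibble::tibble(lppd = lppd, p_waic = p_waic, waic = -2 * (lppd - p_waic))
}

#' Conditional predictive ordinates
#'
#' The CPO of observation i is its leave-one-out predictive density,
#' estimated by the harmonic mean of the per-draw likelihoods:
#' `CPO_i = B / sum_b 1 / f(y_i | eta^(b))`, computed stably as
#' `log CPO_i = log B - logsumexp_b(-ll_bi)`. Observations that are
#' impossible under some draw (a `-Inf` log-likelihood) get `CPO_i = 0`
#' with a warning. Small values flag observations the model finds
#' unlikely; `flag_threshold` marks candidates (default 0.01).
#'
#' @inheritParams waic
#' @param flag_threshold natural-scale CPO below which an observation is
#'   flagged as an outlier candidate.
#' @return a tibble with columns `observation`, `log_cpo`, `cpo`,
#'   `flagged`.
#' @examples
#' cpo(matrix(log(c(0.5, 0.25)), 2, 1)) # harmonic mean 1/3
#' @export
cpo <- function(x, flag_threshold = 0.01) {
  ll <- .as_loglik(x)
  B <- nrow(ll)
  bad <- apply(ll, 2, function(v) any(v == -Inf))
  log_cpo <- log(B) - apply(-ll, 2, function(v) {
    M <- max(v)
    if (!is.finite(M)) return(Inf)
    M + log(sum(exp(v - M)))
  })
  if (any(bad)) {
    warning(sprintf("%d observation(s) impossible under some draw; CPO set to 0",
                    sum(bad)), call. = FALSE)
    log_cpo[bad] <- -Inf
  }
  tibble::tibble(observation = seq_len(ncol(ll)), log_cpo = log_cpo,
                 cpo = exp(log_cpo), flagged = exp(log_cpo) < flag_threshold)
}

#' Leave-one-out predictive criterion from CPO
#'
#' Sums the log conditional predictive ordinates into an estimate of the
#' expected log leave-one-out predictive density, and reports it on the
#' deviance scale (`looic = -2 * elpd_loo`) for direct comparison with
#' [waic()]; on well-behaved fits the two agree closely.
#'
#' @inheritParams waic
#' @return a tibble with columns `elpd_loo`, `looic`.
#' @export
loo_estimate <- function(x) {
  lc <- cpo(x)$log_cpo
  tibble::tibble(elpd_loo = sum(lc), looic = -2 * sum(lc))
}

# draw one replicated response vector at natural-scale parameters
.sample_response <- function(family, n, mu, extras) {
  N <- length(mu)
  switch(family,
    binomial = stats::rbinom(N, n, mu),
    betabinomial = {
      phi <- 1 / extras[["theta"]] - 1
      stats::rbinom(N, n, stats::rbeta(N, phi * mu, phi * (1 - mu)))
    },
    fbb = {
      phi <- 1 / extras[["theta"]] - 1
      w <- extras[["w"]]; p <- extras[["p"]]
      d <- w * pmin(mu / p, (1 - mu) / (1 - p))
      lam <- ifelse(stats::runif(N) < p, mu + (1 - p) * d, mu - p * d)
      stats::rbinom(N, n, stats::rbeta(N, phi * lam, phi * (1 - lam)))
    },
    zibinomial = {
      y <- stats::rbinom(N, n, mu)
      y[stats::runif(N) < extras[["q"]]] <- 0L
      y
    },
    zibetabinomial = {
      phi <- 1 / extras[["theta"]] - 1
      y <- stats::rbinom(N, n, stats::rbeta(N, phi * mu, phi * (1 - mu)))
      y[stats::runif(N) < extras[["q"]]] <- 0L
      y
    }
  )
}

.draw_params <- function(fit, b) {
  k <- ncol(fit$data$X)
  beta <- as.numeric(fit$eta[b, seq_len(k)])
  extras <- stats::plogis(fit$eta[b, -seq_len(k)])
  names(extras) <- fit$model$extras
  list(beta = beta, extras = extras,
       mu = fit$model$link$linkinv(drop(fit$data$X %*% beta)))
}

#' Posterior predictive replicates
#'
#' For each retained posterior draw, one replicated response vector from
#' the fitted model's sampling distribution at that draw.
#'
#' @param fit an [fbb_fit()] object.
#' @param ndraws number of draws to use (default: all retained draws,
#'   subsampled evenly if fewer are requested).
#' @param seed optional integer seed.
#' @return an integer matrix with one row per draw and one column per
#'   observation.
#' @export
posterior_predictive <- function(fit, ndraws = NULL, seed = NULL) {
  stopifnot(inherits(fit, "fbb_fit"))
  if (!is.null(seed)) set.seed(seed)
  B <- nrow(fit$eta)
  idx <- if (is.null(ndraws) || ndraws >= B) seq_len(B)
         else round(seq(1, B, length.out = ndraws))
  out <- matrix(0L, length(idx), length(fit$data$y))
  for (j in seq_along(idx)) {
    pp <- .draw_params(fit, idx[j])
    out[j, ] <- .sample_response(fit$model$family, fit$data$n, pp$mu, pp$extras)
  }
  out
}

#' Posterior predictive p-value of a discrepancy
#'
#' The fraction of replicates whose discrepancy meets or exceeds the
#' observed one, `P(T(y_rep) >= T(y) | y)`; values near 0.5 indicate the
#' model reproduces that feature of the data well, values near 0 or 1 a
#' systematic misfit.
#'
#' @param observed observed discrepancy: a scalar, or one value per
#'   replicate for discrepancies that depend on the parameter draw.
#' @param replicates vector of replicated discrepancies.
#' @return scalar p-value in `[0, 1]`.
#' @export
ppc_pvalue <- function(observed, replicates) {
  stopifnot(length(replicates) >= 1)
  mean(replicates >= observed)
}

#' Posterior predictive checks
#'
#' Runs the standard discrepancy measures over replicated datasets drawn
#' from the posterior predictive distribution: the mean and variance of
#' the response, the proportion of zero counts, and the deviance
#' `-2 sum_i log f(y_i; eta^(b))` (which is compared draw-by-draw against
#' the deviance of the replicate under the same draw). Statistics are
#' accumulated per draw without materializing all replicated datasets.
#'
#' @inheritParams posterior_predictive
#' @param stats character vector among `"mean"`, `"variance"`, `"zeros"`,
#'   `"deviance"`.
#' @return a tibble with one row per discrepancy: `stat`, `observed`
#'   (averaged over draws for the deviance), `p_value`, and a
#'   list-column `replicates` of the B replicated statistics.
#' @export
ppc_check <- function(fit, stats = c("mean", "variance", "zeros", "deviance"),
                      ndraws = NULL, seed = NULL) {
  stopifnot(inherits(fit, "fbb_fit"))
  stats <- match.arg(stats, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  B <- nrow(fit$eta)
  idx <- if (is.null(ndraws) || ndraws >= B) seq_len(B)
         else round(seq(1, B, length.out = ndraws))
  y <- fit$data$y; n <- fit$data$n
  acc <- lapply(stats, function(s) list(obs = numeric(length(idx)),
                                        rep = numeric(length(idx))))
  names(acc) <- stats
  for (j in seq_along(idx)) {
    b <- idx[j]
    pp <- .draw_params(fit, b)
    yr <- .sample_response(fit$model$family, n, pp$mu, pp$extras)
    for (s in stats) {
      acc[[s]]$rep[j] <- switch(s,
        mean = mean(yr), variance = stats::var(yr), zeros = mean(yr == 0),
        deviance = -2 * sum(.family_loglik(fit$model$family, yr, n, pp$mu, pp$extras))
      )
      acc[[s]]$obs[j] <- switch(s,
        mean = mean(y), variance = stats::var(y), zeros = mean(y == 0),
        deviance = -2 * sum(fit$loglik[b, ])
      )
    }
  }
  purrr::map_dfr(stats, function(s) {
    tibble::tibble(
      stat = s,
      observed = mean(acc[[s]]$obs),
      p_value = mean(acc[[s]]$rep >= acc[[s]]$obs),
      replicates = list(acc[[s]]$rep)
    )
  })
}

#' WAIC-based model selection across replications
#'
#' Ranks models by mean WAIC and, when a replication column is present,
#' reports pairwise selection proportions: the fraction of replications
#' in which each model attains a strictly lower WAIC than each
#' competitor. Exact ties are counted separately, never silently awarded.
#'
#' @param waic_table a data frame with columns `model`, `waic` and
#'   optionally `rep` (replication id; defaults to a single replication).
#' @return a list with `ranking` (tibble: `model`, `mean_waic`, `rank`)
#'   and `pairwise` (tibble: `model`, `against`, `prop_selected`,
#'   `prop_ties`).
#' @export
model_selection <- function(waic_table) {
  stopifnot(all(c("model", "waic") %in% names(waic_table)))
  wt <- tibble::as_tibble(waic_table)
  if (!"rep" %in% names(wt)) wt$rep <- 1L
  ranking <- wt |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(mean_waic = mean(.data$waic), .groups = "drop") |>
    dplyr::arrange(.data$mean_waic) |>
    dplyr::mutate(rank = dplyr::row_number())
  models <- unique(wt$model)
  pairs <- expand.grid(model = models, against = models,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$model != pairs$against, , drop = FALSE]
  wide <- tidyr::pivot_wider(wt, id_cols = "rep", names_from = "model",
                             values_from = "waic")
  pairwise <- purrr::pmap_dfr(pairs, function(model, against) {
    a <- wide[[model]]; b <- wide[[against]]
    tibble::tibble(model = model, against = against,
                   prop_selected = mean(a < b), prop_ties = mean(a == b))
  })
  list(ranking = ranking, pairwise = pairwise)
}
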