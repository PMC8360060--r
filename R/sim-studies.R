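# Simulation-study generators and replication harnesses: the model-fit
# comparison (four data-generating scenarios), the excess-of-zeros study,
# and the outlier-contamination study. Generators return tibbles with a
# `truth` attribute recording the generating parameters and any
# contaminated indices, so harnesses can score bias, MSE, coverage and
# selection rates against them.

# trial counts: Poisson draws with zero counts resampled so every
# observation has at least one trial
.rpois_trials <- function(N, mean) {
  n <- stats::rpois(N, mean)
  while (any(n == 0L)) n[n == 0L] <- stats::rpois(sum(n == 0L), mean)
  n
}

#' Simulate data for the model-fit comparison scenarios
#'
#' Four data-generating processes over a single uniform covariate with a
#' logit mean model `logit(mu_i) = beta0 + beta1 x_i`:
#' \describe{
#'   \item{1}{beta-binomial response with precision `phi = 100`;}
#'   \item{2}{flexible beta-binomial response with `phi = 2.333`,
#'     `p = 0.5`, `w = 0.75`;}
#'   \item{3}{a generic mixture of two beta-binomial regressions with
#'     different means and precisions `phi1 = 10`, `phi2 = 20`,
#'     `p = 0.5` (not an FBB);}
#'   \item{4}{a generic mixture with one very small precision
#'     (`phi1 = 10`, `phi2 = 1`, `p = 0.8`), which also induces an
#'     excess of zeros.}
#' }
#' Scenarios 3 and 4 need component means; they are built by shifting
#' the logit of the mean by `+delta` (component 1) and `-delta`
#' (component 2), a documented, configurable construction.
#'
#' @param scenario integer 1-4.
#' @param N sample size (default 150).
#' @param beta true regression coefficients (default `c(1, 3)`).
#' @param trials_mean Poisson mean of the trial counts (default 200;
#'   zero draws are resampled).
#' @param delta logit-scale half-distance between the component means of
#'   scenarios 3-4 (default 0.5).
#' @param seed optional integer seed.
#' @return a tibble with columns `y`, `n`, `x` and a `truth` attribute
#'   listing the generating parameters.
#' @examples
#' d <- simulate_fit_scenario(2, N = 50, seed = 1)
#' attr(d, "truth")$w
#' @export
simulate_fit_scenario <- function(scenario, N = 150, beta = c(1, 3),
                                  trials_mean = 200, delta = 0.5,
                                  seed = NULL) {
  if (!scenario %in% 1:4) stop("`scenario` must be 1, 2, 3 or 4", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::runif(N, -1, 1)
  n <- .rpois_trials(N, trials_mean)
  mu <- stats::plogis(beta[1] + beta[2] * x)
  truth <- list(scenario = scenario, beta = beta, trials_mean = trials_mean)
  if (scenario == 1) {
    phi <- 100
    y <- stats::rbinom(N, n, stats::rbeta(N, phi * mu, phi * (1 - mu)))
    truth$phi <- phi
  } else if (scenario == 2) {
    phi <- 2.333; p <- 0.5; w <- 0.75
    y <- rfbbinom(N, n, mu, w, phi, p)
    truth <- c(truth, list(phi = phi, p = p, w = w))
  } else {
    phi1 <- 10
    phi2 <- if (scenario == 3) 20 else 1
    p <- if (scenario == 3) 0.5 else 0.8
    eta <- stats::qlogis(mu)
    lam1 <- stats::plogis(eta + delta)
    lam2 <- stats::plogis(eta - delta)
    k <- stats::runif(N) < p
    lam <- ifelse(k, lam1, lam2)
    phi <- ifelse(k, phi1, phi2)
    y <- stats::rbinom(N, n, stats::rbeta(N, phi * lam, phi * (1 - lam)))
    truth <- c(truth, list(phi1 = phi1, phi2 = phi2, p = p, delta = delta))
  }
  out <- tibble::tibble(y = as.integer(y), n = as.integer(n), x = x)
  attr(out, "truth") <- truth
  out
}

#' Simulate binomial data with an artificial excess of zeros
#'
#' Generates `Y_i ~ Bin(n_i, logit^-1(1 + 2 x_i))` with
#' `n_i ~ Poisson(50)` and `x ~ Uniform(-1.5, 2)`, then sets the outcome
#' of an exact `round(pct * N)` randomly chosen units to zero. The
#' canonical contamination fractions are 5%, 10%, 20% and 50%; other
#' values are accepted with a message.
#'
#' @param pct fraction of outcomes set to zero, in `[0, 1)`.
#' @param N sample size (default 100).
#' @param beta true coefficients of the generating binomial regression.
#' @param trials_mean Poisson mean of the trial counts (default 50).
#' @param seed optional integer seed.
#' @return a tibble with columns `y`, `n`, `x`; the `truth` attribute
#'   records the generating parameters and the zeroed indices.
#' @export
simulate_zero_excess <- function(pct, N = 100, beta = c(1, 2),
                                 trials_mean = 50, seed = NULL) {
  if (pct < 0 || pct >= 1) stop("`pct` must lie in [0, 1)", call. = FALSE)
  if (!isTRUE(all.equal(pct, 0)) && !pct %in% c(0.05, 0.10, 0.20, 0.50)) {
    message(sprintf("note: pct = %g is outside the canonical set {0.05, 0.1, 0.2, 0.5}", pct))
  }
  if (!is.null(seed)) set.seed(seed)
  x <- stats::runif(N, -1.5, 2)
  n <- .rpois_trials(N, trials_mean)
  y <- stats::rbinom(N, n, stats::plogis(beta[1] + beta[2] * x))
  k <- round(pct * N)
  zeroed <- if (k > 0) sort(sample.int(N, k)) else integer(0)
  y[zeroed] <- 0L
  out <- tibble::tibble(y = as.integer(y), n = as.integer(n), x = x)
  attr(out, "truth") <- list(beta = beta, trials_mean = trials_mean,
                             pct = pct, zeroed = zeroed)
  out
}

#' Simulate binomial data contaminated by outliers
#'
#' Generates the same binomial design as [simulate_zero_excess()] and
#' then flips the counts `y -> n - y` of observations drawn (without
#' replacement) from the covariate tails: three units with
#' `x < x_(0.15)` (scenario `"I"`), three with `x > x_(0.85)`
#' (scenario `"II"`), or three from each tail (scenario `"III"`), the
#' percentiles being empirical quantiles of the generated covariate. If
#' a tail holds fewer than three units the covariate is redrawn.
#'
#' @param scenario `"I"`, `"II"` or `"III"`.
#' @inheritParams simulate_zero_excess
#' @param n_out outliers per selected tail (default 3).
#' @return a tibble with columns `y`, `n`, `x`; the `truth` attribute
#'   records the outlier indices and the original counts.
#' @export
simulate_outliers <- function(scenario = c("I", "II", "III"), N = 100,
                              beta = c(1, 2), trials_mean = 50, n_out = 3,
                              seed = NULL) {
  scenario <- match.arg(scenario)
  if (!is.null(seed)) set.seed(seed)
  repeat {
    x <- stats::runif(N, -1.5, 2)
    lo <- which(x < stats::quantile(x, 0.15))
    hi <- which(x > stats::quantile(x, 0.85))
    need_lo <- scenario %in% c("I", "III")
    need_hi <- scenario %in% c("II", "III")
    if ((!need_lo || length(lo) >= n_out) && (!need_hi || length(hi) >= n_out)) break
  }
  n <- .rpois_trials(N, trials_mean)
  y <- stats::rbinom(N, n, stats::plogis(beta[1] + beta[2] * x))
  idx <- c(if (need_lo) sample(lo, n_out), if (need_hi) sample(hi, n_out))
  idx <- sort(idx)
  y_old <- y[idx]
  y[idx] <- n[idx] - y[idx]
  out <- tibble::tibble(y = as.integer(y), n = as.integer(n), x = x)
  attr(out, "truth") <- list(beta = beta, trials_mean = trials_mean,
                             scenario = scenario, outliers = idx,
                             y_original = as.integer(y_old))
  out
}

# truth values for the parameters each family reports, used for
# bias/MSE/coverage scoring; NULL entries are skipped
.truth_vector <- function(truth, family) {
  tv <- c("(Intercept)" = truth$beta[1], x = truth$beta[2])
  if (family == "betabinomial" && !is.null(truth$phi)) tv <- c(tv, phi = truth$phi)
  if (family == "fbb") {
    if (!is.null(truth$phi)) tv <- c(tv, phi = truth$phi)
    if (!is.null(truth$p)) tv <- c(tv, p = truth$p)
    if (!is.null(truth$w)) tv <- c(tv, w = truth$w)
  }
  tv
}

#' Replicated model-fit study
#'
#' Repeats a data-generating scenario `R` times; on each replication
#' fits every requested family, records posterior means, credible-set
#' coverage of the generating values and WAIC, and aggregates bias
#' (`mean(estimate - truth)`), MSE, coverage, mean WAIC and pairwise
#' WAIC selection proportions. Replications whose fit fails are
#' quarantined and counted, never silently dropped.
#'
#' @param scenario scenario id passed to [simulate_fit_scenario()].
#' @param families families to fit on each replication.
#' @param R number of replications.
#' @param N sample size per replication.
#' @param chains,iter sampler settings per fit (reduced-scale defaults;
#'   pass larger values for paper-scale runs — outputs record the scale
#'   used).
#' @param seed integer seed; replication r uses `seed + r` for data and
#'   fitting.
#' @param level credible level for coverage (default 0.95).
#' @return an object of class `fbb_replication`: a list with `results`
#'   (per-replication, per-model tibble of estimates, coverage and
#'   WAIC), `summary` (bias/MSE/coverage per parameter and model, mean
#'   WAIC), `selection` (pairwise WAIC selection proportions),
#'   `failures`, and the configuration used.
#' @examples
#' \donttest{
#' rs <- run_replications(1, families = c("binomial", "betabinomial"),
#'                        R = 2, chains = 1, iter = 500, seed = 1)
#' rs$summary
#' }
#' @export
run_replications <- function(scenario, families = c("binomial", "betabinomial", "fbb"),
                             R = 25, N = 150, chains = 2, iter = 2000,
                             seed = 1, level = 0.95) {
  stopifnot(R >= 1)
  rows <- list()
  failures <- tibble::tibble(rep = integer(), model = character(),
                             message = character())
  for (r in seq_len(R)) {
    dat <- simulate_fit_scenario(scenario, N = N, seed = seed + r)
    truth <- attr(dat, "truth")
    for (fam in families) {
      res <- tryCatch({
        fit <- fbb_fit(dat, y ~ x, trials = n, family = fam, chains = chains,
                       iter = iter, seed = seed + r)
        ps <- posterior_summary(fit, level = level)
        tv <- .truth_vector(truth, fam)
        ps <- ps[ps$term %in% names(tv), ]
        ps$truth <- tv[ps$term]
        dplyr::mutate(
          tibble::tibble(rep = r, model = fam, term = ps$term,
                         estimate = ps$mean, truth = ps$truth,
                         lower = ps$lower, upper = ps$upper),
          covered = .data$lower <= .data$truth & .data$truth <= .data$upper,
          waic = waic(fit)$waic
        )
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures <- dplyr::bind_rows(failures,
          tibble::tibble(rep = r, model = fam, message = conditionMessage(res)))
      } else {
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  summary <- results |>
    dplyr::group_by(.data$model, .data$term) |>
    dplyr::summarise(
      bias = mean(.data$estimate - .data$truth),
      mse = mean((.data$estimate - .data$truth)^2),
      coverage = mean(.data$covered),
      .groups = "drop"
    )
  waics <- results |>
    dplyr::distinct(.data$rep, .data$model, .data$waic)
  mean_waic <- waics |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(mean_waic = mean(.data$waic), .groups = "drop")
  structure(
    list(results = results,
         summary = dplyr::left_join(summary, mean_waic, by = "model"),
         waics = waics,
         selection = model_selection(waics),
         failures = failures,
         config = list(scenario = scenario, families = families, R = R, N = N,
                       chains = chains, iter = iter, seed = seed)),
    class = "fbb_replication"
  )
}

#' @export
print.fbb_replication <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<fbb_replication> scenario %s: R = %d replications, N = %d (%d chains x %d iters per fit)\n",
              cfg$scenario, cfg$R, cfg$N, cfg$chains, cfg$iter))
  if (nrow(x$failures)) cat(sprintf("  %d quarantined fit failure(s)\n", nrow(x$failures)))
  print(x$summary, n = Inf)
  cat("mean WAIC selection (row beats column fraction):\n")
  print(x$selection$pairwise, n = Inf)
  invisible(x)
}

#' Excess-of-zeros study
#'
#' For each contamination fraction, generates one or more seeded
#' zero-excess datasets and fits the requested families, recording WAIC
#' and — for the FBB family — the posterior mean of the mixing
#' proportion `p`, which tracks the fraction of unchanged observations
#' (the lower mixture component absorbs the zero group).
#'
#' @param pcts contamination fractions (default the canonical
#'   `c(0.05, 0.1, 0.2, 0.5)`).
#' @param R replications per fraction (default 3).
#' @param families families to fit (default FBB only).
#' @inheritParams run_replications
#' @return a tibble with one row per fraction, replication and model:
#'   `pct`, `rep`, `model`, `waic`, `p_mean` (NA for families without a
#'   mixing proportion).
#' @export
run_zero_excess_study <- function(pcts = c(0.05, 0.10, 0.20, 0.50), R = 3,
                                  families = "fbb", N = 100,
                                  chains = 2, iter = 2000, seed = 1) {
  grid <- expand.grid(pct = pcts, rep = seq_len(R), model = families,
                      stringsAsFactors = FALSE)
  purrr::pmap_dfr(grid, function(pct, rep, model) {
    dat <- simulate_zero_excess(pct, N = N, seed = seed + 1000L * rep + round(100 * pct))
    fit <- fbb_fit(dat, y ~ x, trials = n, family = model, chains = chains,
                   iter = iter, seed = seed + rep)
    tibble::tibble(
      pct = pct, rep = rep, model = model, waic = waic(fit)$waic,
      p_mean = if ("p" %in% names(fit$draws)) mean(fit$draws$p) else NA_real_
    )
  })
}

#' Outlier-contamination study
#'
#' Generates one seeded contaminated dataset per scenario, fits the
#' requested families, and records the conditional predictive ordinate
#' of every contaminated observation under each model; a robust family
#' should leave the contaminated points with the highest CPO.
#'
#' @param scenarios outlier scenarios among `"I"`, `"II"`, `"III"`.
#' @inheritParams run_replications
#' @param families families to fit.
#' @return a tibble with one row per scenario, model and contaminated
#'   observation: `scenario`, `model`, `observation`, `log_cpo`, `cpo`,
#'   plus the fitted model's WAIC.
#' @export
run_outlier_study <- function(scenarios = c("I", "II", "III"),
                              families = c("binomial", "betabinomial", "fbb"),
                              N = 100, chains = 2, iter = 2000, seed = 1) {
  purrr::map_dfr(scenarios, function(sc) {
    dat <- simulate_outliers(sc, N = N, seed = seed + match(sc, c("I", "II", "III")))
    idx <- attr(dat, "truth")$outliers
    purrr::map_dfr(families, function(fam) {
      fit <- fbb_fit(dat, y ~ x, trials = n, family = fam, chains = chains,
                     iter = iter, seed = seed)
      cp <- cpo(fit)
      tibble::tibble(scenario = sc, model = fam, observation = idx,
                     log_cpo = cp$log_cpo[idx], cpo = cp$cpo[idx],
                     waic = waic(fit)$waic)
    })
  })
}
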