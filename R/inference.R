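# Posterior sampling and chain management. The sampler is an adaptive
# random-walk Metropolis on the unconstrained parameter scale: during
# warm-up the proposal covariance tracks the running posterior covariance
# (Haario-style) while a Robbins-Monro recursion tunes the global step
# size toward a 0.3 acceptance rate; after warm-up the kernel is frozen,
# so retained draws come from a fixed, valid Markov kernel. Per-draw
# per-observation log-likelihoods are stored for every retained draw,
# which is what WAIC, CPO and the posterior predictive checks consume.

.ADAPT_TARGET <- 0.3

.run_chain <- function(lpfun, init, n_iter, n_warm, thin, n_obs) {
  d <- length(init)
  eta <- init
  cur <- lpfun(eta)
  if (!is.finite(cur$lp)) stop("initial state has zero posterior density", call. = FALSE)

  log_s <- log(2.38 / sqrt(d))
  run_mean <- eta
  run_m2 <- diag(1e-6, d)
  L <- diag(0.1, d)

  n_keep <- floor((n_iter - n_warm) / thin)
  draws <- matrix(NA_real_, n_keep, d)
  ll <- matrix(NA_real_, n_keep, n_obs)
  lp_kept <- numeric(n_keep)
  kept <- 0L
  acc_post <- 0L

  for (t in seq_len(n_iter)) {
    prop <- eta + exp(log_s) * drop(L %*% stats::rnorm(d))
    cand <- lpfun(prop)
    acc <- is.finite(cand$lp) && log(stats::runif(1)) < cand$lp - cur$lp
    if (acc) {
      eta <- prop
      cur <- cand
    }

    if (t <= n_warm) {
      # step-size tuning
      log_s <- log_s + min(0.9, t^-0.6) * ((if (acc) 1 else 0) - .ADAPT_TARGET)
      # running covariance (Welford)
      delta <- eta - run_mean
      run_mean <- run_mean + delta / t
      run_m2 <- run_m2 + tcrossprod(delta, eta - run_mean)
      if (t %% 50L == 0L && t >= 2L * d) {
        sig <- run_m2 / (t - 1) + diag(1e-8, d)
        ch <- tryCatch(chol(sig), error = function(e) NULL)
        if (!is.null(ch)) L <- t(ch)
      }
    } else {
      if (acc) acc_post <- acc_post + 1L
      if ((t - n_warm) %% thin == 0L) {
        kept <- kept + 1L
        draws[kept, ] <- eta
        ll[kept, ] <- cur$ll
        lp_kept[kept] <- cur$lp
      }
    }
  }
  list(draws = draws, loglik = ll, lp = lp_kept,
       accept_rate = acc_post / (n_iter - n_warm))
}

.init_eta <- function(model, X) {
  # random starting values: coefficients from a tight normal to avoid
  # overflow of the linear predictor, unit-interval parameters from
  # their uniform prior (mapped to the logit scale)
  c(stats::rnorm(ncol(X), 0, 2), stats::qlogis(stats::runif(length(model$extras))))
}

# natural-scale draws: coefficients unchanged, extras back-transformed,
# phi derived from theta
.natural_draws <- function(model, X, eta_mat) {
  k <- ncol(X)
  out <- eta_mat[, seq_len(k), drop = FALSE]
  colnames(out) <- colnames(X)
  if (length(model$extras)) {
    nat <- stats::plogis(eta_mat[, k + seq_along(model$extras), drop = FALSE])
    colnames(nat) <- model$extras
    out <- cbind(out, nat)
    if ("theta" %in% model$extras) {
      out <- cbind(out, phi = 1 / nat[, "theta"] - 1)
    }
  }
  out
}

#' Fit a Bayesian count-regression model
#'
#' Samples the joint posterior of the chosen family by adaptive
#' random-walk Metropolis on the unconstrained parameter scale (see
#' [fbb_model()] for priors). Starting values are drawn at random; the
#' first `warmup` fraction of every chain is used for adaptation and
#' discarded; the retained draws of all chains are pooled with their
#' chain labels kept, together with the per-draw per-observation
#' log-likelihood matrix needed by [waic()], [cpo()] and [ppc_check()].
#'
#' @param data a data frame with one row per observation.
#' @param formula model formula; the left-hand side is the success-count
#'   column (e.g. `y ~ x + I(x^2)`).
#' @param trials column of `data` holding the trial counts (bare name).
#' @param family response family, see [fbb_model()].
#' @param link link function for the mean (default `"logit"`).
#' @param chains number of chains (default 4).
#' @param iter iterations per chain, including warm-up (default 10000).
#' @param warmup fraction of each chain discarded as warm-up
#'   (default 0.5).
#' @param thin thinning interval (default 1).
#' @param seed integer seed for reproducibility; identical seed, data and
#'   configuration give identical draws.
#' @param prior_beta_sd prior standard deviation of the coefficients.
#' @return an object of class `fbb_fit` with components `draws` (a tibble
#'   of natural-scale draws with `.chain` and `.iter` columns), `loglik`
#'   (B x N matrix), `model`, `data` and sampler metadata. Methods:
#'   [tidy()], [glance()], [posterior_summary()], [convergence_report()],
#'   [waic()], [cpo()], [ppc_check()], `autoplot()`.
#' @examples
#' d <- simulate_fit_scenario(1, N = 40, seed = 1)
#' f <- fbb_fit(d, y ~ x, trials = n, family = "betabinomial",
#'              chains = 2, iter = 600, seed = 1)
#' tidy(f)
#' @export
fbb_fit <- function(data, formula, trials, family = "fbb", link = "logit",
                    chains = 4, iter = 10000, warmup = 0.5, thin = 1,
                    seed = NULL, prior_beta_sd = 100) {
  stopifnot(chains >= 1, iter >= 4, warmup > 0, warmup < 1, thin >= 1)
  model <- fbb_model(family = family, link = link, prior_beta_sd = prior_beta_sd)
  rd <- regression_data(data, formula, trials = !!rlang::enquo(trials))
  if (!is.null(seed)) set.seed(seed)

  lpfun <- function(eta) .log_post_full(model, rd, eta)
  n_warm <- floor(iter * warmup)
  d <- ncol(rd$X) + length(model$extras)

  chains_out <- vector("list", chains)
  for (c in seq_len(chains)) {
    init <- .init_eta(model, rd$X)
    cur <- lpfun(init)
    tries <- 0L
    while (!is.finite(cur$lp) && tries < 100L) {
      init <- .init_eta(model, rd$X)
      cur <- lpfun(init)
      tries <- tries + 1L
    }
    chains_out[[c]] <- .run_chain(lpfun, init, iter, n_warm, thin, length(rd$y))
  }

  acc <- vapply(chains_out, `[[`, numeric(1), "accept_rate")
  if (any(acc < 0.05)) {
    warning(sprintf(
      "sampler adaptation may have failed: post-warmup acceptance rate %.3f in chain %d",
      min(acc), which.min(acc)), call. = FALSE)
  }

  eta_mat <- do.call(rbind, lapply(chains_out, `[[`, "draws"))
  nat <- .natural_draws(model, rd$X, eta_mat)
  n_keep <- nrow(chains_out[[1]]$draws)
  draws <- tibble::as_tibble(as.data.frame(nat, check.names = FALSE))
  draws <- dplyr::bind_cols(
    tibble::tibble(.chain = rep(seq_len(chains), each = n_keep),
                   .iter = rep(seq_len(n_keep), chains)),
    draws
  )

  structure(
    list(model = model, data = rd, formula = formula,
         draws = draws, eta = eta_mat,
         loglik = do.call(rbind, lapply(chains_out, `[[`, "loglik")),
         lp = unlist(lapply(chains_out, `[[`, "lp")),
         accept_rate = acc,
         config = list(chains = chains, iter = iter, warmup = warmup,
                       thin = thin, seed = seed)),
    class = "fbb_fit"
  )
}

# names of the reported parameters (natural scale)
.param_names <- function(fit) {
  setdiff(names(fit$draws), c(".chain", ".iter"))
}

#' @export
print.fbb_fit <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<fbb_fit> family = %s, N = %d observations\n",
              x$model$family, length(x$data$y)))
  cat(sprintf("  %d chain(s) x %d iterations (%.0f%% warm-up, thin %d): %d retained draws\n",
              cfg$chains, cfg$iter, 100 * cfg$warmup, cfg$thin, nrow(x$draws)))
  print(posterior_summary(x), n = Inf)
  invisible(x)
}

#' Posterior means and credible sets
#'
#' Equal-tailed credible sets from posterior quantiles, one row per
#' parameter, with a significance flag for regression coefficients whose
#' credible set excludes zero.
#'
#' @param fit an [fbb_fit()] object.
#' @param level credible level (default 0.95).
#' @return a tibble with columns `term`, `mean`, `sd`, `lower`, `upper`,
#'   `significant`.
#' @export
posterior_summary <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "fbb_fit"), nrow(fit$draws) >= 2)
  a <- (1 - level) / 2
  pars <- .param_names(fit)
  purrr::map_dfr(pars, function(p) {
    v <- fit$draws[[p]]
    q <- stats::quantile(v, c(a, 1 - a), names = FALSE)
    tibble::tibble(term = p, mean = mean(v), sd = stats::sd(v),
                   lower = q[1], upper = q[2],
                   significant = q[1] > 0 | q[2] < 0)
  })
}

#' Convergence diagnostics for a fitted model
#'
#' Per-parameter split-chain potential scale reduction (split-R-hat),
#' bulk effective sample size, a Geweke z-score (first 10% vs last 50% of
#' each chain, worst across chains) and a Heidelberger-Welch
#' stationarity verdict (all chains must pass at alpha = 0.05). With a
#' single chain, R-hat is computed on the two half-chains (noted in the
#' output).
#'
#' @param fit an [fbb_fit()] object.
#' @return a tibble with columns `term`, `rhat`, `ess`, `geweke_z`,
#'   `heidel_pass`.
#' @export
convergence_report <- function(fit) {
  stopifnot(inherits(fit, "fbb_fit"))
  pars <- .param_names(fit)
  chains <- split(fit$draws, fit$draws$.chain)
  if (length(chains) == 1L) {
    message("single chain: split-Rhat computed on the two half-chains")
  }
  purrr::map_dfr(pars, function(p) {
    mats <- lapply(chains, function(ch) ch[[p]])
    mcl <- coda::mcmc.list(lapply(mats, coda::mcmc))
    gz <- suppressWarnings(vapply(mats, function(v) {
      unname(coda::geweke.diag(coda::mcmc(v), frac1 = 0.1, frac2 = 0.5)$z)
    }, numeric(1)))
    hp <- vapply(mats, function(v) {
      h <- tryCatch(coda::heidel.diag(coda::mcmc(v), pvalue = 0.05),
                    error = function(e) NULL)
      !is.null(h) && isTRUE(h[1, "stest"] == 1)
    }, logical(1))
    tibble::tibble(
      term = p,
      rhat = split_rhat(mats),
      ess = sum(vapply(mats, function(v) unname(coda::effectiveSize(v)), numeric(1))),
      geweke_z = gz[which.max(abs(gz))],
      heidel_pass = all(hp)
    )
  })
}

#' Split-chain potential scale reduction factor
#'
#' Each chain is split into halves, and the classical R-hat
#' (between/within variance ratio) is computed over the resulting
#' half-chains; values near 1 indicate the chains agree.
#'
#' @param chains a list of numeric vectors, one per chain.
#' @return scalar R-hat estimate.
#' @export
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(v) {
    h <- floor(length(v) / 2)
    list(v[seq_len(h)], v[h + seq_len(h)])
  }), recursive = FALSE)
  L <- min(lengths(halves))
  halves <- lapply(halves, function(v) v[seq_len(L)])
  m <- length(halves)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- L * stats::var(means)
  if (W == 0) return(1)
  sqrt(((L - 1) / L * W + B / L) / W)
}
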