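# Regression-model definitions: five families (binomial, beta-binomial,
# flexible beta-binomial, and the two zero-inflated baselines) sharing a
# common link/prior interface and a joint log-posterior over observed
# count data. Sampling operates on unconstrained scales (beta free,
# logit of theta, w, p, q) with the log-Jacobian of each transform added
# to the prior, so the open parameter boundaries are never hit.

.FAMILIES <- c("binomial", "betabinomial", "fbb", "zibinomial", "zibetabinomial")

# extra (non-regression) parameters of each family, on the natural scale;
# all are Uniform(0,1) a priori, with phi derived as 1/theta - 1
.family_extras <- function(family) {
  switch(family,
    binomial = character(0),
    betabinomial = "theta",
    fbb = c("theta", "w", "p"),
    zibinomial = "q",
    zibetabinomial = c("theta", "q"),
    stop(sprintf("unknown family '%s'", family), call. = FALSE)
  )
}

.make_link <- function(link) {
  lk <- stats::make.link(match.arg(link, c("logit", "probit", "cloglog")))
  # keep the inverse strictly interior so log pmfs stay finite at
  # extreme linear predictors
  linkinv <- function(eta) pmin(pmax(lk$linkinv(eta), 1e-10), 1 - 1e-10)
  list(name = lk$name, linkfun = lk$linkfun, linkinv = linkinv)
}

#' Specify a count-regression model
#'
#' Builds the model object pairing a response family with a link function
#' and priors. The linear predictor acts on the mean proportion through
#' `g(mu_i) = x_i' beta`; the regression coefficients get independent
#' diffuse normal priors (mean 0, standard deviation `prior_beta_sd`),
#' and every unit-interval parameter — the overdispersion parameter
#' `theta = 1/(phi+1)`, the component distance `w`, the mixing proportion
#' `p`, and the zero-inflation probability `q` — gets a Uniform(0, 1)
#' prior.
#'
#' @param family one of `"binomial"`, `"betabinomial"`, `"fbb"`,
#'   `"zibinomial"`, `"zibetabinomial"`.
#' @param link link function for the mean: `"logit"` (default),
#'   `"probit"` or `"cloglog"`.
#' @param prior_beta_sd prior standard deviation of each regression
#'   coefficient (default 100, i.e. prior variance 1e4).
#' @return an object of class `fbb_model`.
#' @examples
#' fbb_model("fbb")
#' @export
fbb_model <- function(family = c("fbb", "binomial", "betabinomial",
                                 "zibinomial", "zibetabinomial"),
                      link = "logit", prior_beta_sd = 100) {
  family <- match.arg(family)
  stopifnot(is.numeric(prior_beta_sd), prior_beta_sd > 0)
  structure(
    list(family = family, link = .make_link(link),
         extras = .family_extras(family), prior_beta_sd = prior_beta_sd),
    class = "fbb_model"
  )
}

#' @export
print.fbb_model <- function(x, ...) {
  cat(sprintf("<fbb_model> family = %s, link = %s, beta ~ N(0, %g^2)\n",
              x$family, x$link$name, x$prior_beta_sd))
  if (length(x$extras)) {
    cat("  unit-interval parameters ~ Uniform(0,1):",
        paste(x$extras, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assemble validated regression data
#'
#' Extracts the success counts, trial counts and design matrix from a
#' data frame. The formula's left-hand side names the success-count
#' column; covariates (including factors, which expand to treatment
#' dummies against the first level) form the right-hand side, always with
#' a leading intercept column.
#'
#' @param data a data frame with one row per observation.
#' @param formula model formula, e.g. `y ~ x + I(x^2)`.
#' @param trials column holding the number of trials (bare name or
#'   string).
#' @return a list of class `fbb_data` with elements `y`, `n`, `X`.
#' @examples
#' d <- data.frame(y = c(1, 3, 2), n = c(5, 6, 4), x = c(-1, 0, 1))
#' regression_data(d, y ~ x, trials = n)
#' @export
regression_data <- function(data, formula, trials) {
  stopifnot(is.data.frame(data))
  trials <- rlang::as_name(rlang::enquo(trials))
  if (!trials %in% names(data)) {
    stop(sprintf("trials column '%s' not found in `data`", trials), call. = FALSE)
  }
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- data[[trials]]
  if (length(y) != length(n)) stop("response and trials lengths differ", call. = FALSE)
  if (any(y != floor(y)) || any(n != floor(n))) {
    stop("success and trial counts must be integers", call. = FALSE)
  }
  bad <- which(y < 0 | y > n)
  if (length(bad)) {
    stop(sprintf("rows with y outside [0, n]: %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  if (qr(X)$rank < ncol(X)) {
    warning("design matrix is not of full column rank", call. = FALSE)
  }
  structure(list(y = as.numeric(y), n = as.numeric(n), X = X), class = "fbb_data")
}

#' Mean proportions from the linear predictor
#'
#' Applies the inverse link to `X %*% beta`, returning values kept
#' strictly inside (0, 1) so that downstream log pmfs remain finite even
#' for extreme linear predictors.
#'
#' @param beta coefficient vector of length `ncol(X)`.
#' @param X design matrix with leading intercept column.
#' @param link link name (see [fbb_model()]).
#' @return numeric vector of mean proportions.
#' @export
linear_predictor_mean <- function(beta, X, link = "logit") {
  if (length(beta) != ncol(X)) stop("length(beta) != ncol(X)", call. = FALSE)
  .make_link(link)$linkinv(drop(X %*% beta))
}

# ---- internal unchecked log-pmf kernels (hot path) ---------------------

.ll_binom <- function(y, n, mu) stats::dbinom(y, n, mu, log = TRUE)

.ll_bb <- function(y, n, mu, phi) {
  a <- phi * mu
  b <- phi - a
  lchoose(n, y) + lbeta(a + y, b + n - y) - lbeta(a, b)
}

.ll_fbb <- function(y, n, mu, w, phi, p) {
  d <- w * pmin(mu / p, (1 - mu) / (1 - p))
  .log_sum_exp(
    log(p) + .ll_bb(y, n, mu + (1 - p) * d, phi),
    log1p(-p) + .ll_bb(y, n, mu - p * d, phi)
  )
}

.ll_zi <- function(y, base_ll0, base_ll, q) {
  out <- log1p(-q) + base_ll
  at0 <- y == 0
  if (any(at0)) out[at0] <- .log_sum_exp(rep_len(log(q), sum(at0)), out[at0])
  out
}

# per-observation log-likelihood at natural-scale parameters
.family_loglik <- function(family, y, n, mu, extras) {
  switch(family,
    binomial = .ll_binom(y, n, mu),
    betabinomial = .ll_bb(y, n, mu, 1 / extras[["theta"]] - 1),
    fbb = .ll_fbb(y, n, mu, extras[["w"]], 1 / extras[["theta"]] - 1,
                  extras[["p"]]),
    zibinomial = .ll_zi(y, NULL, .ll_binom(y, n, mu), extras[["q"]]),
    zibetabinomial = .ll_zi(
      y, NULL, .ll_bb(y, n, mu, 1 / extras[["theta"]] - 1), extras[["q"]])
  )
}

# eta layout: c(beta[1..K+1], z[extras]) with z on the logit scale
.eta_names <- function(model, X) c(colnames(X), model$extras)

.eta_split <- function(model, X, eta) {
  k <- ncol(X)
  z <- eta[-seq_len(k)]
  extras <- stats::plogis(z)
  names(extras) <- model$extras
  list(beta = eta[seq_len(k)], z = z, extras = extras)
}

#' Joint log-likelihood of a count-regression model
#'
#' Evaluates the per-observation log pmf of the model's family at the
#' parameter vector `eta` (coefficients followed by the family's extra
#' unit-interval parameters on the unconstrained logit scale), together
#' with their sum. The per-observation vector is what WAIC and CPO
#' consume.
#'
#' @param model an [fbb_model()].
#' @param data an [regression_data()] object (or a list with `y`, `n`, `X`).
#' @param eta numeric parameter vector: `ncol(X)` coefficients, then one
#'   unconstrained value per extra parameter (`theta`, `w`, `p`, `q` as
#'   required by the family).
#' @return a list with `total` (scalar) and `pointwise` (length-N vector).
#' @export
log_likelihood <- function(model, data, eta) {
  sp <- .eta_split(model, data$X, eta)
  mu <- model$link$linkinv(drop(data$X %*% sp$beta))
  ll <- .family_loglik(model$family, data$y, data$n, mu, sp$extras)
  list(total = sum(ll), pointwise = ll)
}

#' Joint log-posterior of a count-regression model
#'
#' Log-likelihood plus log prior: independent normals on the regression
#' coefficients and Uniform(0, 1) on each unit-interval parameter,
#' expressed on the unconstrained scale with the logit-transform
#' log-Jacobian included. States with a non-finite likelihood return
#' `-Inf` (a rejected state) rather than an error, as required during
#' sampling.
#'
#' @inheritParams log_likelihood
#' @return scalar log-posterior density (up to a constant).
#' @export
log_posterior <- function(model, data, eta) {
  .log_post_full(model, data, eta)$lp
}

# returns both the log-posterior and the pointwise log-likelihood so the
# sampler can store the loglik matrix at no extra cost
.log_post_full <- function(model, data, eta) {
  sp <- .eta_split(model, data$X, eta)
  mu <- model$link$linkinv(drop(data$X %*% sp$beta))
  ll <- .family_loglik(model$family, data$y, data$n, mu, sp$extras)
  total <- sum(ll)
  if (!is.finite(total)) return(list(lp = -Inf, ll = ll))
  lprior <- sum(stats::dnorm(sp$beta, 0, data$prior_beta_sd %||% model$prior_beta_sd,
                             log = TRUE))
  if (length(sp$z)) {
    # Uniform(0,1) prior + logit Jacobian: log s + log(1 - s)
    lprior <- lprior + sum(stats::plogis(sp$z, log.p = TRUE) +
                             stats::plogis(-sp$z, log.p = TRUE))
  }
  list(lp = total + lprior, ll = ll)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
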