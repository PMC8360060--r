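# Exact probability functions, moments, intraclass correlations, zero
# probabilities and samplers for the beta-binomial (BB), flexible
# beta-binomial (FBB), flexible beta (FB) and zero-inflated families.
# All pmfs are computed in log space via log-gamma; mixtures via
# log-sum-exp, so that large trial counts never overflow.

# ---- domain guards -----------------------------------------------------

# open-interval guard: parameters of these families live strictly inside
# (0,1); the default epsilon keeps the public API away from the boundary
# where log-gamma terms diverge.
.check_unit <- function(x, name, eps = 1e-12) {
  if (any(!is.finite(x)) || any(x <= eps) || any(x >= 1 - eps)) {
    stop(sprintf("`%s` must lie strictly inside (0, 1)", name), call. = FALSE)
  }
  invisible(x)
}

.check_pos <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be a positive finite number", name), call. = FALSE)
  }
  invisible(x)
}

.check_counts <- function(x, size) {
  if (any(x < 0) || any(x > size) || any(x != floor(x))) {
    stop("`x` must be an integer count in {0, ..., size}", call. = FALSE)
  }
  if (any(size < 0) || any(size != floor(size))) {
    stop("`size` must be a non-negative integer", call. = FALSE)
  }
  invisible(x)
}

.log_sum_exp <- function(a, b) {
  m <- pmax(a, b)
  # both -Inf: log(0 + 0)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# ---- beta-binomial -----------------------------------------------------

#' Beta-binomial distribution
#'
#' Density (pmf) and random generation for the beta-binomial distribution
#' in the mean-precision parameterization: a binomial count whose success
#' probability is marginalized over a `Beta(mu, phi)` distribution with
#' mean `mu` and precision `phi`. The pmf is
#' \deqn{f(y) = \binom{n}{y} \frac{B(\phi\mu + y,\, \phi(1-\mu) + n - y)}
#'   {B(\phi\mu,\, \phi(1-\mu))},}
#' evaluated entirely in log space through [lbeta()] and [lchoose()].
#'
#' @param x vector of counts in `{0, ..., size}`.
#' @param size number of trials (non-negative integer), recycled.
#' @param mu mean proportion, in (0, 1).
#' @param phi precision, `> 0`; the intraclass correlation is
#'   `1 / (phi + 1)`.
#' @param log logical; if `TRUE`, log-probabilities are returned.
#' @param n number of draws.
#' @return `dbetabinom` a numeric vector of (log-)probabilities;
#'   `rbetabinom` an integer vector of counts.
#' @examples
#' dbetabinom(0:5, size = 5, mu = 0.3, phi = 2)
#' mean(rbetabinom(1e4, size = 20, mu = 0.3, phi = 4)) # ~ 6
#' @export
dbetabinom <- function(x, size, mu, phi, log = FALSE) {
  .check_unit(mu, "mu")
  .check_pos(phi, "phi")
  .check_counts(x, size)
  a <- phi * mu
  b <- phi * (1 - mu)
  out <- lchoose(size, x) + lbeta(a + x, b + size - x) - lbeta(a, b)
  if (log) out else exp(out)
}

#' @rdname dbetabinom
#' @export
rbetabinom <- function(n, size, mu, phi) {
  .check_unit(mu, "mu")
  .check_pos(phi, "phi")
  pi <- stats::rbeta(n, phi * mu, phi * (1 - mu))
  stats::rbinom(n, size, pi)
}

#' Moments of the beta-binomial
#'
#' Mean `n * mu` and variance
#' `n * mu * (1 - mu) * (1 + (n - 1) / (phi + 1))`; the bracketed inflation
#' term vanishes as `phi` grows and the binomial variance is recovered.
#'
#' @inheritParams dbetabinom
#' @return a tibble with columns `mean` and `variance`.
#' @export
betabinom_moments <- function(size, mu, phi) {
  .check_unit(mu, "mu")
  .check_pos(phi, "phi")
  tibble::tibble(
    mean = size * mu,
    variance = size * mu * (1 - mu) * (1 + (size - 1) / (phi + 1))
  )
}

#' Intraclass correlation of the beta-binomial
#'
#' The common pairwise correlation of the Bernoulli trials that form a
#' beta-binomial count: `rho = 1 / (phi + 1)`, the overdispersion
#' parameter `theta`.
#'
#' @inheritParams dbetabinom
#' @return numeric vector in (0, 1).
#' @export
icc_betabinom <- function(phi) {
  .check_pos(phi, "phi")
  1 / (phi + 1)
}

#' Probability of zero successes under the beta-binomial
#'
#' Closed form `(phi * (1 - mu))^[n] / phi^[n]` where `x^[n]` is the
#' rising factorial, computed as `exp(lgamma(x + n) - lgamma(x))`.
#'
#' @inheritParams dbetabinom
#' @return numeric vector of probabilities.
#' @export
prob_zero_betabinom <- function(size, mu, phi) {
  .check_unit(mu, "mu")
  .check_pos(phi, "phi")
  if (any(size < 1)) stop("`size` must be >= 1", call. = FALSE)
  lrf <- function(x, n) lgamma(x + n) - lgamma(x)
  exp(lrf(phi * (1 - mu), size) - lrf(phi, size))
}

# ---- flexible beta-binomial -------------------------------------------

#' Component means of the flexible beta-binomial
#'
#' The FBB is a mixture of two beta-binomials with common precision and
#' means `lambda1 > lambda2` determined by the overall mean `mu`, the
#' normalized component distance `w` and the mixing proportion `p`:
#' \deqn{\lambda_1 = \mu + (1-p)\, w \min(\mu/p, (1-\mu)/(1-p)), \quad
#'       \lambda_2 = \mu - p\, w \min(\mu/p, (1-\mu)/(1-p)).}
#' The mixture identity `p * lambda1 + (1 - p) * lambda2 = mu` holds by
#' construction, and both means stay strictly inside (0, 1) for any
#' interior `(mu, w, p)` — the parameterization is variation independent.
#'
#' @param mu overall mean, in (0, 1).
#' @param w normalized distance between the component means, in (0, 1).
#' @param p mixing proportion of the upper component, in (0, 1).
#' @return a tibble with columns `lambda1` and `lambda2`.
#' @examples
#' component_means(mu = 1/3, w = 0.75, p = 0.5)
#' @export
component_means <- function(mu, w, p) {
  .check_unit(mu, "mu"); .check_unit(w, "w"); .check_unit(p, "p")
  d <- w * pmin(mu / p, (1 - mu) / (1 - p))
  tibble::tibble(lambda1 = mu + (1 - p) * d, lambda2 = mu - p * d)
}

#' Separation factor of the flexible beta-binomial
#'
#' The factor `m(mu, p) = min( mu(1-p) / (p(1-mu)), (1-mu)p / ((1-p)mu) )`
#' bounding the squared component separation in the FBB variance and
#' intraclass correlation. The two arguments of the min are reciprocal
#' odds ratios, so `m` is symmetric in `(mu, p)`, lies in (0, 1], and
#' equals 1 exactly when `mu == p`.
#'
#' @inheritParams component_means
#' @return numeric vector in (0, 1].
#' @export
separation_factor <- function(mu, p) {
  .check_unit(mu, "mu"); .check_unit(p, "p")
  r <- (mu * (1 - p)) / (p * (1 - mu))
  pmin(r, 1 / r)
}

#' Flexible beta distribution
#'
#' Density and random generation for the flexible beta (FB) distribution:
#' a two-component mixture of betas with common precision `phi` and means
#' `lambda1 > lambda2` given by [component_means()]. Compounding a
#' binomial with an FB mixing density yields the flexible beta-binomial.
#'
#' @param x vector of values in (0, 1).
#' @inheritParams component_means
#' @inheritParams dbetabinom
#' @export
dflexbeta <- function(x, mu, w, phi, p, log = FALSE) {
  .check_pos(phi, "phi")
  lam <- component_means(mu, w, p)
  out <- .log_sum_exp(
    log(p) + stats::dbeta(x, phi * lam$lambda1, phi * (1 - lam$lambda1), log = TRUE),
    log1p(-p) + stats::dbeta(x, phi * lam$lambda2, phi * (1 - lam$lambda2), log = TRUE)
  )
  if (log) out else exp(out)
}

#' @rdname dflexbeta
#' @export
rflexbeta <- function(n, mu, w, phi, p) {
  .check_pos(phi, "phi")
  lam <- component_means(mu, w, p)
  k <- stats::runif(n) < p
  m <- ifelse(k, lam$lambda1, lam$lambda2)
  stats::rbeta(n, phi * m, phi * (1 - m))
}

#' Flexible beta-binomial distribution
#'
#' Density (pmf) and random generation for the flexible beta-binomial
#' (FBB): a binomial count compounded with a flexible beta mixing density,
#' equivalently the two-component beta-binomial mixture
#' \deqn{f(y) = p\, f_{BB}(y; \lambda_1, \phi) +
#'             (1-p)\, f_{BB}(y; \lambda_2, \phi).}
#' The component log-pmfs are combined with a log-sum-exp. Fixing
#' `mu = p`, `w = 1/phi` and `phi = nu + 1` recovers the beta-binomial
#' `BB(n, mu, nu)` exactly (the BB is an inner point of the family).
#'
#' @inheritParams dbetabinom
#' @inheritParams component_means
#' @examples
#' # bimodal shape with well-separated components
#' dfbbinom(0:10, size = 10, mu = 0.5, w = 0.9, phi = 9, p = 0.5)
#' @export
dfbbinom <- function(x, size, mu, w, phi, p, log = FALSE) {
  lam <- component_means(mu, w, p)
  out <- .log_sum_exp(
    log(p) + dbetabinom(x, size, lam$lambda1, phi, log = TRUE),
    log1p(-p) + dbetabinom(x, size, lam$lambda2, phi, log = TRUE)
  )
  if (log) out else exp(out)
}

#' @rdname dfbbinom
#' @export
rfbbinom <- function(n, size, mu, w, phi, p) {
  pi <- rflexbeta(n, mu, w, phi, p)
  stats::rbinom(n, size, pi)
}

#' Moments of the flexible beta-binomial
#'
#' Mean `n * mu`; the variance adds to the beta-binomial inflation a third
#' term driven by the latent two-group structure:
#' \deqn{Var(Y) = n\mu(1-\mu)\Big[1 + \frac{n-1}{\phi+1} +
#'   \frac{(n-1)\phi}{\phi+1} w^2 m(\mu, p)\Big],}
#' equivalently `n mu (1-mu) (1 + (n-1) rho)` with `rho = icc_fbbinom()`.
#'
#' @inheritParams dfbbinom
#' @return a tibble with columns `mean` and `variance`.
#' @export
fbbinom_moments <- function(size, mu, w, phi, p) {
  rho <- icc_fbbinom(mu, w, phi, p)
  tibble::tibble(
    mean = size * mu,
    variance = size * mu * (1 - mu) * (1 + (size - 1) * rho)
  )
}

#' Intraclass correlation of the flexible beta-binomial
#'
#' `rho = theta + (1 - theta) * w^2 * m(mu, p)` with `theta = 1/(phi+1)`:
#' a weighted mean of the beta-binomial intraclass correlation and the
#' squared normalized separation. Increasing in `w`; collapses to `theta`
#' as `w -> 0`, `p -> 0` or `p -> 1`; symmetric in `(mu, p)`; and, unlike
#' the beta-binomial one, depends on `mu`, so under a regression it is
#' naturally modeled as a function of covariates.
#'
#' @inheritParams dfbbinom
#' @return numeric vector in (0, 1).
#' @export
icc_fbbinom <- function(mu, w, phi, p) {
  .check_pos(phi, "phi")
  .check_unit(w, "w")
  theta <- 1 / (phi + 1)
  theta + (1 - theta) * w^2 * separation_factor(mu, p)
}

#' Probability of zero successes under the flexible beta-binomial
#'
#' Mixture of the component zero probabilities,
#' `p * d0(lambda1) + (1-p) * d0(lambda2)`. Increasing in `w`, tending to
#' the beta-binomial zero probability as `w -> 0` or as `p` approaches
#' either boundary, and maximal over `p` at `p = mu`.
#'
#' @inheritParams dfbbinom
#' @return numeric vector of probabilities.
#' @export
prob_zero_fbbinom <- function(size, mu, w, phi, p) {
  lam <- component_means(mu, w, p)
  p * prob_zero_betabinom(size, lam$lambda1, phi) +
    (1 - p) * prob_zero_betabinom(size, lam$lambda2, phi)
}

# ---- zero-inflated families -------------------------------------------

#' Zero-inflated binomial and beta-binomial distributions
#'
#' A point mass at zero with weight `q` mixed with a base binomial
#' (`dzibinom`) or beta-binomial (`dzibetabinom`) pmf:
#' `f(0) = q + (1 - q) f0(0)` and `f(y) = (1 - q) f0(y)` for `y >= 1`.
#' The zero branch is computed as a log-sum-exp of `log(q)` and
#' `log(1 - q) + log f0(0)`.
#'
#' @inheritParams dbetabinom
#' @param prob binomial success probability, in (0, 1).
#' @param q zero-inflation probability, in (0, 1).
#' @export
dzibinom <- function(x, size, prob, q, log = FALSE) {
  .check_unit(prob, "prob"); .check_unit(q, "q")
  .check_counts(x, size)
  base <- stats::dbinom(x, size, prob, log = TRUE)
  out <- log1p(-q) + base
  at0 <- x == 0
  if (any(at0)) {
    out[at0] <- .log_sum_exp(rep_len(log(q), sum(at0)), out[at0])
  }
  if (log) out else exp(out)
}

#' @rdname dzibinom
#' @export
dzibetabinom <- function(x, size, mu, phi, q, log = FALSE) {
  .check_unit(q, "q")
  base <- dbetabinom(x, size, mu, phi, log = TRUE)
  out <- log1p(-q) + base
  at0 <- x == 0
  if (any(at0)) {
    out[at0] <- .log_sum_exp(rep_len(log(q), sum(at0)), out[at0])
  }
  if (log) out else exp(out)
}

#' @rdname dzibinom
#' @export
rzibinom <- function(n, size, prob, q) {
  .check_unit(prob, "prob"); .check_unit(q, "q")
  y <- stats::rbinom(n, size, prob)
  y[stats::runif(n) < q] <- 0L
  y
}

#' @rdname dzibinom
#' @export
rzibetabinom <- function(n, size, mu, phi, q) {
  .check_unit(q, "q")
  y <- rbetabinom(n, size, mu, phi)
  y[stats::runif(n) < q] <- 0L
  y
}
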