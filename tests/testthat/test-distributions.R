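# exact-math checks for the BB / FBB / zero-inflated families

test_that("beta-binomial pmf matches Bernoulli and high-precision values", {
  # n = 1 collapses to Bernoulli(mu)
  expect_equal(dbetabinom(1, 1, 0.3, 5, log = TRUE), log(0.3))
  expect_equal(dbetabinom(0, 1, 0.3, 5, log = TRUE), log(0.7))
  # frozen value from an arbitrary-precision evaluation of
  # choose(10,3) * B(4.5 + 3, 4.5 + 7) / B(4.5, 4.5)
  expect_equal(dbetabinom(3, 10, 0.5, 9), 0.1243743896484375, tolerance = 1e-12)
  expect_error(dbetabinom(11, 10, 0.5, 9), "integer count")
  expect_error(dbetabinom(3, 10, 1.2, 9), "inside \\(0, 1\\)")
  expect_error(dbetabinom(3, 10, 0.5, -1), "positive")
})

test_that("pmfs are normalized over their support", {
  set.seed(42)
  for (i in 1:8) {
    n <- sample(1:200, 1)
    mu <- runif(1, 0.05, 0.95); phi <- runif(1, 0.2, 50)
    pp <- random_fbb_params()
    q <- runif(1, 0.05, 0.95)
    expect_equal(sum(dbetabinom(0:n, n, mu, phi)), 1, tolerance = 1e-10)
    expect_equal(sum(dfbbinom(0:n, n, pp$mu, pp$w, pp$phi, pp$p)), 1,
                 tolerance = 1e-10)
    expect_equal(sum(dzibinom(0:n, n, mu, q)), 1, tolerance = 1e-10)
    expect_equal(sum(dzibetabinom(0:n, n, mu, phi, q)), 1, tolerance = 1e-10)
  }
})

test_that("component means satisfy the mixture identity and ordering", {
  lam <- component_means(mu = 1/3, w = 0.75, p = 0.5)
  # min(2/3, 4/3) = 2/3, offsets 0.25 each
  expect_equal(lam$lambda1, 1/3 + 0.25, tolerance = 1e-12)
  expect_equal(lam$lambda2, 1/3 - 0.25, tolerance = 1e-12)
  set.seed(1)
  pp <- random_fbb_params(200)
  lam <- component_means(pp$mu, pp$w, pp$p)
  expect_true(all(lam$lambda1 > lam$lambda2))
  expect_true(all(lam$lambda1 < 1 & lam$lambda2 > 0))
  expect_equal(pp$p * lam$lambda1 + (1 - pp$p) * lam$lambda2, pp$mu,
               tolerance = 1e-12)
  # both means collapse to mu as w -> 0
  lam0 <- component_means(0.5, 1e-9, 0.5)
  expect_equal(unlist(lam0), c(lambda1 = 0.5, lambda2 = 0.5), tolerance = 1e-8)
  expect_error(component_means(0, 0.5, 0.5), "inside")
})

test_that("separation factor is a swap-symmetric min of reciprocal odds ratios", {
  expect_equal(separation_factor(0.4, 0.4), 1)
  expect_equal(separation_factor(0.2, 0.5), 0.25)
  set.seed(2)
  a <- runif(50, 0.02, 0.98); b <- runif(50, 0.02, 0.98)
  expect_equal(separation_factor(a, b), separation_factor(b, a))
  expect_true(all(separation_factor(a, b) > 0 & separation_factor(a, b) <= 1))
})

test_that("FBB pmf equals the matched BB at the inner-point identity", {
  set.seed(3)
  for (i in 1:5) {
    p0 <- runif(1, 0.1, 0.9); nu <- runif(1, 0.5, 20); n <- sample(5:60, 1)
    expect_equal(
      dfbbinom(0:n, n, mu = p0, w = 1 / (nu + 1), phi = nu + 1, p = p0),
      dbetabinom(0:n, n, p0, nu),
      tolerance = 1e-12
    )
  }
})

test_that("FBB pmf agrees with numerical compounding over the FB density", {
  set.seed(4)
  pp <- random_fbb_params(4)
  for (i in seq_len(nrow(pp))) {
    n <- 17
    expect_equal(
      dfbbinom(0:n, n, pp$mu[i], pp$w[i], pp$phi[i], pp$p[i]),
      fbb_pmf_quadrature(0:n, n, pp$mu[i], pp$w[i], pp$phi[i], pp$p[i]),
      tolerance = 1e-7
    )
  }
})

test_that("well-separated FBB components give a bimodal pmf", {
  f <- dfbbinom(0:10, 10, mu = 0.5, w = 0.95, phi = 9, p = 0.5)
  d <- diff(f)
  n_max <- sum(d[-length(d)] > 0 & d[-1] < 0) +
    (d[1] < 0) + (d[length(d)] > 0) # boundary modes
  expect_gte(n_max, 2)
})

test_that("moment formulas match their samplers and limits", {
  # Bernoulli case: overdispersion term vanishes
  expect_equal(betabinom_moments(1, 0.3, 2)$variance, 0.3 * 0.7)
  # phi -> infinity recovers the binomial variance
  expect_equal(betabinom_moments(20, 0.3, 1e9)$variance, 20 * 0.3 * 0.7,
               tolerance = 1e-6)
  set.seed(5)
  y <- rbetabinom(1e6, 20, 0.3, 4)
  m <- betabinom_moments(20, 0.3, 4)
  se_mean <- sqrt(m$variance / 1e6)
  expect_equal(mean(y), m$mean, tolerance = 4 * se_mean / m$mean)
  se_var <- sqrt(2 / 1e6) * m$variance # normal-ish bound on var MC error
  expect_lt(abs(var(y) - m$variance), 4 * se_var * 2)

  y2 <- rfbbinom(1e6, 10, mu = 1/3, w = 0.75, phi = 2.333, p = 0.5)
  m2 <- fbbinom_moments(10, 1/3, 0.75, 2.333, 0.5)
  expect_equal(mean(y2), m2$mean, tolerance = 4 * sqrt(m2$variance / 1e6) / m2$mean)
  expect_lt(abs(var(y2) - m2$variance), 4 * sqrt(2 / 1e6) * m2$variance * 2)
  # FBB identity case matches matched BB moments; variance never smaller
  expect_equal(
    fbbinom_moments(10, 0.4, w = 1 / 3, phi = 3, p = 0.4),
    betabinom_moments(10, 0.4, 2)
  )
  set.seed(6)
  pp <- random_fbb_params(50)
  expect_true(all(
    fbbinom_moments(25, pp$mu, pp$w, pp$phi, pp$p)$variance >=
      betabinom_moments(25, pp$mu, pp$phi)$variance
  ))
})

test_that("intraclass correlations follow the closed forms", {
  expect_equal(icc_betabinom(1), 0.5)
  expect_equal(icc_betabinom(99), 0.01)
  expect_lt(icc_betabinom(1e12), 1e-11)
  # mu = p gives m = 1, rho = theta + (1 - theta) w^2
  expect_equal(icc_fbbinom(0.3, 0.6, 3, 0.3), 0.25 + 0.75 * 0.36)
  # direct arithmetic: theta = 0.25, m = 0.25
  expect_equal(icc_fbbinom(0.2, 0.5, 3, 0.5), 0.296875)
  # w -> 0 limit recovers the BB ICC
  expect_equal(icc_fbbinom(0.3, 1e-8, 4, 0.6), icc_betabinom(4), tolerance = 1e-10)
  set.seed(7)
  pp <- random_fbb_params(50)
  rho <- icc_fbbinom(pp$mu, pp$w, pp$phi, pp$p)
  theta <- 1 / (pp$phi + 1)
  expect_true(all(rho > theta & rho < 1))
  # monotone increasing in w, symmetric in (mu, p)
  w_grid <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(icc_fbbinom(0.3, w_grid, 2, 0.6)) > 0))
  expect_equal(icc_fbbinom(pp$mu, pp$w, pp$phi, pp$p),
               icc_fbbinom(pp$p, pp$w, pp$phi, pp$mu))
})

test_that("zero probabilities match the pmf at zero and their limits", {
  expect_equal(prob_zero_betabinom(1, 0.3, 2), 0.7)
  expect_equal(prob_zero_betabinom(5, 0.3, 2), dbetabinom(0, 5, 0.3, 2),
               tolerance = 1e-12)
  # mu -> 1 sends the zero probability to 0
  expect_lt(prob_zero_betabinom(10, 1 - 1e-6, 2), 1e-4)
  set.seed(8)
  pp <- random_fbb_params(20)
  expect_equal(
    prob_zero_fbbinom(12, pp$mu, pp$w, pp$phi, pp$p),
    dfbbinom(0, 12, pp$mu, pp$w, pp$phi, pp$p),
    tolerance = 1e-12
  )
  # w -> 0 limit: within 1e-6 at distance 1e-4 from the boundary
  expect_equal(prob_zero_fbbinom(8, 0.4, 1e-4, 3, 0.6),
               prob_zero_betabinom(8, 0.4, 3), tolerance = 1e-6)
  expect_equal(prob_zero_fbbinom(8, 0.4, 0.3, 3, 1e-4),
               prob_zero_betabinom(8, 0.4, 3), tolerance = 1e-3)
  expect_equal(prob_zero_fbbinom(8, 0.4, 0.3, 3, 1 - 1e-4),
               prob_zero_betabinom(8, 0.4, 3), tolerance = 1e-3)
  # monotone increasing in w; maximized over p at p = mu
  w_grid <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(prob_zero_fbbinom(10, 0.35, w_grid, 2, 0.5)) > 0))
  p_grid <- seq(0.01, 0.99, by = 0.001)
  d0 <- prob_zero_fbbinom(10, 0.35, 0.5, 2, p_grid)
  expect_equal(p_grid[which.max(d0)], 0.35, tolerance = 0.01)
})

test_that("zero-inflated pmfs mix a point mass with the base pmf", {
  # q -> 0 reduces to the base pmf
  expect_equal(dzibinom(0:5, 5, 0.4, 1e-9), dbinom(0:5, 5, 0.4), tolerance = 1e-7)
  # base f(0) = 0.1 (Bernoulli with prob 0.9), q = 0.5 -> f_ZI(0) = 0.55
  expect_equal(dzibinom(0, 1, 0.9, 0.5, log = TRUE), log(0.55))
  expect_equal(dzibetabinom(2, 6, 0.3, 2, 0.25),
               0.75 * dbetabinom(2, 6, 0.3, 2))
})

test_that("samplers are seed-reproducible and match the exact pmf", {
  set.seed(11); a <- rfbbinom(100, 20, 0.4, 0.6, 3, 0.3)
  set.seed(11); b <- rfbbinom(100, 20, 0.4, 0.6, 3, 0.3)
  expect_identical(a, b)
  set.seed(12)
  B <- 2e5; n <- 12
  y <- rfbbinom(B, n, 0.4, 0.6, 3, 0.3)
  emp <- tabulate(y + 1L, nbins = n + 1) / B
  exact <- dfbbinom(0:n, n, 0.4, 0.6, 3, 0.3)
  tv <- 0.5 * sum(abs(emp - exact))
  expect_lt(tv, 4 * (n + 1) / sqrt(B)) # generous Monte-Carlo bound
  expect_equal(mean(y), n * 0.4, tolerance = 0.02)
  # flexible-beta sampler agrees with its density in distribution
  set.seed(13)
  x <- rflexbeta(2e5, 0.4, 0.6, 3, 0.3)
  expect_equal(mean(x), 0.4, tolerance = 0.01)
  ks <- suppressWarnings(stats::ks.test(
    x[1:2000], function(qq) vapply(qq, function(u) {
      stats::integrate(dflexbeta, 0, u, mu = 0.4, w = 0.6, phi = 3, p = 0.3,
                       rel.tol = 1e-8)$value
    }, numeric(1))))
  expect_gt(ks$p.value, 1e-4)
})
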