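# shared fixtures: random interior parameter draws and an independent
# quadrature route to the FBB pmf (binomial compounded against the
# flexible-beta mixing density), used as an oracle for the mixture form.

random_fbb_params <- function(k = 1) {
  tibble::tibble(
    mu = runif(k, 0.05, 0.95),
    w = runif(k, 0.05, 0.95),
    phi = runif(k, 0.2, 30),
    p = runif(k, 0.05, 0.95)
  )
}

# compound representation: integrate Binomial(n, pi) against the FB density
fbb_pmf_quadrature <- function(y, size, mu, w, phi, p) {
  vapply(y, function(yi) {
    stats::integrate(
      function(pi) stats::dbinom(yi, size, pi) * dflexbeta(pi, mu, w, phi, p),
      0, 1, rel.tol = 1e-10, subdivisions = 500L
    )$value
  }, numeric(1))
}

# a minimal object that quacks like an fbb_fit for summary/diagnostic
# functions operating only on the draws tibble
fake_fit <- function(draws_by_chain) {
  draws <- purrr::imap_dfr(draws_by_chain, function(m, ch) {
    m <- as.data.frame(m)
    dplyr::bind_cols(tibble::tibble(.chain = as.integer(ch), .iter = seq_len(nrow(m))), m)
  })
  structure(list(draws = draws), class = "fbb_fit")
}

quick_scenario_fit <- function(family, scenario = 1, N = 60, iter = 1200,
                               chains = 2, seed = 1) {
  d <- simulate_fit_scenario(scenario, N = N, seed = seed)
  fbb_fit(d, y ~ x, trials = n, family = family, chains = chains,
          iter = iter, seed = seed)
}
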