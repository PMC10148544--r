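test_that("pointwise log-likelihood matches hand-computed Bernoulli values", {
  # a single subject at p = 0.5
  ll <- log_likelihood(0, 0, 0, matrix(0, 1, 1), 1, 1)
  expect_equal(ll$pointwise, log(0.5), tolerance = 1e-12)

  # two subjects with p = (0.9, 0.2): total = log 0.9 + log 0.8
  X <- matrix(qlogis(c(0.9, 0.2)), 2, 1)
  ll2 <- log_likelihood(1, 0, c(0, 0), X, c(1, 0), c(1, 2))
  expect_equal(ll2$total, log(0.9) + log(0.8), tolerance = 1e-10)
  expect_equal(sum(ll2$pointwise), ll2$total)

  # all-events likelihood increases monotonically to 0 as b0 grows
  X0 <- matrix(0, 4, 1)
  tot <- vapply(c(0, 5, 20, 100), function(b0) {
    log_likelihood(0, b0, 0, X0, rep(1, 4), rep(1, 4))$total
  }, numeric(1))
  expect_true(all(diff(tot) > 0))
  expect_gt(tot[4], -1e-10)

  # stable far into the tails
  expect_true(is.finite(
    log_likelihood(0, 700, 0, X0, rep(0, 4), rep(1, 4))$total))
  expect_error(log_likelihood(c(1, 2), 0, 0, X0, rep(1, 4), rep(1, 4)),
               "beta")
})

test_that("half-t density is analytic and normalized", {
  expect_equal(dhalf_cauchy(0), 2 / pi, tolerance = 1e-12)
  expect_equal(dhalf_t(0, df = 1), 2 / pi, tolerance = 1e-12)
  expect_equal(dhalf_t(-1, df = 3), 0)
  # independent closed form of the half-Cauchy
  x <- c(0.1, 0.5, 2, 7)
  expect_equal(dhalf_cauchy(x), 2 / (pi * (1 + x^2)), tolerance = 1e-12)
  for (df in c(1, 3, 5, 7)) {
    q <- integrate(dhalf_t, 0, Inf, df = df, scale = 1.7)$value
    expect_equal(q, 1, tolerance = 1e-3)
  }
})

test_that("horseshoe log prior equals independent density evaluation", {
  # standard normal at 0 for the coefficient term
  expect_equal(log_prior_horseshoe(0, 1, 1, df = 1),
               -0.5 * log(2 * pi) + 2 * log(1 / pi),
               tolerance = 1e-10)
  # brute-force closed forms, written out rather than reusing the package
  beta <- 0.5; lambda <- 2; tau <- 0.5
  norm_term <- -0.5 * log(2 * pi) - log(lambda * tau) -
    beta^2 / (2 * (lambda * tau)^2)
  hc <- function(x, s) 2 / (pi * s * (1 + (x / s)^2))
  expect_equal(log_prior_horseshoe(beta, lambda, tau, df = 1),
               norm_term + log(hc(lambda, 1)) + log(hc(tau, 1)),
               tolerance = 1e-10)
  # df = 5 local term via the explicit Student-t formula
  df <- 5
  t5 <- gamma((df + 1) / 2) / (gamma(df / 2) * sqrt(df * pi)) *
    (1 + lambda^2 / df)^(-(df + 1) / 2)
  expect_equal(log_prior_horseshoe(beta, lambda, tau, df = 5),
               norm_term + log(2 * t5) + log(hc(tau, 1)),
               tolerance = 1e-10)
  # literal parameterization: scale carried by the local prior
  lit <- -0.5 * log(2 * pi) - log(lambda) - beta^2 / (2 * lambda^2) +
    log(hc(lambda, tau)) + log(hc(tau, 1))
  expect_equal(log_prior_horseshoe(beta, lambda, tau, df = 1, literal = TRUE),
               lit, tolerance = 1e-10)
  expect_error(log_prior_horseshoe(0, 1, 1, df = 2), "df")
  expect_error(log_prior_horseshoe(0, -1, 1, df = 1), "positive")
})

test_that("laplace prior: compound form, change of variables, marginal", {
  # exponential mixing density at tau^2 = 0 is alpha^2/2
  expect_equal(dexp(0, rate = 2^2 / 2), 2, tolerance = 1e-12)
  # marginal double-exponential closed form
  expect_equal(dlaplace_marginal(0), 0.5, tolerance = 1e-12)
  expect_equal(dlaplace_marginal(1.3, alpha = 2, sigma = 0.5),
               2 * exp(-2 * 1.3 / 0.5), tolerance = 1e-10)
  # joint log-density at (beta, tau) = (0.3, 1.2), alpha = 2, sigma = 1
  beta <- 0.3; tau <- 1.2; alpha <- 2
  by_hand <- (-0.5 * log(2 * pi) - log(tau) - beta^2 / (2 * tau^2)) +
    (log(alpha^2 / 2) - alpha^2 / 2 * tau^2) + log(2 * tau)
  expect_equal(log_prior_laplace(beta, tau, alpha = alpha, sigma = 1),
               by_hand, tolerance = 1e-10)
  # integrating the compound over tau recovers the marginal Laplace
  marg <- integrate(function(t) {
    vapply(t, function(ti) {
      exp(log_prior_laplace(0.8, ti, alpha = 1.5, sigma = 1))
    }, numeric(1))
  }, 0, Inf)$value
  expect_equal(marg, dlaplace_marginal(0.8, alpha = 1.5), tolerance = 1e-6)
  expect_equal(integrate(dlaplace_marginal, -Inf, Inf, alpha = 1.3)$value, 1,
               tolerance = 1e-6)
  expect_error(log_prior_laplace(0, -1), "positive")
})

test_that("shrinkage ordering: horseshoe spikes at zero, out-tails laplace", {
  # marginal horseshoe density (tau fixed at 1) by quadrature
  hs_marginal <- function(b) {
    integrate(function(l) {
      dnorm(b, 0, l) * dhalf_cauchy(l)
    }, 0, Inf, rel.tol = 1e-10)$value
  }
  # near zero the horseshoe is far above the vague Normal(0, 100)
  expect_gt(log(hs_marginal(0.01)), dnorm(0.01, 0, 100, log = TRUE))
  # at |beta| = 10 its tail is heavier than the Laplace's
  expect_gt(log(hs_marginal(10)), dlaplace_marginal(10, log = TRUE))
})

test_that("log posterior is additive and matches a naive-loop oracle", {
  set.seed(42)
  n <- 5; p <- 3
  X <- matrix(rnorm(n * p), n, p)
  y <- c(1, 0, 0, 1, 0)
  site <- c(1, 2, 1, 2, 1)
  params <- list(beta = c(0.5, -0.2, 0.1), b0 = -1.5, u = c(0.1, -0.3),
                 sigma_site = 0.4, lambda = c(1.2, 0.5, 2), tau = 0.7)
  for (prior in list(prior_spec("horseshoe", df = 3),
                     prior_spec("laplace", df = 3), prior_spec("vague"))) {
    lp <- log_posterior(params, X, y, site, prior)
    expect_true(is.finite(lp))
    # additivity: recompute from the exported components
    prior_term <- switch(prior$family,
      horseshoe = log_prior_horseshoe(params$beta, params$lambda, params$tau,
                                      df = prior$df),
      laplace = log_prior_laplace(params$beta, params$tau),
      vague = log_prior_vague(params$beta))
    expect_equal(lp,
                 log_likelihood(params$beta, params$b0, params$u, X, y,
                                site)$total + prior_term +
                   dnorm(params$b0, 0, 100, log = TRUE) +
                   sum(dnorm(params$u, 0, params$sigma_site, log = TRUE)) +
                   dhalf_t(params$sigma_site, 4, 2.5, log = TRUE),
                 tolerance = 1e-10)
  }
  # fully independent naive-loop recomputation, vague prior
  acc <- 0
  for (i in 1:n) {
    eta <- params$b0 + params$u[site[i]]
    for (j in 1:p) eta <- eta + X[i, j] * params$beta[j]
    prob <- 1 / (1 + exp(-eta))
    acc <- acc + if (y[i] == 1) log(prob) else log(1 - prob)
  }
  for (j in 1:p) {
    acc <- acc - 0.5 * log(2 * pi) - log(100) - params$beta[j]^2 / (2 * 100^2)
  }
  acc <- acc - 0.5 * log(2 * pi) - log(100) - params$b0^2 / (2 * 100^2)
  for (s in 1:2) {
    acc <- acc - 0.5 * log(2 * pi) - log(params$sigma_site) -
      params$u[s]^2 / (2 * params$sigma_site^2)
  }
  nu <- 4; sc <- 2.5; z <- params$sigma_site / sc
  acc <- acc + log(2) - log(sc) + lgamma((nu + 1) / 2) - lgamma(nu / 2) -
    0.5 * log(nu * base::pi) - (nu + 1) / 2 * log(1 + z^2 / nu)
  expect_equal(log_posterior(params, X, y, site, prior_spec("vague")), acc,
               tolerance = 1e-8)
})
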