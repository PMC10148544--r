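test_that("pointwise log-likelihood matrix matches a per-subject oracle", {
  set.seed(7)
  n <- 5; p <- 3; S <- 20
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("v", 1:p)
  y <- c(1, 0, 1, 0, 0)
  site <- c(1, 2, 1, 2, 1)
  B <- matrix(rnorm(S * p, 0, 0.5), S, p)
  colnames(B) <- colnames(X)
  u <- matrix(rnorm(S * 2, 0, 0.2), S, 2)
  fit <- fake_fit(B, b0 = rnorm(S, -1, 0.3), u = u)
  ll <- pointwise_loglik_matrix(fit, X, y, site)
  expect_equal(dim(ll), c(S, n))
  # naive loop oracle
  for (s in c(1, 9, S)) {
    for (i in 1:n) {
      eta <- unname(fit$draws[s, "b0"]) + u[s, site[i]] + sum(X[i, ] * B[s, ])
      pr <- 1 / (1 + exp(-eta))
      expect_equal(ll[s, i], if (y[i] == 1) log(pr) else log(1 - pr),
                   tolerance = 1e-10)
    }
  }
  # row sums equal the per-draw total log-likelihood
  expect_equal(rowSums(ll)[3],
               log_likelihood(B[3, ], fit$draws[3, "b0"], u[3, ], X, y,
                              site)$total, tolerance = 1e-10)
  # single draw at p = 0.5 everywhere
  f0 <- fake_fit(matrix(0, 2, p, dimnames = list(NULL, colnames(X))))
  expect_true(all(abs(pointwise_loglik_matrix(f0, X * 0, y) - log(0.5)) <
                    1e-12))
  expect_error(pointwise_loglik_matrix(fit, X[, 1:2], y, site), "match")
})

test_that("WAIC reproduces hand arithmetic and degenerate cases", {
  # 2 draws, 1 subject: lppd = log 0.375, p_waic = var(ll), elpd = -1.2210
  ll <- matrix(log(c(0.5, 0.25)), 2, 1)
  w <- compute_waic(ll)
  expect_equal(w$elpd_waic, log(0.375) - var(log(c(0.5, 0.25))),
               tolerance = 1e-10)
  expect_equal(w$elpd_waic, -1.221, tolerance = 1e-3)
  expect_equal(w$waic, -2 * w$elpd_waic)
  # constant draws: zero effective parameters, waic = -2 sum ll
  llc <- matrix(log(0.3), 50, 4)
  wc <- compute_waic(llc)
  expect_equal(wc$p_waic, 0)
  expect_equal(wc$waic, -2 * 4 * log(0.3), tolerance = 1e-10)
  expect_error(compute_waic(matrix(c(log(0.5), -Inf), 2, 1)), "finite")
  # doubling the data doubles elpd in expectation
  set.seed(3)
  ll1 <- matrix(rnorm(2000, -0.5, 0.1), 100, 20)
  w1 <- compute_waic(ll1)
  w2 <- compute_waic(cbind(ll1, ll1))
  expect_equal(w2$elpd_waic, 2 * w1$elpd_waic, tolerance = 1e-9)
})

test_that("PSIS-LOO agrees with WAIC when draws are constant", {
  llc <- matrix(log(0.3), 200, 4)
  l <- compute_psis_loo(llc)
  w <- compute_waic(llc)
  expect_equal(l$elpd_loo, w$elpd_waic, tolerance = 1e-10)
  expect_equal(l$looic, w$waic, tolerance = 1e-10)
  expect_true(all(l$pareto_k == 0))
})

test_that("PSIS-LOO tracks WAIC on well-specified simulated draws", {
  set.seed(21)
  S <- 800; n <- 60
  # simulated Bernoulli log-likelihoods with draw-level wobble
  p_true <- runif(n, 0.1, 0.9)
  y <- rbinom(n, 1, p_true)
  eta <- outer(rnorm(S, 0, 0.2), qlogis(p_true), "+")
  pr <- plogis(eta)
  ll <- t(t(log(pr)) * y + t(log(1 - pr)) * (1 - y))
  l <- compute_psis_loo(ll)
  w <- compute_waic(ll)
  expect_lt(abs(l$elpd_loo - w$elpd_waic),
            2 * sqrt(l$se_elpd^2 + w$se_elpd^2))
  expect_true(all(l$pareto_k < 0.7))
  expect_gte(l$p_loo, 0)
})

test_that("model ranking orders by LOOIC and excludes failures", {
  mk <- function(id, looic, waic, conv) {
    s <- data.frame(id = id, family = "horseshoe", df = 1,
                    elpd_waic = -waic / 2, p_waic = 1, waic = waic,
                    se_waic = 1, elpd_loo = -looic / 2, p_loo = 1,
                    looic = looic, se_looic = 1, max_pareto_k = 0.1,
                    converged = conv, escalations = 0)
    class(s) <- c("model_score", "data.frame")
    s
  }
  tab <- rank_models(list(mk("a", 100, 100, TRUE), mk("b", 90, 95, TRUE),
                          mk("c", 95, 90, TRUE), mk("bad", 10, 10, FALSE)))
  expect_identical(tab$id[which(tab$rank == 1)], "b")
  expect_identical(tab$id[1:3], c("b", "c", "a"))
  # the non-converged model is present but never ranked
  expect_true(is.na(tab$rank[tab$id == "bad"]))
  # ties on looic break by waic
  t2 <- rank_models(list(mk("x", 50, 60, TRUE), mk("y", 50, 55, TRUE)))
  expect_identical(t2$id[which(t2$rank == 1)], "y")
  expect_error(rank_models(list(mk("z", 1, 1, FALSE))), "converged")
})

test_that("harm probabilities summarize coefficient draws exactly", {
  B <- matrix(c(0.2, 0.4, 0.6, -0.1), 4, 1, dimnames = list(NULL, "x"))
  h <- harm_probabilities(fake_fit(B))
  expect_equal(h$p_harm, 0.75)
  expect_equal(h$median_ror, exp(0.3), tolerance = 1e-10)
  # symmetric draws: probability one half
  Bs <- matrix(c(-2, -1, 1, 2), 4, 1, dimnames = list(NULL, "x"))
  expect_equal(harm_probabilities(fake_fit(Bs))$p_harm, 0.5)
  # location shift multiplies the median odds ratio by exp(c) exactly
  set.seed(2)
  B2 <- matrix(rnorm(501), 501, 1, dimnames = list(NULL, "x"))
  h0 <- harm_probabilities(fake_fit(B2))
  h1 <- harm_probabilities(fake_fit(B2 + 0.8))
  expect_equal(h1$median_ror, h0$median_ror * exp(0.8), tolerance = 1e-10)
  # interval ordered around the median
  expect_true(all(h0$cri_low <= h0$median_ror & h0$median_ror <= h0$cri_high))
})

test_that("hard shrinkage keeps tails and whole categorical blocks", {
  harm <- data.frame(
    variable = c("a", "b", "c", "race_black", "race_other"),
    predictor = c("a", "b", "c", "race", "race"),
    median_ror = 1, cri_low = 1, cri_high = 1,
    p_harm = c(0.90, 0.50, 0.06, 0.70, 0.40),
    important = FALSE)
  sel <- hard_shrinkage(harm, 0.65)
  expect_setequal(sel$predictors, c("a", "c", "race"))
  # the whole race block rides along although only one dummy passed
  expect_true(all(c("race_black", "race_other") %in% sel$columns))
  expect_warning(hard_shrinkage(harm, 0.95), "intercept-only")
  expect_error(hard_shrinkage(harm, 0.4), "threshold")
  # monotonicity: higher thresholds select nested subsets
  set.seed(9)
  rh <- data.frame(variable = sprintf("v%02d", 1:30),
                   predictor = sprintf("v%02d", 1:30),
                   median_ror = 1, cri_low = 1, cri_high = 1,
                   p_harm = runif(30), important = FALSE)
  prev <- NULL
  for (t in c(0.55, 0.6, 0.65, 0.7, 0.8)) {
    cur <- suppressWarnings(hard_shrinkage(rh, t)$predictors)
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})
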