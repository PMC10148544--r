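# Shared fixtures: all synthetic, built in code at test time.

# Down-scaled default cohort for pipeline tests.
small_cohort <- function(n = 300L, seed = 3L) {
  cfg <- default_pnat_config(seed = seed)
  cfg$n_subjects <- as.integer(n)
  generate_cohort(cfg)
}

# Short chains for smoke-level MCMC tests.
tiny_mcmc <- function(seed = 9L, chains = 2, iters = 300) {
  mcmc_config(chains = chains, warmup = iters, sampling = iters, seed = seed)
}

# A config of independent continuous predictors with a sparse set of true
# effects -- the recovery-study generator (n subjects, p predictors, the
# first few carrying the given log odds ratios).
sparse_config <- function(n = 1200L, p = 43L, effects = c(0.7, -0.6, 0.5),
                          seed = 1L, site_sd = 0.3, prevalence = 0.10) {
  cont <- setNames(
    rep(list(list(dist = "normal", mean = 0, sd = 1)), p),
    sprintf("v%02d", seq_len(p)))
  synthetic_config(n_subjects = n, n_sites = 4L, site_sd = site_sd,
                   target_prevalence = prevalence,
                   true_effects = setNames(effects,
                                           names(cont)[seq_along(effects)]),
                   continuous_spec = cont, seed = seed)
}

# Minimal hand-built posterior_fit around a given coefficient draw matrix,
# for testing draw-summarising functions without running MCMC.
fake_fit <- function(B, b0 = NULL, u = NULL, sigma_site = NULL,
                     column_map = NULL) {
  S <- nrow(B)
  draws <- cbind(b0 = b0 %||% rep(0, S), B)
  has_site <- !is.null(u)
  if (has_site) {
    colnames(u) <- paste0("u[", seq_len(ncol(u)), "]")
    draws <- cbind(draws, u, sigma_site = sigma_site %||% rep(0.3, S))
  }
  structure(list(draws = draws, chain = rep(1L, S),
                 diagnostics = data.frame(param = colnames(draws),
                                          rhat = 1, ess = S),
                 divergences = 0L, prior = prior_spec("vague"),
                 mcmc = mcmc_config(chains = 2, seed = 1),
                 beta_names = colnames(B), column_map = column_map,
                 has_site = has_site,
                 n_sites = if (has_site) ncol(u) else 0L,
                 converged = TRUE, escalations_used = 0L),
            class = "posterior_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
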