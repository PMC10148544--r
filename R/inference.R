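#' MCMC sampler settings
#'
#' @param chains number of chains (at least 2 for Rhat validity; default 4).
#' @param warmup adaptation + burn-in iterations per chain (default 1000).
#' @param sampling retained iterations per chain (default 1000).
#' @param seed integer seed; chains get derived RNG streams, so identical
#'   settings reproduce identical draws.
#' @param max_escalations maximum number of refits with longer chains when
#'   convergence fails (default 2).
#' @param escalation_factor multiplier applied to warmup and sampling at
#'   each escalation (default 2).
#' @return an object of class `"mcmc_config"`.
#' @export
mcmc_config <- function(chains = 4, warmup = 1000, sampling = 1000,
                        seed = 1L, max_escalations = 2,
                        escalation_factor = 2) {
  stop_if_not(chains >= 1 && warmup >= 2 && sampling >= 2,
              "chain and iteration counts must be positive")
  stop_if_not(max_escalations >= 0 && escalation_factor > 1,
              "invalid escalation settings")
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 sampling = as.integer(sampling), seed = as.integer(seed),
                 max_escalations = as.integer(max_escalations),
                 escalation_factor = escalation_factor),
            class = "mcmc_config")
}

# JAGS model string for a prior family. Site random intercept included only
# when has_site; p = 0 designs (intercept-only) omit the beta block.
#
# Half-t / half-Cauchy scales are written as inverse-gamma auxiliary
# mixtures (x ~ t+_nu(0, A)  <=>  x^2 | a ~ IG(nu/2, nu/a),
# a ~ IG(1/2, 1/A^2)), and the Laplace as its exponential scale mixture of
# normals, so every conditional is conjugate and the glm module can block
# sample; direct half-Cauchy nodes mix poorly under generic slice updates.
jags_model_string <- function(prior, has_site, p) {
  lik <- if (has_site) {
    "  for (i in 1:n) {
    y[i] ~ dbern(pr[i])
    logit(pr[i]) <- b0 + u[site[i]] + xb[i]
  }"
  } else {
    "  for (i in 1:n) {
    y[i] ~ dbern(pr[i])
    logit(pr[i]) <- b0 + xb[i]
  }"
  }
  xb <- if (p > 1) "  xb <- X %*% beta" else if (p == 1) {
    "  for (i in 1:n) { xb[i] <- X[i, 1] * beta[1] }"
  } else "  for (i in 1:n) { xb[i] <- 0 }"
  site <- if (has_site) sprintf(
    "  for (s in 1:n_site) { u[s] ~ dnorm(0, prec_site) }
  aux_site ~ dgamma(0.5, %.8f)
  prec_site ~ dgamma(%.1f, %d * aux_site)
  sigma_site <- pow(prec_site, -0.5)",
    1 / prior$random_sd_scale^2, prior$random_sd_df / 2,
    prior$random_sd_df) else ""
  hs_global <- "  aux_tau ~ dgamma(0.5, 1)
  prec_tau ~ dgamma(0.5, aux_tau)
  tau <- pow(prec_tau, -0.5)"
  beta <- if (p == 0) "" else switch(prior$family,
    vague = "  for (j in 1:p) { beta[j] ~ dnorm(0, 1.0E-4) }",
    horseshoe = if (prior$literal_horseshoe) paste0(hs_global, "
  for (j in 1:p) {
    aux_lam[j] ~ dgamma(0.5, prec_tau)
    prec_lam[j] ~ dgamma(0.5, aux_lam[j])
    beta[j] ~ dnorm(0, prec_lam[j])
  }") else paste0(hs_global, sprintf("
  for (j in 1:p) {
    aux_lam[j] ~ dgamma(0.5, 1)
    prec_lam[j] ~ dgamma(%.1f, %d * aux_lam[j])
    beta[j] ~ dnorm(0, prec_lam[j] * prec_tau)
  }", prior$df / 2, prior$df)),
    laplace = sprintf(
      "  lambda_lasso ~ dchisqr(%d)
  half_rate_sq <- pow(lambda_lasso * %.8f, 2) / 2
  for (j in 1:p) {
    slab[j] ~ dexp(half_rate_sq)
    beta[j] ~ dnorm(0, 1 / slab[j])
  }", prior$df, prior$alpha / prior$sigma_lasso))
  paste0("model {\n", lik, "\n", xb, "\n",
         "  b0 ~ dnorm(0, 1.0E-4)\n", site, "\n", beta, "\n}\n")
}

# Coerce design input to a plain matrix plus optional column map.
design_parts <- function(design) {
  if (inherits(design, "design_matrix")) {
    list(X = design$matrix, column_map = design$column_map)
  } else {
    X <- as.matrix(design)
    if (is.null(colnames(X)) && ncol(X) > 0) {
      colnames(X) <- paste0("x", seq_len(ncol(X)))
    }
    list(X = X, column_map = NULL)
  }
}

#' Draw from the posterior of the multilevel logistic model
#'
#' Samples the joint posterior of [log_posterior()] with JAGS (block Gibbs
#' with the `glm` module's conditionally-Gaussian samplers). Coefficient
#' columns are named after the design columns; the site random intercept is
#' included when `site_ids` is non-`NULL`. Draws are reproducible given the
#' seed in `mcmc`.
#'
#' @param design a `design_matrix` or numeric matrix (standardized columns).
#' @param y binary outcome vector.
#' @param site_ids integer site index per subject, or `NULL` for a
#'   single-level model.
#' @param prior a [prior_spec()].
#' @param mcmc an [mcmc_config()].
#' @return an object of class `"posterior_fit"`: list with `draws` (matrix,
#'   one row per retained draw, named columns), `chain` (chain index per
#'   row), `diagnostics` (per-parameter split-Rhat and effective sample
#'   size; JAGS reports no divergent transitions, so `divergences` is 0),
#'   `prior`, `mcmc`, `converged`, `escalations_used`.
#' @export
sample_posterior <- function(design, y, site_ids = NULL, prior, mcmc) {
  stop_if_not(inherits(prior, "prior_spec"), "`prior` must be a prior_spec")
  stop_if_not(inherits(mcmc, "mcmc_config"), "`mcmc` must be an mcmc_config")
  dp <- design_parts(design)
  X <- dp$X
  stop_if_not(nrow(X) == length(y), "design rows must match outcome length")
  stop_if_not(all(y %in% c(0, 1)), "`y` must be binary 0/1")
  has_site <- !is.null(site_ids)
  p <- ncol(X)
  dat <- list(y = as.integer(y), n = length(y))
  if (p > 0) { dat$X <- X; dat$p <- p }
  if (has_site) {
    stop_if_not(length(site_ids) == length(y),
                "`site_ids` must match outcome length")
    site_ids <- as.integer(site_ids)
    dat$site <- site_ids
    dat$n_site <- max(site_ids)
  }
  model_str <- jags_model_string(prior, has_site, p)
  inits <- lapply(seq_len(mcmc$chains), function(ch) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = (abs(mcmc$seed) + 104729L * ch) %% .Machine$integer.max,
                b0 = qlogis(min(max(mean(y), 0.02), 0.98)))
    if (p > 0) {
      ini$beta <- rep(0, p)
      if (prior$family == "horseshoe") {
        ini$aux_tau <- 1
        ini$prec_tau <- 4 # tau = 0.5
        ini$aux_lam <- rep(1, p)
        ini$prec_lam <- rep(1, p)
      }
      if (prior$family == "laplace") {
        ini$lambda_lasso <- prior$df
        ini$slab <- rep(1, p)
      }
    }
    if (has_site) {
      ini$aux_site <- 1
      ini$prec_site <- 11 # sigma_site ~ 0.3
      ini$u <- rep(0, dat$n_site)
    }
    ini
  })
  monitors <- c("b0", if (p > 0) "beta",
                if (has_site) c("u", "sigma_site"),
                if (p > 0 && prior$family == "horseshoe") "tau",
                if (p > 0 && prior$family == "laplace") "lambda_lasso")
  rjags::load.module("glm", quiet = TRUE)
  jm <- rjags::jags.model(textConnection(model_str), data = dat,
                          inits = inits, n.chains = mcmc$chains,
                          n.adapt = ceiling(mcmc$warmup / 2), quiet = TRUE)
  burn <- mcmc$warmup - ceiling(mcmc$warmup / 2)
  if (burn > 0) stats::update(jm, burn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, monitors, n.iter = mcmc$sampling,
                              progress.bar = "none")
  draws_by_chain <- lapply(samp, as.matrix)
  draws <- do.call(rbind, draws_by_chain)
  chain <- rep(seq_len(mcmc$chains), each = mcmc$sampling)
  # rename beta[j] -> design column names
  if (p > 0) {
    bcols <- paste0("beta[", seq_len(p), "]")
    if (p == 1) bcols <- ifelse("beta" %in% colnames(draws), "beta", bcols)
    colnames(draws)[match(bcols, colnames(draws))] <- colnames(X)
  }
  stop_if_not(all(is.finite(draws)), "sampler returned non-finite draws")
  diag <- posterior_diagnostics(draws, chain, mcmc$chains)
  structure(list(draws = draws, chain = chain, diagnostics = diag,
                 divergences = 0L, prior = prior, mcmc = mcmc,
                 beta_names = if (p > 0) colnames(X) else character(0),
                 column_map = dp$column_map, has_site = has_site,
                 n_sites = if (has_site) dat$n_site else 0L,
                 converged = NA, escalations_used = 0L),
            class = "posterior_fit")
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat("<posterior_fit>", x$prior$family,
      if (!is.null(x$prior$df)) paste0("df=", x$prior$df),
      ":", nrow(x$draws), "draws x", ncol(x$draws), "parameters;",
      "max Rhat", round(max(x$diagnostics$rhat, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Split-chain Rhat
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain trends register as apparent non-convergence.
#'
#' @param x numeric matrix, iterations by chains.
#' @return scalar Rhat (NA for zero-variance chains).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Per-parameter split-Rhat + ESS table.
posterior_diagnostics <- function(draws, chain, n_chains) {
  iters <- nrow(draws) / n_chains
  rhat <- vapply(seq_len(ncol(draws)), function(j) {
    split_rhat(matrix(draws[, j], nrow = iters, ncol = n_chains))
  }, numeric(1))
  ess <- vapply(seq_len(ncol(draws)), function(j) {
    as.numeric(coda::effectiveSize(draws[, j]))
  }, numeric(1))
  data.frame(param = colnames(draws), rhat = rhat, ess = ess,
             row.names = NULL)
}

#' Check MCMC convergence
#'
#' Fails when any parameter's split-Rhat exceeds `rhat_max` or the divergent
#' transition fraction exceeds `divergence_max` (always zero with the JAGS
#' backend, which has no divergence diagnostic).
#'
#' @param fit a `posterior_fit`.
#' @param rhat_max split-Rhat threshold (default 1.05).
#' @param divergence_max maximum tolerated divergence fraction (default 0.01).
#' @return list with `pass` (logical) and `offending` (parameter names).
#' @export
check_convergence <- function(fit, rhat_max = 1.05, divergence_max = 0.01) {
  stop_if_not(fit$mcmc$chains >= 2,
              "Rhat requires at least 2 chains")
  rhat <- fit$diagnostics$rhat
  bad <- fit$diagnostics$param[!is.na(rhat) & rhat > rhat_max]
  div_frac <- fit$divergences / nrow(fit$draws)
  list(pass = length(bad) == 0 && div_frac <= divergence_max,
       offending = as.character(bad))
}

#' Fit with convergence escalation
#'
#' Fits via [sample_posterior()]; if [check_convergence()] fails, refits
#' with warmup and sampling multiplied by `escalation_factor`, up to
#' `max_escalations` times (heavy-tailed shrinkage priors — Laplace with 1
#' df especially — mix slowly and may need substantially longer chains). A
#' fit that still fails is returned flagged `converged = FALSE` rather than
#' raising, so a model grid can tolerate and exclude it.
#'
#' @inheritParams sample_posterior
#' @param rhat_max split-Rhat threshold passed to [check_convergence()].
#' @return a `posterior_fit` with `converged` and `escalations_used` set.
#' @export
fit_with_escalation <- function(design, y, site_ids = NULL, prior, mcmc,
                                rhat_max = 1.05) {
  cur <- mcmc
  for (k in 0:mcmc$max_escalations) {
    fit <- sample_posterior(design, y, site_ids, prior, cur)
    fit$escalations_used <- k
    chk <- check_convergence(fit, rhat_max = rhat_max)
    fit$converged <- chk$pass
    if (chk$pass) return(fit)
    cur <- mcmc_config(chains = cur$chains,
                       warmup = ceiling(cur$warmup * cur$escalation_factor),
                       sampling = ceiling(cur$sampling * cur$escalation_factor),
                       seed = cur$seed + 1L,
                       max_escalations = cur$max_escalations,
                       escalation_factor = cur$escalation_factor)
  }
  fit
}

#' Persist posterior draws and diagnostics
#'
#' `write_fit()` writes the draws as a columnar CSV (one column per
#' parameter plus a `chain` column, one row per retained draw) and the
#' diagnostics, prior and sampler settings as `<path>.json`;
#' `read_fit()` reconstructs a `posterior_fit` usable by all
#' draw-summarising functions.
#'
#' @param fit a `posterior_fit`.
#' @param path CSV file path.
#' @return `write_fit()` returns `path` invisibly; `read_fit()` a
#'   `posterior_fit`.
#' @export
write_fit <- function(fit, path) {
  write.csv(cbind(chain = fit$chain, as.data.frame(fit$draws)), path,
            row.names = FALSE)
  jsonlite::write_json(
    list(diagnostics = fit$diagnostics, prior = unclass(fit$prior),
         mcmc = unclass(fit$mcmc), beta_names = fit$beta_names,
         has_site = fit$has_site, n_sites = fit$n_sites,
         converged = fit$converged, escalations_used = fit$escalations_used,
         column_map = fit$column_map),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  tab <- read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  prior <- meta$prior
  class(prior) <- "prior_spec"
  cm <- meta$column_map
  if (!is.data.frame(cm) || nrow(cm) == 0) cm <- NULL
  mcmc <- meta$mcmc
  class(mcmc) <- "mcmc_config"
  structure(list(draws = as.matrix(tab[, -1, drop = FALSE]),
                 chain = tab$chain, diagnostics = meta$diagnostics,
                 divergences = 0L, prior = prior, mcmc = mcmc,
                 beta_names = meta$beta_names %||% character(0),
                 column_map = cm, has_site = meta$has_site,
                 n_sites = meta$n_sites, converged = meta$converged,
                 escalations_used = meta$escalations_used),
            class = "posterior_fit")
}

#' Coefficient draws of a fit
#'
#' The S x p matrix of population-level coefficient draws, columns named
#' after the design columns (p may be 0 for intercept-only fits).
#'
#' @param fit a `posterior_fit`.
#' @return numeric matrix.
#' @export
beta_draws <- function(fit) {
  fit$draws[, fit$beta_names, drop = FALSE]
}
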