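#' Specify a prior family for the population-level coefficients
#'
#' Builds the prior specification used throughout the model grid. Three
#' families are supported:
#'
#' \describe{
#'   \item{`"horseshoe"`}{global-local scale mixture:
#'     \eqn{\beta_j \mid \lambda_j, \tau \sim N(0, (\lambda_j \tau)^2)} with
#'     local scales \eqn{\lambda_j \sim t^+_\nu(0, 1)} (half-Student-t with
#'     `df` degrees of freedom; `df = 1` is the classic half-Cauchy
#'     horseshoe) and global scale \eqn{\tau \sim C^+(0, 1)}.}
#'   \item{`"laplace"`}{double-exponential (Bayesian LASSO) shrinkage,
#'     expressed as an exponential scale mixture of normals:
#'     \eqn{\beta_j \mid \sigma, \tau \sim N(0, \tau^2\sigma^2)},
#'     \eqn{\tau^2 \sim \mathrm{Exp}(\alpha^2/2)}, so that marginally
#'     \eqn{\beta_j} is Laplace with rate \eqn{\alpha/\sigma}. For sampling,
#'     `df` indexes a chi-square mixing family on the global rate that
#'     collapses to this exponential form (see [jags_model_string()]).}
#'   \item{`"vague"`}{independent \eqn{N(0, 100^2)} reference priors; `df`
#'     is ignored.}
#' }
#'
#' All families share a \eqn{N(0, 100^2)} prior on the intercept and a
#' half-Student-t(4, 0, `random_sd_scale`) prior on the between-site
#' random-intercept SD.
#'
#' @param family one of `"horseshoe"`, `"laplace"`, `"vague"`.
#' @param df degrees of freedom of the shrinkage family, one of 1, 3, 5, 7.
#'   Required for the shrinkage families, ignored (and dropped) for `"vague"`.
#' @param alpha Laplace rate hyperparameter \eqn{\alpha} (default 1).
#' @param sigma_lasso fixed residual-scale stand-in \eqn{\sigma} in the
#'   Laplace hierarchy; there is no Gaussian residual scale in a Bernoulli
#'   likelihood, so it is fixed at 1.
#' @param random_sd_scale scale of the half-Student-t(4) prior on the site
#'   random-intercept SD (default 2.5).
#' @param literal_horseshoe logical; if `TRUE` the horseshoe is parameterized
#'   with \eqn{\beta_j \sim N(0, \lambda_j^2)}, \eqn{\lambda_j \sim
#'   C^+(0, \tau)} (scale carried by the local prior rather than the
#'   coefficient prior). The two forms define the same marginal model; the
#'   default `FALSE` uses the standard \eqn{N(0, (\lambda_j\tau)^2)},
#'   \eqn{\lambda_j \sim t^+_\nu(0,1)} parameterization.
#'
#' @return an object of class `"prior_spec"`.
#' @examples
#' prior_spec("horseshoe", df = 7)
#' prior_spec("vague")
#' @export
prior_spec <- function(family = c("horseshoe", "laplace", "vague"), df = NULL,
                       alpha = 1, sigma_lasso = 1, random_sd_scale = 2.5,
                       literal_horseshoe = FALSE) {
  family <- match.arg(family)
  if (family == "vague") {
    df <- NULL
  } else {
    stop_if_not(!is.null(df) && length(df) == 1 && df %in% c(1, 3, 5, 7),
                "`df` must be one of 1, 3, 5, 7 for shrinkage priors")
    df <- as.integer(df)
  }
  stop_if_not(alpha > 0 && sigma_lasso > 0 && random_sd_scale > 0,
              "prior hyperparameters must be positive")
  structure(list(family = family, df = df, alpha = alpha,
                 sigma_lasso = sigma_lasso, random_sd_scale = random_sd_scale,
                 intercept_sd = 100, random_sd_df = 4,
                 literal_horseshoe = isTRUE(literal_horseshoe)),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec> family:", x$family,
      if (!is.null(x$df)) paste0("df: ", x$df), "\n")
  invisible(x)
}

#' Half-Student-t and half-Cauchy densities
#'
#' Density of the positive half of a Student-t (or Cauchy, `df = 1`)
#' distribution with the given scale: twice the full density on `x >= 0`,
#' zero below.
#'
#' @param x evaluation points.
#' @param df degrees of freedom.
#' @param scale scale parameter (> 0).
#' @param log return log-density?
#' @return numeric vector of (log-)densities.
#' @examples
#' dhalf_t(0, df = 1, scale = 1) # = 2/pi
#' @export
dhalf_t <- function(x, df, scale = 1, log = FALSE) {
  stop_if_not(all(scale > 0), "`scale` must be positive")
  ld <- ifelse(x < 0, -Inf, log(2) + dt(x / scale, df = df, log = TRUE) - log(scale))
  if (log) ld else exp(ld)
}

#' @rdname dhalf_t
#' @export
dhalf_cauchy <- function(x, scale = 1, log = FALSE) {
  dhalf_t(x, df = 1, scale = scale, log = log)
}

#' Pointwise Bernoulli log-likelihood of the multilevel logistic model
#'
#' Computes the log-likelihood of binary outcomes under
#' \eqn{p_i = \mathrm{logit}^{-1}(b_0 + u_{site(i)} + x_i^\top\beta)},
#' stably for linear predictors up to about \eqn{\pm 700}.
#'
#' @param beta coefficient vector (length = `ncol(X)`).
#' @param b0 scalar intercept.
#' @param u site random-intercept vector; `u[site_ids[i]]` is added to
#'   subject `i`'s linear predictor. May be length 0 with `site_ids` all 1
#'   and `u = 0` handled via `numeric(0)`? Use a zero vector for no site
#'   effect.
#' @param X numeric design matrix (n x p).
#' @param y binary outcome vector (0/1).
#' @param site_ids integer site index per subject (1-based).
#' @return list with `total` (scalar) and `pointwise` (length-n vector).
#' @examples
#' X <- matrix(0, 1, 1)
#' log_likelihood(0, 0, 0, X, 1, 1)$pointwise # log 0.5
#' @export
log_likelihood <- function(beta, b0, u, X, y, site_ids) {
  stop_if_not(nrow(X) == length(y) && length(y) == length(site_ids),
              "design rows, outcome and site ids must align")
  stop_if_not(ncol(X) == length(beta), "`beta` length must match design columns")
  eta <- as.numeric(b0 + u[site_ids] + X %*% beta)
  pw <- y * log_inv_logit(eta) + (1 - y) * log_inv_logit(-eta)
  list(total = sum(pw), pointwise = pw)
}

#' Horseshoe log prior density
#'
#' Joint log-density of coefficients and shrinkage scales under the
#' horseshoe:
#' \eqn{\sum_j [\log N(\beta_j \mid 0, (\lambda_j\tau)^2)
#'   + \log t^+_{\nu}(\lambda_j \mid 0, 1)] + \log C^+(\tau \mid 0, 1)}.
#' With `df = 1` the local term is the half-Cauchy of the classic horseshoe.
#' The `literal` parameterization instead uses
#' \eqn{N(\beta_j \mid 0, \lambda_j^2)} with
#' \eqn{\lambda_j \sim C^+(0, \tau)} (the same marginal model, the global
#' scale entering through the local prior).
#'
#' @param beta,lambda coefficient and local-scale vectors (equal length).
#' @param tau global scale (> 0).
#' @param df local half-Student-t degrees of freedom (1, 3, 5 or 7).
#' @param literal use the local-scale-carries-tau parameterization?
#' @return scalar log-density.
#' @export
log_prior_horseshoe <- function(beta, lambda, tau, df = 1, literal = FALSE) {
  stop_if_not(df %in% c(1, 3, 5, 7), "`df` must be one of 1, 3, 5, 7")
  stop_if_not(all(lambda > 0) && tau > 0, "scales must be positive")
  stop_if_not(length(beta) == length(lambda), "beta and lambda must align")
  if (literal) {
    sum(dnorm(beta, 0, lambda, log = TRUE)) +
      sum(dhalf_t(lambda, df = df, scale = tau, log = TRUE)) +
      dhalf_cauchy(tau, 1, log = TRUE)
  } else {
    sum(dnorm(beta, 0, lambda * tau, log = TRUE)) +
      sum(dhalf_t(lambda, df = df, scale = 1, log = TRUE)) +
      dhalf_cauchy(tau, 1, log = TRUE)
  }
}

#' Laplace (Bayesian LASSO) log prior density
#'
#' Joint log-density of the compound exponential-normal hierarchy
#' \eqn{\beta_j \mid \sigma, \tau \sim N(0, \tau^2\sigma^2)},
#' \eqn{\tau^2 \sim \mathrm{Exp}(\alpha^2/2)}, evaluated on the `tau` scale
#' by change of variables (`p(tau) = 2 tau p(tau^2)`). Marginally each
#' \eqn{\beta_j} is double-exponential with rate \eqn{\alpha/\sigma};
#' [dlaplace_marginal()] gives that closed form.
#'
#' @param beta coefficient vector.
#' @param tau global scale (> 0).
#' @param alpha exponential rate hyperparameter (> 0).
#' @param sigma fixed scale multiplier (> 0).
#' @return scalar log-density.
#' @export
log_prior_laplace <- function(beta, tau, alpha = 1, sigma = 1) {
  stop_if_not(tau > 0 && alpha > 0 && sigma > 0,
              "`tau`, `alpha`, `sigma` must be positive")
  sum(dnorm(beta, 0, tau * sigma, log = TRUE)) +
    dexp(tau^2, rate = alpha^2 / 2, log = TRUE) + log(2 * tau)
}

#' Marginal Laplace density of a coefficient
#'
#' Closed-form double-exponential marginal implied by the exponential-normal
#' mixture: rate \eqn{\alpha/\sigma}, i.e. density
#' \eqn{\frac{\alpha}{2\sigma} e^{-\alpha |\beta| / \sigma}}.
#'
#' @inheritParams log_prior_laplace
#' @param log return log-density?
#' @return numeric vector.
#' @export
dlaplace_marginal <- function(beta, alpha = 1, sigma = 1, log = FALSE) {
  ld <- log(alpha) - log(2 * sigma) - alpha * abs(beta) / sigma
  if (log) ld else exp(ld)
}

#' Vague-prior log density
#'
#' Independent Normal(0, 100) log prior on each coefficient.
#'
#' @param beta coefficient vector.
#' @param sd prior standard deviation (default 100).
#' @return scalar log-density.
#' @export
log_prior_vague <- function(beta, sd = 100) {
  sum(dnorm(beta, 0, sd, log = TRUE))
}

#' Joint log posterior density (up to the normalizing constant)
#'
#' Assembles the multilevel logistic likelihood, the family prior on the
#' coefficients, the Normal(0, 100) intercept prior, the
#' Normal(0, sigma_site) site-intercept priors and the half-Student-t(4)
#' prior on sigma_site.
#'
#' @param params named list with elements `beta`, `b0`, `u`, `sigma_site`
#'   and (family-dependent) `lambda`, `tau`.
#' @param X,y,site_ids data, as in [log_likelihood()].
#' @param prior a [prior_spec()].
#' @return scalar log posterior density.
#' @export
log_posterior <- function(params, X, y, site_ids, prior) {
  stop_if_not(inherits(prior, "prior_spec"), "`prior` must be a prior_spec")
  ll <- log_likelihood(params$beta, params$b0, params$u, X, y, site_ids)$total
  lp <- switch(prior$family,
    horseshoe = log_prior_horseshoe(params$beta, params$lambda, params$tau,
                                    df = prior$df,
                                    literal = prior$literal_horseshoe),
    laplace   = log_prior_laplace(params$beta, params$tau,
                                  alpha = prior$alpha,
                                  sigma = prior$sigma_lasso),
    vague     = log_prior_vague(params$beta, sd = prior$intercept_sd)
  )
  ll + lp +
    dnorm(params$b0, 0, prior$intercept_sd, log = TRUE) +
    sum(dnorm(params$u, 0, params$sigma_site, log = TRUE)) +
    dhalf_t(params$sigma_site, df = prior$random_sd_df,
            scale = prior$random_sd_scale, log = TRUE)
}
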