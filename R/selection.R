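# Site random-intercept draws as an S x n_site matrix (zero columns when
# the fit has no site term).
u_draws <- function(fit) {
  nm <- colnames(fit$draws)
  cols <- grep("^u(\\[|$)", nm, value = TRUE)
  fit$draws[, cols, drop = FALSE]
}

#' Pointwise log-likelihood matrix
#'
#' Entry (s, i) is the Bernoulli log-likelihood of subject i at posterior
#' draw s — the input to WAIC and PSIS-LOO.
#'
#' @param fit a `posterior_fit`.
#' @param design design matrix (object or plain matrix) aligned with `fit`.
#' @param y binary outcomes.
#' @param site_ids site indices (or `NULL` for single-level fits).
#' @return S x n numeric matrix.
#' @export
pointwise_loglik_matrix <- function(fit, design, y, site_ids = NULL) {
  X <- design_parts(design)$X
  stop_if_not(nrow(X) == length(y), "design rows must match outcome length")
  B <- beta_draws(fit)
  stop_if_not(ncol(B) == ncol(X),
              "fit coefficients do not match design columns")
  eta <- matrix(fit$draws[, "b0"], nrow(fit$draws), length(y))
  if (ncol(X) > 0) eta <- eta + B %*% t(X)
  if (!is.null(site_ids)) {
    U <- u_draws(fit)
    stop_if_not(ncol(U) >= max(site_ids), "unseen site index for this fit")
    eta <- eta + U[, site_ids, drop = FALSE]
  }
  dimnames(eta) <- NULL
  ym <- matrix(y, nrow(eta), length(y), byrow = TRUE)
  ym * log_inv_logit(eta) + (1 - ym) * log_inv_logit(-eta)
}

#' Widely applicable information criterion (WAIC)
#'
#' \eqn{\widehat{\mathrm{elpd}}_{waic} = \sum_i [\log \frac{1}{S}\sum_s
#' e^{\ell_{si}} - \mathrm{Var}_s(\ell_{si})]}, with the log-mean-exp
#' computed stably; `waic = -2 elpd`.
#'
#' @param ll S x n pointwise log-likelihood matrix.
#' @return list with `elpd_waic`, `p_waic`, `waic`, their standard errors,
#'   and the pointwise `elpd_i`.
#' @export
compute_waic <- function(ll) {
  stop_if_not(nrow(ll) >= 2, "WAIC needs at least 2 draws")
  stop_if_not(all(is.finite(ll)), "non-finite log-likelihood entries")
  S <- nrow(ll)
  lppd_i <- col_logsumexp(ll) - log(S)
  p_i <- apply(ll, 2, var)
  elpd_i <- lppd_i - p_i
  n <- ncol(ll)
  list(elpd_waic = sum(elpd_i), p_waic = sum(p_i),
       waic = -2 * sum(elpd_i),
       se_elpd = sqrt(n * var(elpd_i)),
       se_waic = 2 * sqrt(n * var(elpd_i)),
       pointwise = elpd_i)
}

# Zhang & Stephens (2009) posterior-mean fit of a generalized Pareto
# distribution to exceedances x > 0, with the mild prior regularization of
# the shape commonly used for importance-weight diagnostics.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bs * xstar)
  k_th <- vapply(theta, function(th) mean(log1p(-th * x)), numeric(1))
  l_th <- n * (log(-theta / k_th) - k_th - 1)
  w <- 1 / vapply(jj, function(j) sum(exp(l_th - l_th[j])), numeric(1))
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  k <- (n * k + 10 * 0.5) / (n + 10)
  list(k = k, sigma = sigma)
}

# Generalized Pareto quantile function.
qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p) else sigma / k * ((1 - p)^(-k) - 1)
}

# Pareto-smooth one vector of log importance ratios: fit a GPD to the top
# `tail_frac` of ratios and replace them by expected order statistics,
# truncated at the largest raw ratio. Returns shifted log weights + k-hat.
psis_smooth <- function(lr, tail_frac = 0.2) {
  S <- length(lr)
  lr <- lr - max(lr)
  M <- ceiling(tail_frac * S)
  ord <- order(lr)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lr[ord[S - M]]
  exc <- exp(lr[tail_ids]) - exp(cutoff)
  if (M < 5 || max(exc) <= 0 || length(unique(exc)) < 2) {
    return(list(lw = lr, k = 0))
  }
  fit <- gpd_fit(exc[exc > 0])
  qq <- qgpd((seq_len(M) - 0.5) / M, fit$k, fit$sigma)
  smoothed <- pmin(log(qq + exp(cutoff)), 0) # cap at the max raw ratio
  lr[tail_ids] <- smoothed
  list(lw = lr, k = fit$k)
}

#' Pareto-smoothed importance-sampling leave-one-out (PSIS-LOO)
#'
#' Approximates exact leave-one-out cross-validation from a single
#' posterior sample: per subject the importance ratios
#' \eqn{r_{si} = \exp(-\ell_{si})} are tail-stabilized by fitting a
#' generalized Pareto distribution to the top 20% and replacing them by its
#' expected order statistics (truncated at the largest raw ratio), then
#' \eqn{\mathrm{elpd}_{loo,i} = \log \frac{\sum_s w_{si}
#' e^{\ell_{si}}}{\sum_s w_{si}}}. The fitted Pareto shape \eqn{\hat k} is
#' reported per subject (values above 0.7 flag unreliable weights).
#' Degenerate (all-equal) ratios fall back to plain importance sampling
#' with \eqn{\hat k = 0}.
#'
#' @param ll S x n pointwise log-likelihood matrix (S at least 100 for
#'   stable tail fits).
#' @param tail_frac fraction of draws treated as the weight tail.
#' @return list with `elpd_loo`, `p_loo`, `looic`, standard errors,
#'   pointwise `elpd_i`, and `pareto_k`.
#' @export
compute_psis_loo <- function(ll, tail_frac = 0.2) {
  stop_if_not(all(is.finite(ll)), "non-finite log-likelihood entries")
  S <- nrow(ll)
  n <- ncol(ll)
  lppd_i <- col_logsumexp(ll) - log(S)
  res <- lapply(seq_len(n), function(i) psis_smooth(-ll[, i], tail_frac))
  elpd_i <- vapply(seq_len(n), function(i) {
    lw <- res[[i]]$lw
    logsumexp(lw + ll[, i]) - logsumexp(lw)
  }, numeric(1))
  k <- vapply(res, `[[`, numeric(1), "k")
  list(elpd_loo = sum(elpd_i), p_loo = sum(lppd_i - elpd_i),
       looic = -2 * sum(elpd_i),
       se_elpd = sqrt(n * var(elpd_i)),
       se_looic = 2 * sqrt(n * var(elpd_i)),
       pointwise = elpd_i, pareto_k = k)
}

#' Score a fitted model by WAIC and PSIS-LOO
#'
#' @param fit a `posterior_fit`.
#' @param design,y,site_ids training data the fit was drawn on.
#' @param id optional model label.
#' @return a one-row data frame of class `"model_score"` with elpd/p/IC
#'   values for both criteria, their SEs, the maximum Pareto k, and the
#'   convergence flag.
#' @export
score_model <- function(fit, design, y, site_ids = NULL, id = NULL) {
  ll <- pointwise_loglik_matrix(fit, design, y, site_ids)
  w <- compute_waic(ll)
  l <- compute_psis_loo(ll)
  out <- data.frame(
    id = id %||% paste0(fit$prior$family, fit$prior$df %||% ""),
    family = fit$prior$family, df = fit$prior$df %||% NA_integer_,
    elpd_waic = w$elpd_waic, p_waic = w$p_waic, waic = w$waic,
    se_waic = w$se_waic,
    elpd_loo = l$elpd_loo, p_loo = l$p_loo, looic = l$looic,
    se_looic = l$se_looic, max_pareto_k = max(l$pareto_k),
    converged = isTRUE(fit$converged),
    escalations = fit$escalations_used, stringsAsFactors = FALSE)
  class(out) <- c("model_score", "data.frame")
  out
}

#' Rank models by information criteria
#'
#' Excludes non-converged models, then orders ascending by LOOIC with WAIC
#' as tie-breaker (lower = better out-of-sample fit).
#'
#' @param scores a list of `model_score` rows or a stacked data frame.
#' @return the stacked comparison table, ranked; non-converged models are
#'   appended at the bottom with `rank = NA`.
#' @export
rank_models <- function(scores) {
  if (is.list(scores) && !is.data.frame(scores)) {
    scores <- do.call(rbind, scores)
  }
  stop_if_not(any(scores$converged), "no converged models to rank")
  ok <- scores[scores$converged, , drop = FALSE]
  bad <- scores[!scores$converged, , drop = FALSE]
  ok <- ok[order(ok$looic, ok$waic), , drop = FALSE]
  ok$rank <- seq_len(nrow(ok))
  if (nrow(bad)) bad$rank <- NA_integer_
  out <- rbind(ok, bad)
  rownames(out) <- NULL
  out
}

#' Posterior harm-probability table
#'
#' Per design column: posterior median regularized odds ratio
#' \eqn{e^{\mathrm{median}(\beta)}}, 95% credible interval from the 2.5%
#' and 97.5% coefficient quantiles, and the posterior probability of harm
#' \eqn{P(\mathrm{OR} > 1)} = fraction of draws with \eqn{\beta > 0}.
#' Probabilities of at least 0.8 (or at most 0.2, protective) are flagged
#' `important`.
#'
#' @param fit a `posterior_fit`.
#' @return a data frame of class `"harm_table"` with columns `variable`,
#'   `predictor`, `median_ror`, `cri_low`, `cri_high`, `p_harm`,
#'   `important`.
#' @export
harm_probabilities <- function(fit) {
  B <- beta_draws(fit)
  cm <- fit$column_map
  pred <- if (!is.null(cm)) cm$predictor[match(colnames(B), cm$column)]
          else colnames(B)
  qs <- apply(B, 2, quantile, probs = c(0.025, 0.5, 0.975))
  p <- colMeans(B > 0)
  out <- data.frame(variable = colnames(B), predictor = pred,
                    median_ror = exp(qs[2, ]), cri_low = exp(qs[1, ]),
                    cri_high = exp(qs[3, ]), p_harm = p,
                    important = p >= 0.8 | p <= 0.2,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("harm_table", "data.frame")
  out
}

#' Hard-shrinkage variable selection
#'
#' Post-fit selection by thresholding the posterior harm probability:
#' retain variables with \eqn{P(\mathrm{OR} > 1) \ge t} (harmful) or
#' \eqn{\le 1 - t} (protective). Categorical predictors are kept as whole
#' blocks when any of their dummies passes.
#'
#' @param harm a [harm_probabilities()] table.
#' @param threshold selection threshold in (0.5, 1) (default 0.65).
#' @return list with `predictors` (selected predictor blocks) and
#'   `columns` (their design columns); empty with a warning when nothing
#'   passes (intercept-only model).
#' @export
hard_shrinkage <- function(harm, threshold = 0.65) {
  stop_if_not(threshold > 0.5 && threshold < 1,
              "`threshold` must lie in (0.5, 1)")
  pass <- harm$p_harm >= threshold | harm$p_harm <= 1 - threshold
  preds <- unique(harm$predictor[pass])
  if (length(preds) == 0) {
    warning("no variable passed the hard-shrinkage threshold; ",
            "intercept-only model")
  }
  list(predictors = preds,
       columns = harm$variable[harm$predictor %in% preds],
       threshold = threshold)
}

#' Threshold sweep for the final parsimonious model
#'
#' For each selection threshold: apply [hard_shrinkage()] to the full
#' model's harm table, refit the reduced predictor set on the training data
#' with `refit_prior`, and measure test-set AUROC. Identical selections are
#' refit once. The chosen model is the smallest selected set whose AUROC is
#' within `tol` of the full model's test AUROC.
#'
#' @param fit converged full-model `posterior_fit`.
#' @param design_train,y_train,site_train training data of the full fit.
#' @param design_test,y_test,site_test held-out evaluation data (already
#'   encoded with the training scaling).
#' @param thresholds probability thresholds, swept in the given order
#'   (default 0.7, 0.65, 0.6).
#' @param refit_prior prior for the reduced refits (convention: same
#'   shrinkage family/df as the winning full model).
#' @param mcmc an [mcmc_config()] for the refits.
#' @param tol AUROC tolerance defining "retains the discriminative ability"
#'   (default 0.01).
#' @return list with `table` (one row per threshold: threshold,
#'   n_selected, auroc), `full_auroc`, `chosen` (threshold, selection and
#'   refit `posterior_fit` of the chosen model; `NULL` fit if the chosen
#'   selection is empty).
#' @export
threshold_sweep <- function(fit, design_train, y_train, site_train = NULL,
                            design_test, y_test, site_test = NULL,
                            thresholds = c(0.7, 0.65, 0.6), refit_prior,
                            mcmc, tol = 0.01) {
  harm <- harm_probabilities(fit)
  pp_full <- posterior_predict(fit, design_test, site_test)
  full_auc <- auroc(pp_full$prob, y_test)$auc
  cache <- list()
  rows <- list()
  for (t in thresholds) {
    sel <- hard_shrinkage(harm, t)
    key <- paste0("sel:", paste(sort(sel$predictors), collapse = "|"))
    if (is.null(cache[[key]])) {
      if (length(sel$predictors) == 0) {
        cache[[key]] <- list(fit = NULL, auc = NA_real_, sel = sel)
      } else {
        red_tr <- subset_design(design_train, sel$predictors)
        red_te <- subset_design(design_test, sel$predictors)
        rf <- fit_with_escalation(red_tr, y_train, site_train, refit_prior,
                                  mcmc)
        pp <- posterior_predict(rf, red_te, site_test)
        cache[[key]] <- list(fit = rf, auc = auroc(pp$prob, y_test)$auc,
                             sel = sel)
      }
    }
    rows[[as.character(t)]] <-
      data.frame(threshold = t, n_selected = length(sel$predictors),
                 auroc = cache[[key]]$auc)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- which(!is.na(tab$auroc) & tab$auroc >= full_auc - tol)
  pick <- if (length(ok)) ok[which.min(tab$n_selected[ok])]
          else which.max(tab$auroc)
  key <- paste0("sel:",
                paste(sort(hard_shrinkage(harm, tab$threshold[pick])$predictors),
                      collapse = "|"))
  list(table = tab, full_auroc = full_auc,
       chosen = list(threshold = tab$threshold[pick],
                     selection = cache[[key]]$sel,
                     fit = cache[[key]]$fit, auroc = cache[[key]]$auc))
}
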