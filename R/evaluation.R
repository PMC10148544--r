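#' Posterior predictive probabilities with credible intervals
#'
#' For each new subject, the event probability per posterior draw is
#' \eqn{\mathrm{logit}^{-1}(b_0 + u + x^\top\beta)}; the reported
#' probability is the posterior mean and the 95% CrI the 2.5%/97.5%
#' quantiles over draws. In `"known"` mode the fitted site effect of
#' `site_ids_new` is used (sites must have been seen in training); in
#' `"marginal"` mode a fresh site effect is drawn from
#' \eqn{N(0, \sigma_{site})} per draw and subject, for prediction at new
#' sites.
#'
#' @param fit a `posterior_fit`.
#' @param design_new design for the new subjects, encoded with the
#'   training scaling.
#' @param site_ids_new site indices (ignored for single-level fits;
#'   required in `"known"` mode for multilevel fits).
#' @param site_mode `"known"` or `"marginal"`.
#' @param seed RNG seed for the marginal-mode site draws.
#' @return data frame with `prob`, `lower`, `upper` per subject.
#' @export
posterior_predict <- function(fit, design_new, site_ids_new = NULL,
                              site_mode = c("known", "marginal"),
                              seed = 1L) {
  site_mode <- match.arg(site_mode)
  X <- design_parts(design_new)$X
  B <- beta_draws(fit)
  stop_if_not(ncol(B) == ncol(X),
              "fit coefficients do not match design columns")
  S <- nrow(fit$draws)
  eta <- matrix(fit$draws[, "b0"], S, nrow(X))
  if (ncol(X) > 0) eta <- eta + B %*% t(X)
  if (fit$has_site) {
    if (site_mode == "known") {
      stop_if_not(!is.null(site_ids_new), "site ids required in known mode")
      if (max(site_ids_new) > fit$n_sites) {
        stop("unseen site in known mode; use site_mode = \"marginal\"",
             call. = FALSE)
      }
      eta <- eta + u_draws(fit)[, site_ids_new, drop = FALSE]
    } else {
      sig <- fit$draws[, "sigma_site"]
      eta <- eta + with_seed(seed,
        matrix(rnorm(S * nrow(X), 0, sig), S, nrow(X)))
    }
  }
  P <- plogis(eta)
  qs <- apply(P, 2, quantile, probs = c(0.025, 0.975))
  data.frame(prob = colMeans(P), lower = qs[1, ], upper = qs[2, ])
}

#' Area under the ROC curve with DeLong confidence interval
#'
#' Concordance-based AUROC: the fraction of (event, non-event) pairs in
#' which the event carries the higher predicted probability, ties counted
#' half. The 95% CI uses DeLong's asymptotic variance of the underlying
#' two-sample rank statistic (placement values).
#'
#' @param p predicted probabilities (any monotone score works).
#' @param y binary outcomes; both classes must be present.
#' @return list with `auc`, `se`, and `ci` (95%, clipped to `[0, 1]`).
#' @examples
#' auroc(c(0.9, 0.3, 0.7, 0.1), c(1, 1, 0, 0))$auc # 0.75
#' @export
auroc <- function(p, y) {
  stop_if_not(length(p) == length(y), "lengths differ")
  stop_if_not(all(y %in% c(0, 1)) && length(unique(y)) == 2,
              "`y` must contain both classes")
  p1 <- p[y == 1]
  p0 <- p[y == 0]
  n1 <- length(p1)
  n0 <- length(p0)
  # placement of each event among non-events, and vice versa
  v10 <- vapply(p1, function(x) (sum(x > p0) + 0.5 * sum(x == p0)) / n0,
                numeric(1))
  v01 <- vapply(p0, function(x) (sum(p1 > x) + 0.5 * sum(p1 == x)) / n1,
                numeric(1))
  auc <- mean(v10)
  se <- sqrt(var(v10) / n1 + var(v01) / n0)
  list(auc = auc, se = se,
       ci = pmin(pmax(auc + c(-1, 1) * qnorm(0.975) * se, 0), 1))
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes; `brier_null()` is the score of the constant prediction at the
#' observed event rate q, which equals q(1 - q).
#'
#' @param p predicted probabilities in `[0, 1]`.
#' @param y binary outcomes.
#' @return scalar score.
#' @examples
#' brier(rep(0.5, 4), c(1, 0, 0, 0)) # 0.25
#' @export
brier <- function(p, y) {
  stop_if_not(all(p >= 0 & p <= 1), "`p` must lie in [0, 1]")
  mean((p - y)^2)
}

#' @rdname brier
#' @export
brier_null <- function(y) {
  q <- mean(y)
  q * (1 - q)
}

#' Logistic recalibration intercept and slope
#'
#' Fits \eqn{\mathrm{logit}\,P(y = 1) = a + b\,\mathrm{logit}(p)} jointly;
#' perfectly calibrated predictions give a = 0, b = 1, while b < 1 means
#' the predictions are too extreme. Under separation (or non-convergence)
#' the model is refit with a weak ridge penalty and flagged.
#'
#' @param p predicted probabilities, strictly inside (0, 1).
#' @param y binary outcomes.
#' @param fixed_slope if `TRUE`, also report the calibration-in-the-large
#'   intercept with the slope fixed at 1 (offset model).
#' @return list with `intercept`, `slope`, `ridged` flag, and optionally
#'   `intercept_fixed_slope`.
#' @export
calibration_metrics <- function(p, y, fixed_slope = FALSE) {
  stop_if_not(all(p > 0 & p < 1), "`p` must lie strictly inside (0, 1)")
  lp <- qlogis(p)
  stop_if_not(var(lp) > 0, "constant predictions cannot be recalibrated")
  ridged <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ lp, family = binomial()),
    warning = function(w) {
      ridged <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- coef(fit)
  if (ridged || any(!is.finite(cf)) || any(abs(cf) > 20)) {
    ridged <- TRUE
    cf <- ridge_logistic(cbind(1, lp), y, lambda = 1e-4)
  }
  out <- list(intercept = unname(cf[1]), slope = unname(cf[2]),
              ridged = ridged)
  if (fixed_slope) {
    f0 <- glm(y ~ 1 + offset(lp), family = binomial())
    out$intercept_fixed_slope <- unname(coef(f0)[1])
  }
  out
}

# Newton-Raphson logistic regression with an L2 penalty on all
# coefficients; fallback for separated recalibration fits.
ridge_logistic <- function(X, y, lambda = 1e-4, maxit = 100) {
  b <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- as.numeric(X %*% b)
    mu <- plogis(eta)
    W <- mu * (1 - mu)
    g <- crossprod(X, y - mu) - lambda * b
    H <- crossprod(X * W, X) + diag(lambda, ncol(X))
    step <- solve(H, g)
    b <- b + step
    if (max(abs(step)) < 1e-10) break
  }
  as.numeric(b)
}

#' Decile calibration table
#'
#' Bins subjects by deciles of the predicted probability (tied predictions
#' kept in one bin) and reports mean prediction, observed event proportion
#' and count per bin — the table behind the usual calibration plot.
#'
#' @param p predicted probabilities.
#' @param y binary outcomes (n of at least 10).
#' @return data frame with `bin`, `mean_predicted`, `observed`, `n`;
#'   counts sum to `length(y)`.
#' @export
calibration_deciles <- function(p, y) {
  stop_if_not(length(p) >= 10, "need at least 10 subjects")
  breaks <- unique(quantile(p, probs = seq(0, 1, 0.1)))
  if (length(breaks) < 2) {
    return(data.frame(bin = 1L, mean_predicted = mean(p),
                      observed = mean(y), n = length(y)))
  }
  g <- cut(p, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(
    bin = sort(unique(g)),
    mean_predicted = as.numeric(tapply(p, g, mean)),
    observed = as.numeric(tapply(y, g, mean)),
    n = as.integer(table(g)))
  rownames(out) <- NULL
  out
}

#' Full out-of-sample evaluation report
#'
#' The evaluation triad for a clinical prediction model: discrimination
#' (AUROC with 95% CI), accuracy (Brier score, with the null-model score
#' q(1-q) for reference) and calibration (logistic recalibration intercept
#' and slope, plus the decile table).
#'
#' @param p predicted probabilities.
#' @param y binary outcomes.
#' @return an object of class `"eval_report"`.
#' @export
evaluate_predictions <- function(p, y) {
  a <- auroc(p, y)
  cal <- calibration_metrics(p, y)
  structure(list(auroc = a$auc, auroc_ci = a$ci, brier = brier(p, y),
                 brier_null = brier_null(y),
                 calibration_intercept = cal$intercept,
                 calibration_slope = cal$slope, ridged = cal$ridged,
                 deciles = calibration_deciles(p, y)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n",
      sprintf("  AUROC: %.2f (95%% CI %.2f - %.2f)\n", x$auroc,
              x$auroc_ci[1], x$auroc_ci[2]),
      sprintf("  Brier: %.3f (null %.3f)\n", x$brier, x$brier_null),
      sprintf("  Calibration intercept %.2f, slope %.2f\n",
              x$calibration_intercept, x$calibration_slope))
  invisible(x)
}
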