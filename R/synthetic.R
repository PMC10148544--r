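#' Configure a synthetic multi-site cohort
#'
#' Defines the generating process for a synthetic smoking-cessation-style
#' cohort: a multi-site sample with a rare binary adverse-event outcome,
#' ordinal psychosocial item batteries generated through a Gaussian copula
#' with equicorrelated latent scores within each scale block, continuous
#' clinical measures, categorical demographics, a three-arm treatment, a
#' binary metabolizer group, and a site random intercept on the logit scale.
#' The outcome is Bernoulli with
#' \eqn{\mathrm{logit}(p_i) = b_0 + u_{site(i)} + \sum_j \theta_j z_{ij}},
#' where \eqn{z_{ij}} is the standardized value (numeric predictors) or a
#' category indicator (categorical predictors) and \eqn{b_0} is tuned by
#' Monte-Carlo root-finding so the marginal event probability matches
#' `target_prevalence` (see [tune_intercept()]).
#'
#' @param n_subjects number of subjects.
#' @param n_sites number of study sites.
#' @param site_probs site membership probabilities (sums to 1).
#' @param site_sd SD of the Normal(0, site_sd^2) site random intercepts,
#'   logit scale.
#' @param target_prevalence marginal event probability in (0, 0.5].
#' @param true_effects named numeric vector of log odds ratios. Names are
#'   predictor column names (effect per 1 SD of the generated column) or
#'   `"column=level"` for a categorical level indicator.
#' @param item_blocks list of ordinal item blocks; each block is a list with
#'   `name`, `levels` (integer vector of admissible scores), `corr` (latent
#'   equicorrelation in `[0, 1)`), and `items` — a named list of per-item
#'   category probability vectors over `levels`.
#' @param continuous_spec named list of continuous column generators; each
#'   element a list with `dist` (`"normal"` or `"lognormal"`), its
#'   parameters, optional `round` digits and `min`/`max` truncation bounds.
#' @param demographics_spec named list of categorical columns; each element
#'   a list with `levels` (first level = reference) and `probs`.
#' @param seed integer seed; identical configs (including seed) generate
#'   identical cohorts.
#'
#' @return an object of class `"synthetic_config"`.
#' @seealso [default_pnat_config()] for the packaged default emulating a
#'   1203-subject four-site trial at 10% prevalence.
#' @export
synthetic_config <- function(n_subjects, n_sites, site_probs = NULL,
                             site_sd = 0.3, target_prevalence = 0.1,
                             true_effects = numeric(0), item_blocks = list(),
                             continuous_spec = list(),
                             demographics_spec = list(), seed = 1L) {
  site_probs <- site_probs %||% rep(1 / n_sites, n_sites)
  stop_if_not(n_subjects >= 1 && n_sites >= 1, "counts must be positive")
  stop_if_not(abs(sum(site_probs) - 1) < 1e-9,
              "`site_probs` must sum to 1")
  stop_if_not(length(site_probs) == n_sites,
              "`site_probs` length must equal `n_sites`")
  stop_if_not(site_sd >= 0, "`site_sd` must be non-negative")
  stop_if_not(target_prevalence > 0 && target_prevalence <= 0.5,
              "`target_prevalence` must lie in (0, 0.5]")
  for (b in item_blocks) {
    stop_if_not(b$corr >= 0 && b$corr < 1,
                "item block latent correlation must lie in [0, 1)")
    for (pr in b$items) {
      stop_if_not(length(pr) == length(b$levels) && abs(sum(pr) - 1) < 1e-6,
                  "item category probabilities must match levels and sum to 1")
    }
  }
  cfg <- structure(list(n_subjects = as.integer(n_subjects),
                        n_sites = as.integer(n_sites),
                        site_probs = site_probs, site_sd = site_sd,
                        target_prevalence = target_prevalence,
                        true_effects = true_effects,
                        item_blocks = item_blocks,
                        continuous_spec = continuous_spec,
                        demographics_spec = demographics_spec,
                        seed = as.integer(seed)),
                   class = "synthetic_config")
  known <- generated_predictor_names(cfg)
  bad <- setdiff(effect_base_name(names(true_effects)), known)
  stop_if_not(length(bad) == 0,
              paste("true_effects name unknown predictors:",
                    paste(bad, collapse = ", ")))
  cfg
}

# Column name part of an effect key ("col" or "col=level").
effect_base_name <- function(keys) sub("=.*$", "", keys)

# All predictor column names a config generates.
generated_predictor_names <- function(config) {
  c(unlist(lapply(config$item_blocks, function(b) names(b$items))),
    names(config$continuous_spec), names(config$demographics_spec))
}

#' Default synthetic cohort configuration
#'
#' The packaged study conditions: 1203 subjects, four equally likely sites
#' with site-intercept SD 0.3 (logit scale), 10% marginal event prevalence,
#' ordinal item batteries (13 withdrawal-symptom items scored 0-4, 20 affect
#' items scored 1-5, a heaviness-of-smoking index scored 0-6) with latent
#' within-scale correlation 0.4, two continuous smoking-urge factor scores,
#' and categorical demographics with realistic frequencies. Sparse true
#' effects: eight nonzero log odds ratios on sleep/attention/affect items
#' and the second urges factor (the largest being 0.148 per SD for
#' nightmares and -0.139 for feeling proud); all treatment effects are zero.
#'
#' @param seed integer seed stored in the config.
#' @return a [synthetic_config()] object.
#' @export
default_pnat_config <- function(seed = 1L) {
  lv04 <- 0:4
  p_low   <- c(0.55, 0.25, 0.12, 0.05, 0.03) # median 0 [0, 1]
  p_zero  <- c(0.78, 0.12, 0.06, 0.03, 0.01) # median 0 [0, 0]
  p_rare  <- c(0.80, 0.12, 0.05, 0.02, 0.01)
  p_high  <- c(0.05, 0.10, 0.25, 0.30, 0.30) # median 3 [2, 4]
  p_cough <- c(0.35, 0.30, 0.20, 0.10, 0.05)
  mnws <- list(
    angry_irritable = p_low, anxious_nervous = p_low,
    depressed_mood = p_zero, desire_to_smoke = p_high,
    difficulty_concentrating = p_low, increased_appetite = p_low,
    insomnia_sleep_problems = p_low, restless = p_low, impatient = p_low,
    constipation = p_rare, cough = p_cough, dreaming_nightmares = p_zero,
    sore_throat = p_rare)
  pos_mid  <- c(0.10, 0.22, 0.33, 0.25, 0.10) # median 3 [2, 4]
  pos_high <- c(0.04, 0.12, 0.30, 0.38, 0.16) # median 4 [3, 4]
  neg_low  <- c(0.70, 0.18, 0.07, 0.03, 0.02) # median 1 [1, 1]
  neg_mid  <- c(0.55, 0.25, 0.12, 0.05, 0.03) # median 1 [1, 2]
  panas <- list(
    interested = pos_high, excited = pos_mid, strong = pos_mid,
    enthusiastic = pos_mid, proud = pos_mid, alert = pos_high,
    inspired = pos_mid, determined = pos_high, attentive = pos_high,
    active = pos_mid,
    distressed = neg_mid, upset = neg_mid, guilty = neg_low,
    scared = neg_low, hostile = neg_low, irritable_panas = neg_mid,
    ashamed = neg_low, nervous = neg_mid, jittery = neg_low,
    afraid = neg_low)
  item_blocks <- list(
    list(name = "mnws", levels = lv04, corr = 0.4, items = mnws),
    list(name = "panas", levels = 1:5, corr = 0.4, items = panas),
    list(name = "ftnd", levels = 0:6, corr = 0,
         items = list(ftnd_hsi = c(0.02, 0.05, 0.10, 0.25, 0.35, 0.15, 0.08))))
  continuous_spec <- list(
    age = list(dist = "normal", mean = 46, sd = 11, round = 0,
               min = 18, max = 65),
    co_level = list(dist = "normal", mean = 23, sd = 10, round = 0, min = 1),
    weekly_drinks = list(dist = "lognormal", meanlog = 0.55, sdlog = 1,
                         round = 0, min = 0),
    qsub_f1 = list(dist = "lognormal", meanlog = log(17), sdlog = 0.55,
                   round = 0, min = 0),
    qsub_f2 = list(dist = "lognormal", meanlog = log(6), sdlog = 0.6,
                   round = 0, min = 0))
  demographics_spec <- list(
    race = list(levels = c("caucasian", "african_american", "other"),
                probs = c(0.553, 0.376, 0.071)),
    hispanic = list(levels = c("no", "yes"), probs = c(0.948, 0.052)),
    female = list(levels = c("no", "yes"), probs = c(0.561, 0.439)),
    marital = list(levels = c("never_married", "divorced_widowed_separated",
                              "married"),
                   probs = c(0.337, 0.258, 0.405)),
    education_gt_hs = list(levels = c("no", "yes"), probs = c(0.308, 0.692)),
    employment = list(levels = c("full_time", "part_time",
                                 "retired_unemployed"),
                      probs = c(0.458, 0.166, 0.376)),
    obesity = list(levels = c("normal", "underweight", "overweight", "obese"),
                   probs = c(0.267, 0.010, 0.346, 0.377)),
    menthol = list(levels = c("no", "yes"), probs = c(0.527, 0.473)),
    treatment = list(levels = c("placebo", "varenicline", "patch"),
                     probs = c(0.324, 0.338, 0.338)),
    nmr = list(levels = c("slow", "normal"), probs = c(0.533, 0.467)),
    baseline_nae = list(levels = c("no", "yes"), probs = c(0.9784, 0.0216)))
  true_effects <- c(
    difficulty_concentrating = log(1.05),
    insomnia_sleep_problems  = log(1.09),
    restless                 = log(1.04),
    impatient                = log(1.03),
    dreaming_nightmares      = log(1.16),
    proud                    = log(0.87),
    irritable_panas          = log(1.05),
    qsub_f2                  = log(1.01))
  synthetic_config(n_subjects = 1203L, n_sites = 4L, site_sd = 0.3,
                   target_prevalence = 0.10, true_effects = true_effects,
                   item_blocks = item_blocks,
                   continuous_spec = continuous_spec,
                   demographics_spec = demographics_spec, seed = seed)
}

# Draw the covariate part of a cohort (no outcome) of size n.
draw_covariates <- function(config, n) {
  out <- list()
  for (b in config$item_blocks) {
    k <- length(b$items)
    common <- rnorm(n)
    lat <- sqrt(b$corr) * matrix(common, n, k) +
      sqrt(1 - b$corr) * matrix(rnorm(n * k), n, k)
    for (j in seq_len(k)) {
      cuts <- qnorm(cumsum(b$items[[j]])[-length(b$levels)])
      out[[names(b$items)[j]]] <-
        b$levels[1 + findInterval(lat[, j], cuts)]
    }
  }
  for (nm in names(config$continuous_spec)) {
    cs <- config$continuous_spec[[nm]]
    x <- switch(cs$dist,
      normal = rnorm(n, cs$mean, cs$sd),
      lognormal = exp(rnorm(n, cs$meanlog, cs$sdlog)),
      stop("unknown continuous dist: ", cs$dist))
    if (!is.null(cs$min)) x <- pmax(x, cs$min)
    if (!is.null(cs$max)) x <- pmin(x, cs$max)
    if (!is.null(cs$round)) x <- round(x, cs$round)
    out[[nm]] <- x
  }
  for (nm in names(config$demographics_spec)) {
    ds <- config$demographics_spec[[nm]]
    out[[nm]] <- factor(sample(ds$levels, n, replace = TRUE,
                               prob = ds$probs), levels = ds$levels)
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

# Linear predictor contribution of the configured true effects.
effect_offset <- function(config, covariates) {
  eta <- numeric(nrow(covariates))
  for (key in names(config$true_effects)) {
    eff <- config$true_effects[[key]]
    if (eff == 0) next
    base <- effect_base_name(key)
    x <- covariates[[base]]
    if (grepl("=", key, fixed = TRUE)) {
      lev <- sub("^.*=", "", key)
      z <- as.numeric(x == lev)
    } else if (is.factor(x)) {
      # bare name on a binary factor: indicator of the non-reference level
      z <- as.numeric(x == levels(x)[2])
    } else {
      s <- sd(x)
      z <- if (s > 0) (x - mean(x)) / s else x * 0
    }
    eta <- eta + eff * z
  }
  eta
}

#' Tune the global intercept to hit the target prevalence
#'
#' Monte-Carlo root-finding for the logit-scale intercept \eqn{b_0} such
#' that the marginal simulated event probability (averaging over covariates,
#' configured true effects and site random intercepts) equals
#' `target_prevalence`. A single covariate draw of size `n_mc` is simulated
#' from a seed derived from the config seed, then
#' \eqn{\bar p(b_0) = \mathrm{mean}\,\mathrm{logit}^{-1}(b_0 + u + \eta)}
#' is solved for the target with [stats::uniroot()].
#'
#' @param config a [synthetic_config()].
#' @param n_mc Monte-Carlo sample size (at least 10^4).
#' @return the intercept `b0` (scalar); the achieved Monte-Carlo prevalence
#'   is within 0.002 of the target.
#' @examples
#' cfg <- default_pnat_config()
#' cfg$true_effects[] <- 0; cfg$site_sd <- 0
#' tune_intercept(cfg) # ~ qlogis(0.10) = -2.197
#' @export
tune_intercept <- function(config, n_mc = 1e5) {
  stop_if_not(n_mc >= 1e4, "`n_mc` must be at least 10^4")
  with_seed(config$seed + 1000003L, {
    cov <- draw_covariates(config, n_mc)
    eta <- effect_offset(config, cov)
    if (config$site_sd > 0) eta <- eta + rnorm(n_mc, 0, config$site_sd)
    f <- function(b0) mean(plogis(b0 + eta)) - config$target_prevalence
    r <- tryCatch(
      uniroot(f, lower = qlogis(config$target_prevalence) - 10,
              upper = qlogis(config$target_prevalence) + 10,
              extendInt = "yes", tol = 1e-8, maxiter = 100),
      error = function(e) stop("intercept root-find failed in 100 iterations",
                               " (bracket ", qlogis(config$target_prevalence) - 10,
                               ", ", qlogis(config$target_prevalence) + 10, "): ",
                               conditionMessage(e), call. = FALSE))
    r$root
  })
}

#' Generate a synthetic cohort
#'
#' Draws a complete cohort (no missing values) from a
#' [synthetic_config()]: ordinal items by thresholding equicorrelated latent
#' Gaussians (Gaussian copula), categoricals from their configured
#' frequencies, sites from `site_probs`, and the binary outcome from
#' \eqn{\mathrm{Bernoulli}(\mathrm{logit}^{-1}(b_0 + u_{site} + \eta))}
#' with \eqn{b_0} tuned by [tune_intercept()]. Identical configs (including
#' the seed) give identical cohorts.
#'
#' @param config a [synthetic_config()].
#' @param b0 optional pre-tuned intercept; computed when `NULL`.
#' @return a data frame of class `"cohort_data"` with columns `subject_id`,
#'   `site_id`, `outcome` and the predictors; attributes `kinds` (named
#'   character vector of column kinds), `config`, and `b0`.
#' @export
generate_cohort <- function(config, b0 = NULL) {
  stop_if_not(inherits(config, "synthetic_config"),
              "`config` must be a synthetic_config")
  stop_if_not(config$n_subjects >= 2 * config$n_sites,
              "`n_subjects` must be at least twice `n_sites`")
  if (is.null(b0)) b0 <- tune_intercept(config)
  n <- config$n_subjects
  with_seed(config$seed, {
    site <- sample(seq_len(config$n_sites), n, replace = TRUE,
                   prob = config$site_probs)
    u <- rnorm(config$n_sites, 0, config$site_sd)
    cov <- draw_covariates(config, n)
    eta <- b0 + u[site] + effect_offset(config, cov)
    y <- rbinom(n, 1, plogis(eta))
    dat <- cbind(data.frame(subject_id = seq_len(n),
                            site_id = factor(site,
                                             levels = seq_len(config$n_sites)),
                            outcome = y),
                 cov)
    kinds <- c(subject_id = "id", site_id = "site", outcome = "outcome",
               predictor_kinds(config))
    structure(dat, kinds = kinds, config = config, b0 = b0,
              class = c("cohort_data", "data.frame"))
  })
}

# Named vector of predictor kinds implied by a config.
predictor_kinds <- function(config) {
  k <- c()
  for (b in config$item_blocks) {
    k[names(b$items)] <- paste0("ordinal:", b$name)
  }
  k[names(config$continuous_spec)] <- "continuous"
  for (nm in names(config$demographics_spec)) {
    ds <- config$demographics_spec[[nm]]
    k[nm] <- if (nm == "treatment") "treatment"
             else if (nm == "nmr") "nmr"
             else if (nm == "baseline_nae") "baseline_nae"
             else if (length(ds$levels) == 2) "binary" else "categorical"
  }
  k
}

#' Predictor column names of a cohort
#'
#' @param cohort a `cohort_data` object.
#' @return character vector of predictor column names (everything except
#'   subject id, site and outcome).
#' @export
predictor_names <- function(cohort) {
  setdiff(names(cohort), c("subject_id", "site_id", "outcome"))
}

#' Read and write cohorts as CSV with a JSON sidecar
#'
#' `write_cohort()` writes the cohort table as plain CSV (factors as
#' strings, outcome as 0/1) plus `<path>.json` describing the column kinds;
#' `read_cohort()` reconstructs the typed `cohort_data` object.
#'
#' @param cohort a `cohort_data` object.
#' @param path CSV file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a `cohort_data` object.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  kinds <- attr(cohort, "kinds")
  lev <- lapply(Filter(is.factor, as.data.frame(cohort)), levels)
  jsonlite::write_json(list(kinds = as.list(kinds), levels = lev),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  dat <- read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  for (nm in names(meta$levels)) {
    dat[[nm]] <- factor(dat[[nm]], levels = meta$levels[[nm]])
  }
  structure(dat, kinds = unlist(meta$kinds),
            class = c("cohort_data", "data.frame"))
}
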