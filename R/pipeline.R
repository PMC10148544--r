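#' Baseline descriptive and univariate-screen table
#'
#' The usual cohort-description table split by outcome status: scale items
#' and scores as median \[Q1, Q3\], other continuous variables as mean (SD),
#' categoricals as N (%) per level with the reference level marked. Each
#' predictor additionally gets the posterior probability of harm
#' P(OR > 1) from an unadjusted Bayesian multilevel logistic regression
#' (that single predictor in raw units, site random intercept, vague
#' prior). With an empty outcome class only the descriptives are produced.
#'
#' @param cohort a `cohort_data` object.
#' @param predictors predictors to tabulate (default: all).
#' @param mcmc an [mcmc_config()] for the univariate fits; the default uses
#'   2 chains of 500/500 for speed.
#' @return data frame of class `"baseline_table"` with one row per
#'   predictor level: `variable`, `level`, `events`, `no_events`, `p_harm`.
#' @export
baseline_table <- function(cohort, predictors = NULL, mcmc = NULL) {
  preds <- predictors %||% predictor_names(cohort)
  mcmc <- mcmc %||% mcmc_config(chains = 2, warmup = 500, sampling = 500)
  d <- as.data.frame(cohort)
  kinds <- attr(cohort, "kinds")
  y <- d$outcome
  site <- as.integer(d$site_id)
  both_classes <- length(unique(y)) == 2

  fmt_num <- function(x, kind) {
    if (grepl("^ordinal", kind) || kind == "score") {
      sprintf("%s [%s, %s]", median(x), quantile(x, 0.25), quantile(x, 0.75))
    } else {
      sprintf("%.0f (%.0f)", mean(x), sd(x))
    }
  }
  rows <- list()
  for (nm in preds) {
    x <- d[[nm]]
    kind <- kinds[[nm]] %||% if (is.numeric(x)) "continuous" else "categorical"
    p_harm <- rep(NA_real_, 1)
    if (is.numeric(x)) {
      if (both_classes) {
        fit <- sample_posterior(matrix(x, dimnames = list(NULL, nm)), y,
                                site, prior_spec("vague"), mcmc)
        p_harm <- mean(beta_draws(fit)[, 1] > 0)
      }
      rows[[nm]] <- data.frame(
        variable = nm, level = "",
        events = fmt_num(x[y == 1], kind),
        no_events = fmt_num(x[y == 0], kind), p_harm = p_harm)
    } else {
      f <- if (is.factor(x)) x else factor(x)
      X <- vapply(levels(f)[-1], function(l) as.numeric(f == l),
                  numeric(length(f)))
      ph <- rep(NA_real_, nlevels(f) - 1)
      if (both_classes) {
        fit <- sample_posterior(X, y, site, prior_spec("vague"), mcmc)
        ph <- colMeans(beta_draws(fit) > 0)
      }
      tab1 <- table(f[y == 1]); tab0 <- table(f[y == 0])
      rows[[nm]] <- data.frame(
        variable = nm, level = levels(f),
        events = sprintf("%d (%.0f%%)", tab1, 100 * prop.table(tab1 + 0)),
        no_events = sprintf("%d (%.0f%%)", tab0, 100 * prop.table(tab0 + 0)),
        p_harm = c(NA_real_, ph))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("baseline_table", "data.frame")
  out
}

#' Enumerate the model grid
#'
#' The study grid crosses the predictor sets with the shrinkage families
#' and their degrees of freedom, plus one vague-prior comparator per
#' predictor set: 2 x (2 x 4 + 1) = 18 model configurations by default.
#'
#' @param predictor_sets predictor sets to cross (default summary + item).
#' @param families shrinkage families (default horseshoe + laplace).
#' @param dfs degrees of freedom grid (default 1, 3, 5, 7).
#' @return data frame with columns `predictor_set`, `family`, `df` (NA for
#'   vague) and `id`.
#' @export
grid_configs <- function(predictor_sets = c("summary", "item"),
                         families = c("horseshoe", "laplace"),
                         dfs = c(1, 3, 5, 7)) {
  shrink <- expand.grid(predictor_set = predictor_sets, family = families,
                        df = dfs, stringsAsFactors = FALSE)
  vague <- data.frame(predictor_set = predictor_sets, family = "vague",
                      df = NA_integer_)
  g <- rbind(shrink, vague)
  g <- g[order(g$predictor_set, g$family, g$df), ]
  g$id <- paste0(g$predictor_set, ":", g$family,
                 ifelse(is.na(g$df), "", paste0(":df", g$df)))
  rownames(g) <- NULL
  g
}

#' Fit and score the full model grid
#'
#' Encodes both predictor sets, fits every grid configuration on the
#' training subjects with [fit_with_escalation()], scores each by WAIC and
#' PSIS-LOO on the training set, and ranks the converged models
#' ([rank_models()]). Non-converged models stay in the table flagged but
#' unranked, as a grid must tolerate hard-to-sample cells.
#'
#' @param cohort a screened `cohort_data`.
#' @param split a [split_cohort()] result.
#' @param mcmc an [mcmc_config()].
#' @param grid a [grid_configs()] table (defaults to the full 18-model
#'   grid).
#' @param scale_on `"full"` standardizes with whole-cohort statistics (the
#'   conventional order, which leaks a little test information);
#'   `"train"` uses training-set statistics only.
#' @param rhat_max convergence threshold for escalation.
#' @return an object of class `"grid_result"`: list with `table` (ranked
#'   comparison), `fits`, `designs` (per predictor set, full-cohort rows),
#'   `winner_id`, `split`, `train_rows`, `test_rows`, `site_ids`, `y`.
#' @export
run_grid <- function(cohort, split, mcmc, grid = grid_configs(),
                     scale_on = c("full", "train"), rhat_max = 1.05) {
  scale_on <- match.arg(scale_on)
  d <- as.data.frame(cohort)
  train_rows <- which(d$subject_id %in% split$train_ids)
  test_rows <- which(d$subject_id %in% split$test_ids)
  y <- d$outcome
  site <- as.integer(d$site_id)
  designs <- list()
  for (set in unique(grid$predictor_set)) {
    scaling <- if (scale_on == "train") {
      encode_design(cohort[train_rows, ], set)$scaling
    } else NULL
    designs[[set]] <- encode_design(cohort, set, scaling = scaling)
  }
  fits <- list()
  scores <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    prior <- if (g$family == "vague") prior_spec("vague")
             else prior_spec(g$family, df = g$df)
    des <- designs[[g$predictor_set]]
    X_tr <- structure(list(matrix = des$matrix[train_rows, , drop = FALSE],
                           column_map = des$column_map,
                           scaling = des$scaling,
                           predictor_set = des$predictor_set),
                      class = "design_matrix")
    fit <- fit_with_escalation(X_tr, y[train_rows], site[train_rows], prior,
                               mcmc, rhat_max = rhat_max)
    fits[[g$id]] <- fit
    scores[[g$id]] <- score_model(fit, X_tr, y[train_rows], site[train_rows],
                                  id = g$id)
    scores[[g$id]]$predictor_set <- g$predictor_set
  }
  tab <- rank_models(scores)
  structure(list(table = tab, fits = fits, designs = designs,
                 winner_id = tab$id[which(tab$rank == 1)], split = split,
                 train_rows = train_rows, test_rows = test_rows,
                 site_ids = site, y = y, grid = grid),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat("<grid_result>", nrow(x$table), "models; winner:", x$winner_id, "\n")
  print(head(x$table[, c("id", "waic", "looic", "converged", "rank")], 5))
  invisible(x)
}

#' Finalize the winning model: selection sweep, harm table, evaluation
#'
#' Runs the hard-shrinkage [threshold_sweep()] on the grid winner (refits
#' with the winner's own shrinkage prior), then reports the chosen reduced
#' model's posterior harm table and its test-set evaluation (AUROC, Brier,
#' calibration; known-site prediction, since the split is within site),
#' plus the train-set AUROC for comparison. An empty selection yields an
#' intercept-only final model, flagged in the output.
#'
#' @param grid_result a [run_grid()] result.
#' @param mcmc an [mcmc_config()] for the sweep refits.
#' @param thresholds harm-probability thresholds (default 0.7, 0.65, 0.6).
#' @param tol AUROC tolerance for the sweep.
#' @return list with `sweep` (threshold table), `harm` (final-model harm
#'   table or `NULL`), `eval` (test-set `eval_report`), `train_auroc`,
#'   `intercept_only` flag, and the final `fit`.
#' @export
finalize_model <- function(grid_result, mcmc, thresholds = c(0.7, 0.65, 0.6),
                           tol = 0.01) {
  gr <- grid_result
  win <- gr$fits[[gr$winner_id]]
  stop_if_not(isTRUE(win$converged), "winning model did not converge")
  set <- gr$grid$predictor_set[gr$grid$id == gr$winner_id]
  des <- gr$designs[[set]]
  sub_rows <- function(rows) {
    structure(list(matrix = des$matrix[rows, , drop = FALSE],
                   column_map = des$column_map, scaling = des$scaling,
                   predictor_set = des$predictor_set),
              class = "design_matrix")
  }
  tr <- gr$train_rows; te <- gr$test_rows
  sweep <- threshold_sweep(win, sub_rows(tr), gr$y[tr], gr$site_ids[tr],
                           sub_rows(te), gr$y[te], gr$site_ids[te],
                           thresholds = thresholds, refit_prior = win$prior,
                           mcmc = mcmc, tol = tol)
  final_fit <- sweep$chosen$fit
  intercept_only <- is.null(final_fit)
  if (intercept_only) {
    warning("empty hard-shrinkage selection: intercept-only final model")
    final_fit <- win
    harm <- NULL
    sel_preds <- character(0)
  } else {
    harm <- harm_probabilities(final_fit)
    sel_preds <- sweep$chosen$selection$predictors
  }
  pred_des <- function(rows) {
    if (intercept_only) sub_rows(rows) else
      subset_design(sub_rows(rows), sel_preds)
  }
  pp_te <- posterior_predict(if (intercept_only) win else final_fit,
                             pred_des(te), gr$site_ids[te])
  pp_tr <- posterior_predict(if (intercept_only) win else final_fit,
                             pred_des(tr), gr$site_ids[tr])
  list(sweep = sweep$table, full_auroc = sweep$full_auroc,
       chosen_threshold = sweep$chosen$threshold, harm = harm,
       eval = evaluate_predictions(pp_te$prob, gr$y[te]),
       train_auroc = auroc(pp_tr$prob, gr$y[tr])$auc,
       intercept_only = intercept_only, fit = final_fit,
       selected_predictors = sel_preds)
}

#' Run the whole study end to end
#'
#' Simulate (or load) a cohort, screen predictors, split, optionally build
#' the baseline table, fit and rank the model grid, finalize the winner and
#' evaluate it. With `out_dir` set, all tables are persisted as CSV, the
#' evaluation report and a reproducibility manifest as JSON. Identical
#' config and seed reproduce identical outputs.
#'
#' @param config a [synthetic_config()] (ignored when `cohort` is given).
#' @param seed master seed; derives the cohort, split and MCMC seeds.
#' @param cohort optional pre-built `cohort_data` (e.g. from
#'   [read_cohort()]); skips simulation.
#' @param mcmc an [mcmc_config()]; its seed is overridden from `seed`.
#' @param grid a [grid_configs()] table.
#' @param ratio training fraction.
#' @param thresholds hard-shrinkage thresholds.
#' @param baseline build the univariate baseline table? (expensive; one
#'   MCMC fit per predictor).
#' @param scale_on standardization source, `"full"` or `"train"`.
#' @param out_dir optional output directory.
#' @return list with `cohort`, `screen`, `split`, `epv`, `baseline`,
#'   `grid`, `final`, `manifest`.
#' @export
run_study <- function(config = default_pnat_config(), seed = 1L,
                      cohort = NULL, mcmc = mcmc_config(),
                      grid = grid_configs(), ratio = 0.7,
                      thresholds = c(0.7, 0.65, 0.6), baseline = FALSE,
                      scale_on = c("full", "train"), out_dir = NULL) {
  scale_on <- match.arg(scale_on)
  if (is.null(cohort)) {
    config$seed <- as.integer(seed)
    cohort <- generate_cohort(config)
  }
  scr <- screen_predictors(cohort)
  split <- split_cohort(scr$cohort, ratio = ratio, seed = seed + 1L)
  mcmc$seed <- as.integer(seed + 2L)
  base_tab <- if (isTRUE(baseline)) baseline_table(scr$cohort) else NULL
  gr <- run_grid(scr$cohort, split, mcmc, grid = grid, scale_on = scale_on)
  fin <- finalize_model(gr, mcmc, thresholds = thresholds)
  epv <- vapply(gr$designs, function(d) {
    compute_epv(sum(gr$y[gr$train_rows]), ncol(d$matrix))
  }, numeric(1))
  manifest <- list(package = "rarebayes",
                   version = as.character(utils::packageVersion("rarebayes")),
                   seed = seed, n_subjects = nrow(cohort),
                   n_sites = nlevels(as.data.frame(cohort)$site_id),
                   ratio = ratio, thresholds = thresholds,
                   mcmc = unclass(mcmc), grid_ids = gr$grid$id,
                   winner = gr$winner_id,
                   chosen_threshold = fin$chosen_threshold,
                   selected = fin$selected_predictors, epv = as.list(epv))
  out <- list(cohort = cohort, screen = scr$report, split = split,
              epv = epv, baseline = base_tab, grid = gr, final = fin,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    write.csv(gr$table, file.path(out_dir, "model_comparison.csv"),
              row.names = FALSE)
    write.csv(fin$sweep, file.path(out_dir, "threshold_sweep.csv"),
              row.names = FALSE)
    if (!is.null(fin$harm)) {
      write.csv(fin$harm, file.path(out_dir, "harm_table.csv"),
                row.names = FALSE)
    }
    if (!is.null(base_tab)) {
      write.csv(base_tab, file.path(out_dir, "baseline_table.csv"),
                row.names = FALSE)
    }
    jsonlite::write_json(
      list(auroc = fin$eval$auroc, auroc_ci = fin$eval$auroc_ci,
           brier = fin$eval$brier, brier_null = fin$eval$brier_null,
           calibration_intercept = fin$eval$calibration_intercept,
           calibration_slope = fin$eval$calibration_slope,
           train_auroc = fin$train_auroc),
      file.path(out_dir, "eval_report.json"), auto_unbox = TRUE,
      digits = NA)
    write.csv(fin$eval$deciles, file.path(out_dir, "calibration_deciles.csv"),
              row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
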