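# Columns that are part of the study design and therefore exempt from
# data-driven screening (treatment arm, metabolizer group, baseline event
# indicator): they stay in the model regardless of their variance profile.
protected_kinds <- c("treatment", "nmr", "baseline_nae")

#' Screen predictors for degenerate or redundant columns
#'
#' Applies the conventional pre-modelling screen: drops zero-variance
#' columns; near-zero-variance columns (frequency ratio of the two most
#' common values above `freq_ratio_cut` *and* percent unique values below
#' `unique_pct_cut`); one member of each highly correlated numeric pair
#' (|Pearson r| above `corr_cut`, dropping the member with the larger mean
#' absolute correlation); and columns that are exact linear combinations of
#' retained columns. Uses `caret::nearZeroVar()`,
#' `caret::findCorrelation()` and `caret::findLinearCombos()`. Treatment,
#' metabolizer-group and baseline-event columns are design-protected and
#' never dropped.
#'
#' @param cohort a `cohort_data` object.
#' @param freq_ratio_cut near-zero-variance frequency-ratio cutoff
#'   (default 19, i.e. 95/5).
#' @param unique_pct_cut near-zero-variance percent-unique cutoff
#'   (default 10).
#' @param corr_cut pairwise absolute-correlation cutoff (default 0.9).
#' @return list with `cohort` (screened) and `report`, a `screen_report`
#'   whose five name lists partition the input predictors.
#' @export
screen_predictors <- function(cohort, freq_ratio_cut = 19,
                              unique_pct_cut = 10, corr_cut = 0.9) {
  stop_if_not(nrow(cohort) > 0, "cohort is empty")
  stop_if_not(freq_ratio_cut > 0 && unique_pct_cut > 0 && corr_cut > 0,
              "screening cutoffs must be positive")
  preds <- predictor_names(cohort)
  kinds <- attr(cohort, "kinds")
  protected <- preds[kinds[preds] %in% protected_kinds]
  dat <- as.data.frame(cohort)[preds]

  nzv <- caret::nearZeroVar(dat, freqCut = freq_ratio_cut,
                            uniqueCut = unique_pct_cut, saveMetrics = TRUE)
  zero_var <- setdiff(rownames(nzv)[nzv$zeroVar], protected)
  near_zero <- setdiff(rownames(nzv)[nzv$nzv & !nzv$zeroVar], protected)
  keep <- setdiff(preds, c(zero_var, near_zero))

  num <- keep[vapply(dat[keep], is.numeric, logical(1))]
  high_corr <- character(0)
  if (length(num) >= 2) {
    cm <- cor(dat[num])
    idx <- caret::findCorrelation(cm, cutoff = corr_cut, exact = TRUE)
    high_corr <- setdiff(num[idx], protected)
    keep <- setdiff(keep, high_corr)
  }

  lin_dep <- character(0)
  if (length(keep) >= 2) {
    mm <- model.matrix(~ . - 1, data = dat[keep])
    combo <- caret::findLinearCombos(mm)
    if (length(combo$remove)) {
      owner <- attr(mm, "assign")
      lin_dep <- setdiff(unique(keep[owner[combo$remove]]), protected)
      keep <- setdiff(keep, lin_dep)
    }
  }
  stop_if_not(length(keep) > 0, "screening dropped every predictor")

  dropped <- c(zero_var, near_zero, high_corr, lin_dep)
  out <- cohort[, c("subject_id", "site_id", "outcome", keep)]
  attr(out, "kinds") <- kinds[names(kinds) %in% names(out)]
  attr(out, "config") <- attr(cohort, "config")
  class(out) <- class(cohort)
  report <- structure(list(dropped_zero_variance = zero_var,
                           dropped_near_zero_variance = near_zero,
                           dropped_high_correlation = high_corr,
                           dropped_linear_dependence = lin_dep,
                           retained = keep),
                      class = "screen_report")
  list(cohort = out, report = report)
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>", length(x$retained), "retained;",
      length(x$dropped_zero_variance), "zero-var,",
      length(x$dropped_near_zero_variance), "near-zero-var,",
      length(x$dropped_high_correlation), "high-corr,",
      length(x$dropped_linear_dependence), "linearly dependent dropped\n")
  invisible(x)
}

# Scale summary scores derived from the item batteries.
summary_scores <- function(cohort) {
  d <- as.data.frame(cohort)
  kinds <- attr(cohort, "kinds")
  mnws <- names(kinds)[kinds == "ordinal:mnws"]
  panas <- names(kinds)[kinds == "ordinal:panas"]
  pos <- intersect(panas, c("interested", "excited", "strong", "enthusiastic",
                            "proud", "alert", "inspired", "determined",
                            "attentive", "active"))
  neg <- setdiff(panas, pos)
  out <- list()
  if (length(mnws)) out$mnws_total <- rowSums(d[mnws])
  if (length(pos)) out$panas_positive <- rowSums(d[pos])
  if (length(neg)) out$panas_negative <- rowSums(d[neg])
  qs <- intersect(c("qsub_f1", "qsub_f2"), names(d))
  if (length(qs)) out$qsub_total <- rowSums(d[qs])
  as.data.frame(out)
}

#' Build the standardized, dummy-coded design matrix
#'
#' Encodes a screened cohort into the numeric matrix handed to the sampler.
#' Two predictor sets are supported: `"summary"` replaces the item
#' batteries with per-scale summary scores (withdrawal total, positive and
#' negative affect totals, urges total) while `"item"` carries each ordinal
#' item, both urges factor scores and the heaviness-of-smoking index as
#' individual columns. Both sets share the demographic/clinical columns,
#' treatment, metabolizer group, the baseline event indicator and the
#' metabolizer-by-treatment interaction. Continuous and ordinal columns are
#' z-standardized (ordinal scores treated as numeric); each categorical
#' predictor with k levels contributes k-1 indicators against its declared
#' reference (first) level; indicators are not standardized.
#'
#' @param cohort a (screened) `cohort_data` object.
#' @param predictor_set `"summary"` or `"item"`.
#' @param scaling optional list of per-column `c(mean, sd)` to standardize
#'   with (e.g. from a training design, for encoding test data); computed
#'   from `cohort` when `NULL`.
#' @param interaction include metabolizer-by-treatment interaction columns?
#' @return an object of class `"design_matrix"`: list with `matrix` (n x p,
#'   named columns), `column_map` (data frame mapping columns to source
#'   predictors/categories and interaction flags), `scaling`, and
#'   `predictor_set`.
#' @export
encode_design <- function(cohort, predictor_set = c("summary", "item"),
                          scaling = NULL, interaction = TRUE) {
  predictor_set <- match.arg(predictor_set)
  kinds <- attr(cohort, "kinds")
  d <- as.data.frame(cohort)
  preds <- predictor_names(cohort)

  item_cols <- preds[grepl("^ordinal:", kinds[preds])]
  qsub_cols <- intersect(c("qsub_f1", "qsub_f2"), preds)
  base_cont <- setdiff(preds[kinds[preds] == "continuous"], qsub_cols)
  cat_cols <- preds[kinds[preds] %in%
                      c("categorical", "binary", "treatment", "nmr",
                        "baseline_nae")]
  bad <- setdiff(preds, c(item_cols, qsub_cols, base_cont, cat_cols))
  stop_if_not(length(bad) == 0,
              paste("unknown predictor kinds for:", paste(bad, collapse = ", ")))

  if (predictor_set == "summary") {
    num_part <- cbind(d[base_cont], summary_scores(cohort))
  } else {
    num_part <- d[c(base_cont, item_cols, qsub_cols)]
  }

  cols <- list(); cmap <- list()
  for (nm in names(num_part)) {
    x <- as.numeric(num_part[[nm]])
    sc <- scaling[[nm]] %||% c(mean = mean(x), sd = sd(x))
    stop_if_not(sc[2] > 0, paste("zero-variance column in design:", nm))
    cols[[nm]] <- (x - sc[1]) / sc[2]
    cmap[[nm]] <- data.frame(column = nm, predictor = nm,
                             category = "continuous", interaction = FALSE)
    if (is.null(scaling)) scaling <- list()
    scaling[[nm]] <- sc
  }
  for (nm in cat_cols) {
    f <- d[[nm]]
    if (!is.factor(f)) f <- factor(f)
    for (lev in levels(f)[-1]) {
      cn <- paste0(nm, "_", lev)
      cols[[cn]] <- as.numeric(f == lev)
      cmap[[cn]] <- data.frame(column = cn, predictor = nm, category = lev,
                               interaction = FALSE)
    }
  }
  if (interaction && "nmr" %in% cat_cols && "treatment" %in% cat_cols) {
    nmr_ind <- as.numeric(d$nmr == levels(d$nmr)[2])
    for (lev in levels(d$treatment)[-1]) {
      cn <- paste0("nmr_x_treatment_", lev)
      cols[[cn]] <- nmr_ind * as.numeric(d$treatment == lev)
      cmap[[cn]] <- data.frame(column = cn, predictor = "nmr_x_treatment",
                               category = lev, interaction = TRUE)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  structure(list(matrix = X, column_map = do.call(rbind, cmap),
                 scaling = scaling, predictor_set = predictor_set),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix>", nrow(x$matrix), "x", ncol(x$matrix),
      sprintf("(%s set)\n", x$predictor_set))
  invisible(x)
}

#' Subset a design matrix to selected predictors
#'
#' Keeps whole predictor blocks (all dummies of a categorical, the single
#' column of a numeric predictor) for the named predictors.
#'
#' @param design a `design_matrix`.
#' @param predictors character vector of predictor names to keep.
#' @return a reduced `design_matrix`.
#' @export
subset_design <- function(design, predictors) {
  keep <- design$column_map$predictor %in% predictors
  stop_if_not(any(keep), "no design columns match the requested predictors")
  structure(list(matrix = design$matrix[, design$column_map$column[keep],
                                        drop = FALSE],
                 column_map = design$column_map[keep, , drop = FALSE],
                 scaling = design$scaling,
                 predictor_set = design$predictor_set),
            class = "design_matrix")
}

#' Outcome-preserving stratified train/test split
#'
#' Splits subjects into train and test sets at the given ratio within each
#' site-by-metabolizer stratum, allocating events and non-events separately
#' by largest-remainder rounding so per-stratum and overall event rates in
#' the two parts differ by at most one subject's worth. Strata with fewer
#' than two subjects are allocated wholly to train with a warning.
#'
#' @param cohort a `cohort_data` object.
#' @param ratio training fraction in (0, 1) (default 0.7).
#' @param seed integer seed controlling which subjects fill each allocation.
#' @return an object of class `"split_result"`: list with `train_ids`,
#'   `test_ids` (subject ids) and `strata`, a per-stratum data frame of
#'   sizes and event rates in each part.
#' @export
split_cohort <- function(cohort, ratio = 0.7, seed = 1L) {
  stop_if_not(ratio > 0 && ratio < 1, "`ratio` must lie in (0, 1)")
  d <- as.data.frame(cohort)
  stratum <- interaction(d$site_id,
                         if ("nmr" %in% names(d)) d$nmr else factor("all"),
                         drop = TRUE, sep = ":")
  small <- names(which(table(stratum) < 2))
  if (length(small)) {
    warning("strata with < 2 subjects allocated wholly to train: ",
            paste(small, collapse = ", "))
  }
  cells <- split(seq_len(nrow(d)),
                 list(stratum = stratum, event = d$outcome), drop = FALSE)
  # largest-remainder allocation, events and non-events pooled separately
  alloc <- integer(length(cells))
  names(alloc) <- names(cells)
  for (ev in c("0", "1")) {
    ids <- grep(paste0("\\.", ev, "$"), names(cells))
    sizes <- lengths(cells[ids])
    target <- ratio * sizes
    base <- floor(target)
    extra <- round(ratio * sum(sizes)) - sum(base)
    if (extra > 0) {
      give <- order(target - base, sizes, decreasing = TRUE)[seq_len(extra)]
      base[give] <- base[give] + 1
    }
    alloc[ids] <- pmin(base, sizes)
  }
  train_rows <- with_seed(seed, {
    unlist(lapply(names(cells), function(cn) {
      rows <- cells[[cn]]
      st <- sub("\\.[01]$", "", cn)
      if (st %in% small) return(rows)
      if (length(rows) <= 1 && alloc[cn] >= length(rows)) return(rows)
      rows[sample.int(length(rows), alloc[cn])]
    }), use.names = FALSE)
  })
  train_rows <- sort(unique(train_rows))
  test_rows <- setdiff(seq_len(nrow(d)), train_rows)
  strata <- do.call(rbind, lapply(levels(stratum), function(s) {
    tr <- intersect(train_rows, which(stratum == s))
    te <- intersect(test_rows, which(stratum == s))
    data.frame(stratum = s, n_train = length(tr), n_test = length(te),
               events_train = sum(d$outcome[tr]),
               events_test = sum(d$outcome[te]),
               rate_train = if (length(tr)) mean(d$outcome[tr]) else NA_real_,
               rate_test = if (length(te)) mean(d$outcome[te]) else NA_real_)
  }))
  structure(list(train_ids = d$subject_id[train_rows],
                 test_ids = d$subject_id[test_rows], strata = strata,
                 ratio = ratio, seed = seed),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat("<split_result>", length(x$train_ids), "train /", length(x$test_ids),
      "test across", nrow(x$strata), "strata\n")
  invisible(x)
}

#' Events-per-variable ratio
#'
#' Number of training-set events divided by the number of candidate design
#' columns, rounded to one decimal — the bookkeeping quantity motivating
#' shrinkage (values below ~10 flag overfitting risk for unpenalized
#' logistic regression).
#'
#' @param n_events_train number of outcome events in the training set.
#' @param n_design_columns number of design-matrix columns.
#' @return scalar EPV.
#' @examples
#' compute_epv(86, 26) # 3.3
#' compute_epv(86, 58) # 1.5
#' @export
compute_epv <- function(n_events_train, n_design_columns) {
  stop_if_not(n_design_columns > 0, "`n_design_columns` must be positive")
  round(n_events_train / n_design_columns, 1)
}
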