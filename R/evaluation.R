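#' Assemble a cohort for modeling and evaluation
#'
#' Runs wear-time filtering and change-point segmentation once over the
#' epoch records and bundles the results with covariates and capacity
#' measurements. Downstream tuning and evaluation rebuild grids, profiles
#' and quartile cutoffs from training partitions only, so the expensive
#' segmentation is shared.
#'
#' @param epochs Epoch data frame ([read_epochs()] / [simulate_cohort()]).
#' @param covariates Covariate data frame ([read_covariates()]).
#' @param capacity Capacity data frame ([read_capacity()]).
#' @param config A [seg_config()].
#' @return An object of class `"activity_cohort"`.
#' @export
build_cohort <- function(epochs, covariates, capacity,
                         config = seg_config()) {
  seg <- segment_activity(epochs, config)
  structure(list(segments = seg$segments, days = seg$days,
                 covariates = covariates, capacity = capacity,
                 seg_config = config),
            class = "activity_cohort")
}

#' @export
print.activity_cohort <- function(x, ...) {
  cat(sprintf(paste0("Activity cohort: %d subjects with valid days, %d",
                     " segments over %d valid days\n"),
              length(unique(x$days$subject_id[x$days$valid])),
              nrow(x$segments), sum(x$days$valid)))
  invisible(x)
}

.MEASURES <- c(walk400 = "walk400_time", walk20 = "walk20_pace",
               sitstand = "sitstand_rate")

.measure_column <- function(measure) {
  if (measure %in% .MEASURES) return(measure)
  if (measure %in% names(.MEASURES)) return(.MEASURES[[measure]])
  stop("unknown measure: ", measure, " (use one of ",
       paste(names(.MEASURES), collapse = ", "), ")")
}

# subject-level analysis frame: covariates + capacity value, complete cases,
# restricted to subjects with >= 1 valid day
.eval_frame <- function(cohort, measure) {
  col <- .measure_column(measure)
  vd <- cohort$days[cohort$days$valid, , drop = FALSE]
  ok_subj <- unique(vd$subject_id)
  df <- merge(cohort$covariates,
              cohort$capacity[, c("subject_id", col)], by = "subject_id")
  df <- df[df$subject_id %in% ok_subj, , drop = FALSE]
  df$value <- df[[col]]
  df <- df[stats::complete.cases(df[, c("bmi", "age", "sex", "height",
                                        "oa_subcohort", "value")]), ,
           drop = FALSE]
  if (nrow(df) < 10) stop("too few complete subjects for evaluation")
  df[order(df$subject_id), , drop = FALSE]
}

#' Quartile categorization from training quantiles
#'
#' Converts continuous capacity values to ordered categories using the
#' empirical quartiles of the training values (linear-interpolation
#' quantiles, R type 7): category 1 for values strictly below Q1 (the lowest
#' quartile), 3 for values strictly above Q3 (the highest quartile), and 2
#' for the interquartile range. Values exactly at a cutoff map to
#' category 2. Cutoffs always come from the training values, never from the
#' new values.
#'
#' @param train_values Numeric vector of at least 4 training values.
#' @param values Numeric vector to categorize (defaults to the training
#'   values themselves).
#' @return Integer vector of categories in 1..3, with attributes `Q1` and
#'   `Q3`.
#' @export
quartile_categorize <- function(train_values, values = train_values) {
  if (length(train_values) < 4)
    stop("at least 4 training values are required")
  q <- stats::quantile(train_values, c(0.25, 0.75), type = 7, names = FALSE)
  out <- ifelse(values < q[1], 1L, ifelse(values > q[2], 3L, 2L))
  attr(out, "Q1") <- q[1]
  attr(out, "Q3") <- q[2]
  out
}

#' Goodman-Kruskal Gamma rank correlation
#'
#' Computes `Gamma = (C - D) / (C + D)` over all unordered pairs, where C
#' counts concordant pairs (both vectors order the pair the same strict
#' way) and D discordant pairs; pairs tied on either vector are excluded.
#' Computed from the contingency table of the two ordinal vectors.
#'
#' @param predicted,true Equal-length ordinal vectors (length >= 2).
#' @return Gamma in \[-1, 1\], or flagged `NaN` with a warning when no
#'   untied pairs exist.
#' @examples
#' goodman_kruskal_gamma(c(1, 2, 3, 2), c(1, 3, 2, 2))  # 0.5
#' @export
goodman_kruskal_gamma <- function(predicted, true) {
  if (length(predicted) != length(true))
    stop("predicted and true must have equal length")
  if (length(predicted) < 2) stop("at least 2 observations are required")
  lp <- sort(unique(predicted))
  lt <- sort(unique(true))
  tab <- table(factor(predicted, levels = lp), factor(true, levels = lt))
  nr <- nrow(tab)
  nc <- ncol(tab)
  C <- 0
  D <- 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      nij <- tab[i, j]
      if (nij == 0) next
      if (i < nr && j < nc)
        C <- C + nij * sum(tab[(i + 1):nr, (j + 1):nc])
      if (i < nr && j > 1)
        D <- D + nij * sum(tab[(i + 1):nr, 1:(j - 1)])
    }
  }
  if (C + D == 0) {
    warning("Gamma undefined: no untied pairs")
    return(NaN)
  }
  (C - D) / (C + D)
}

# stratified fold assignment: within each category, subjects are shuffled
# and dealt round-robin (rotating the starting fold per stratum), keeping
# every fold's category proportions within one observation of the global
# proportions
.stratified_folds <- function(categories, folds, seed) {
  set.seed(seed)
  fold <- integer(length(categories))
  offset <- 0L
  for (cc in sort(unique(categories))) {
    idx <- which(categories == cc)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% folds) + 1L
    offset <- offset + length(idx)
  }
  fold
}

# fit the measure model on train, predict categories on test; at most
# n/4 profile predictors enter (the densest first), keeping the design
# comfortably below the coefficient budget
.fit_predict <- function(train_df, test_df, profile_cols, k_covariate,
                         k_profile) {
  smooth <- c("bmi", "age", "height")
  max_cols <- max(0L, floor(nrow(train_df) / 4))
  if (length(profile_cols) > max_cols)
    profile_cols <- profile_cols[seq_len(max_cols)]
  w <- class_weights(train_df$category)
  ks <- c(stats::setNames(rep(k_covariate, length(smooth)), smooth),
          stats::setNames(rep(k_profile, length(profile_cols)),
                          profile_cols))
  fit <- tryCatch(
    fit_ordinal_gam(train_df, "category",
                    smooth = c(smooth, profile_cols),
                    factors = c("sex", "oa_subcohort"),
                    weights = w, k = ks),
    error = function(e) stop("model fit failed: ", conditionMessage(e)))
  predict_category(fit, test_df)$category
}

# profiles for all subjects under a grid built from training segments only;
# retained columns are ordered by descending training support so that
# downstream coefficient-budget truncation keeps the best-estimated classes
.profile_frame <- function(cohort, train_subjects, width, min_nonzero) {
  tr_segs <- cohort$segments[cohort$segments$subject_id %in% train_subjects,
                             , drop = FALSE]
  if (nrow(tr_segs) == 0) stop("no training segments for grid construction")
  grid <- build_grid(tr_segs, width)
  prof <- function_profiles(cohort$segments, cohort$days, grid)
  tr <- prof[prof$subject_id %in% train_subjects, , drop = FALSE]
  nz <- colSums(tr[, grid$labels, drop = FALSE] > 0)
  mins <- colSums(tr[, grid$labels, drop = FALSE])
  keep <- grid$labels[nz >= min_nonzero]
  keep <- keep[order(-nz[keep], -mins[keep], keep)]
  list(grid = grid, profiles = prof, keep = keep)
}

#' Tune the pattern-class interval width by repeated cross-validation
#'
#' For each candidate width, runs repeated stratified 5-fold
#' cross-validation: within every fold, the grid, the function profiles'
#' retained columns, the quartile cutoffs and the model are derived from the
#' fold-training subjects only, and the fold-test Gamma is recorded. The
#' width maximizing the mean Gamma is selected (ties go to the smaller
#' width). Folds whose predictions or truths have no untied pairs yield a
#' flagged `NaN` Gamma and are excluded from the mean.
#'
#' @param cohort An [build_cohort()] object.
#' @param measure One of `"walk400"`, `"walk20"`, `"sitstand"` (or the
#'   corresponding column names).
#' @param widths Candidate interval widths (counts/min).
#' @param folds Number of folds.
#' @param repeats Number of repetitions of the fold assignment.
#' @param seed Integer seed; fold assignments derive deterministically from
#'   it.
#' @param min_nonzero Minimum nonzero training subjects for a profile column
#'   to enter the model.
#' @param k_covariate,k_profile Basis dimensions for covariate and profile
#'   smooths.
#' @return A list with `selected_width`, `curve` (data frame of width, mean
#'   Gamma and number of usable folds) and the full `gammas` matrix.
#' @export
cv_tune_width <- function(cohort, measure,
                          widths = c(175, 350, 700, 1050, 1400),
                          folds = 5, repeats = 10, seed = 1,
                          min_nonzero = 10, k_covariate = 10,
                          k_profile = 5) {
  if (length(widths) < 2) stop("at least 2 candidate widths are required")
  widths <- as.numeric(widths)
  ord <- order(widths)
  df <- .eval_frame(cohort, measure)
  strat <- quartile_categorize(df$value)
  gam_mat <- matrix(NA_real_, nrow = length(widths),
                    ncol = folds * repeats,
                    dimnames = list(paste0("w", widths), NULL))
  for (r in seq_len(repeats)) {
    fold <- .stratified_folds(strat, folds, seed * 1000 + r)
    for (f in seq_len(folds)) {
      tr <- df[fold != f, , drop = FALSE]
      te <- df[fold == f, , drop = FALSE]
      tr$category <- as.integer(quartile_categorize(tr$value))
      te$category <- as.integer(quartile_categorize(tr$value, te$value))
      if (length(unique(tr$category)) < 2) next
      for (wi in seq_along(widths)) {
        pf <- .profile_frame(cohort, tr$subject_id, widths[wi], min_nonzero)
        trm <- merge(tr, pf$profiles[, c("subject_id", pf$keep),
                                     drop = FALSE], by = "subject_id")
        tem <- merge(te, pf$profiles[, c("subject_id", pf$keep),
                                     drop = FALSE], by = "subject_id")
        # a numerically infeasible fold-width fit is flagged and excluded
        # from the mean, like an undefined Gamma
        g <- tryCatch({
          pred <- .fit_predict(trm, tem, pf$keep, k_covariate, k_profile)
          suppressWarnings(goodman_kruskal_gamma(pred, tem$category))
        }, error = function(e) {
          warning("fold ", f, ", width ", widths[wi], ": ",
                  conditionMessage(e), call. = FALSE)
          NaN
        })
        gam_mat[wi, (r - 1) * folds + f] <- g
      }
    }
  }
  mean_g <- apply(gam_mat, 1, function(z) mean(z[is.finite(z)]))
  n_used <- apply(gam_mat, 1, function(z) sum(is.finite(z)))
  # argmax with ties to the smaller width
  m_ord <- mean_g[ord]
  sel <- widths[ord][which.max(round(m_ord, 12))]
  list(selected_width = sel,
       curve = data.frame(width = widths[ord], mean_gamma = m_ord,
                          n_folds_used = n_used[ord]),
       gammas = gam_mat, seed = seed)
}

#' Held-out with/without-profile evaluation
#'
#' Stratified 80/20 split of the cohort; quartile cutoffs, the pattern-class
#' grid extents and both model fits are derived from the training partition
#' only. Two models are fit — the full composite descriptor (BMI, age, sex,
#' height, OA subcohort and the function profile) and a covariates-only
#' baseline — and both held-out Gammas are reported with their difference.
#'
#' @inheritParams cv_tune_width
#' @param width Pattern-class interval width (counts/min).
#' @param split Training fraction.
#' @return An object of class `"evaluation_report"`: measure, width, the
#'   two Gammas, their difference, partition sizes, training cutoffs and
#'   grid extents.
#' @export
holdout_evaluate <- function(cohort, measure, width, split = 0.8, seed = 1,
                             min_nonzero = 10, k_covariate = 10,
                             k_profile = 5) {
  df <- .eval_frame(cohort, measure)
  strat <- quartile_categorize(df$value)
  set.seed(seed)
  test_idx <- logical(nrow(df))
  for (cc in sort(unique(strat))) {
    idx <- which(strat == cc)
    idx <- idx[sample.int(length(idx))]
    n_te <- max(1L, round((1 - split) * length(idx)))
    test_idx[idx[seq_len(n_te)]] <- TRUE
  }
  tr <- df[!test_idx, , drop = FALSE]
  te <- df[test_idx, , drop = FALSE]
  tr$category <- as.integer(quartile_categorize(tr$value))
  cuts <- quartile_categorize(tr$value)
  te$category <- as.integer(quartile_categorize(tr$value, te$value))
  if (length(unique(te$category)) < 3)
    warning("held-out partition is missing a category; ",
            "Gamma uses the available pairs")
  pf <- .profile_frame(cohort, tr$subject_id, width, min_nonzero)
  trm <- merge(tr, pf$profiles[, c("subject_id", pf$keep), drop = FALSE],
               by = "subject_id")
  tem <- merge(te, pf$profiles[, c("subject_id", pf$keep), drop = FALSE],
               by = "subject_id")
  pred_with <- .fit_predict(trm, tem, pf$keep, k_covariate, k_profile)
  pred_without <- .fit_predict(trm, tem, character(0), k_covariate,
                               k_profile)
  g_with <- suppressWarnings(goodman_kruskal_gamma(pred_with, tem$category))
  g_without <- suppressWarnings(goodman_kruskal_gamma(pred_without,
                                                      tem$category))
  structure(list(measure = .measure_column(measure), width = width,
                 gamma_with_profile = g_with,
                 gamma_without_profile = g_without,
                 delta = g_with - g_without,
                 n_train = nrow(trm), n_test = nrow(tem),
                 n_profile_classes = length(pf$keep),
                 cutoffs = c(Q1 = attr(cuts, "Q1"), Q3 = attr(cuts, "Q3")),
                 grid_extents = c(M = pf$grid$M, S = pf$grid$S),
                 seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("Held-out evaluation (%s, width %g):\n",
                     "  Gamma with profile    %.3f\n",
                     "  Gamma without profile %.3f\n",
                     "  improvement           %+.3f\n",
                     "  (n_train = %d, n_test = %d, %d profile classes)\n"),
              x$measure, x$width, x$gamma_with_profile,
              x$gamma_without_profile, x$delta, x$n_train, x$n_test,
              x$n_profile_classes))
  invisible(x)
}
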