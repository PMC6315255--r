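test_that("quartile categorization follows training type-7 quantiles", {
  train <- 1:8  # Q1 = 2.75, Q3 = 6.25
  expect_equal(as.integer(quartile_categorize(train, c(2, 5, 7))),
               c(1L, 2L, 3L))
  cuts <- quartile_categorize(train)
  expect_equal(attr(cuts, "Q1"), 2.75)
  expect_equal(attr(cuts, "Q3"), 6.25)

  # a value exactly at Q1 goes to the interquartile category
  train9 <- 1:9  # Q1 = 3 exactly
  expect_equal(as.integer(quartile_categorize(train9, 3)), 2L)

  # degenerate training distribution
  same <- rep(5, 8)
  expect_equal(as.integer(quartile_categorize(same, c(4, 5, 6))),
               c(1L, 2L, 3L))

  expect_error(quartile_categorize(1:3), "at least 4")
  # cutoffs never come from the new values
  expect_equal(as.integer(quartile_categorize(train, c(100, 200, 300))),
               c(3L, 3L, 3L))
})

test_that("Gamma matches hand-enumerated pair counts", {
  expect_equal(goodman_kruskal_gamma(c(1, 2, 3, 2, 1), c(1, 2, 3, 2, 1)), 1)
  # reversing the category order negates Gamma
  expect_equal(goodman_kruskal_gamma(4 - c(1, 2, 3, 2, 1),
                                     c(1, 2, 3, 2, 1)), -1)
  # C = 3, D = 1 over the 6 pairs (two tied pairs excluded)
  expect_equal(goodman_kruskal_gamma(c(1, 2, 3, 2), c(1, 3, 2, 2)), 0.5)
  expect_warning(g <- goodman_kruskal_gamma(rep(2, 5), c(1, 2, 3, 2, 1)),
                 "undefined")
  expect_true(is.nan(g))
  expect_error(goodman_kruskal_gamma(1:3, 1:4), "equal length")
})

test_that("Gamma agrees with exhaustive enumeration and is symmetric", {
  set.seed(202)
  for (i in 1:40) {
    n <- sample(2:30, 1)
    p <- sample(1:4, n, replace = TRUE)
    t <- sample(1:4, n, replace = TRUE)
    g1 <- suppressWarnings(goodman_kruskal_gamma(p, t))
    g2 <- oracle_gamma(p, t)
    expect_identical(is.nan(g1), is.nan(g2))
    if (!is.nan(g1)) {
      expect_equal(g1, g2)
      expect_equal(suppressWarnings(goodman_kruskal_gamma(t, p)), g1)
      expect_equal(suppressWarnings(goodman_kruskal_gamma(5 - p, t)), -g1)
      expect_gte(g1, -1)
      expect_lte(g1, 1)
    }
  }
})

test_that("stratified folds keep category proportions within one observation", {
  set.seed(203)
  cats <- rep(c(1, 2, 3), c(23, 41, 17))
  fold <- funcprofile:::.stratified_folds(cats, 5, seed = 9)
  for (cc in 1:3) {
    per_fold <- table(factor(fold[cats == cc], levels = 1:5))
    expect_lte(diff(range(per_fold)), 1)
  }
})

test_that("width tuning is deterministic with ties going to the smaller width", {
  cohort <- shared_cohort()
  tune1 <- suppressWarnings(
    cv_tune_width(cohort, "walk400", widths = c(700, 700), folds = 4,
                  repeats = 1, seed = 5, min_nonzero = 5))
  # identical candidates give identical curves; the tie rule returns the
  # first (smallest) width
  expect_equal(tune1$curve$mean_gamma[1], tune1$curve$mean_gamma[2])
  expect_equal(tune1$selected_width, 700)

  tune2 <- suppressWarnings(
    cv_tune_width(cohort, "walk400", widths = c(700, 700), folds = 4,
                  repeats = 1, seed = 5, min_nonzero = 5))
  expect_identical(tune1$gammas, tune2$gammas)

  # the first repeat's folds are unchanged when more repeats are added
  tune3 <- suppressWarnings(
    cv_tune_width(cohort, "walk400", widths = c(700, 700), folds = 4,
                  repeats = 2, seed = 5, min_nonzero = 5))
  expect_equal(tune3$gammas[, 1:4], tune1$gammas[, 1:4])
})

test_that("held-out evaluation is deterministic and leak-free", {
  cohort <- shared_cohort()
  r1 <- suppressWarnings(holdout_evaluate(cohort, "walk400", 700, seed = 3,
                                          min_nonzero = 5))
  r2 <- suppressWarnings(holdout_evaluate(cohort, "walk400", 700, seed = 3,
                                          min_nonzero = 5))
  expect_identical(r1[c("gamma_with_profile", "gamma_without_profile",
                        "delta", "cutoffs", "grid_extents")],
                   r2[c("gamma_with_profile", "gamma_without_profile",
                        "delta", "cutoffs", "grid_extents")])
  expect_true(abs(r1$gamma_with_profile) <= 1)
  expect_true(abs(r1$gamma_without_profile) <= 1)

  # grid extents derive from training segments only: excluding the subject
  # carrying the maximum segment mean shrinks M, and the excluded subject
  # still receives a (clipped) profile
  segs <- cohort$segments
  top_subj <- segs$subject_id[which.max(segs$mean)]
  train <- setdiff(unique(segs$subject_id), top_subj)
  pf <- funcprofile:::.profile_frame(cohort, train, 700, min_nonzero = 5)
  expect_lt(pf$grid$M, max(segs$mean))
  expect_true(top_subj %in% pf$profiles$subject_id)
})
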