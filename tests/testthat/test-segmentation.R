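test_that("energy divergence matches hand-enumerated values", {
  # identical degenerate distributions
  expect_equal(energy_divergence(rep(5, 3), rep(5, 3)), 0)
  # all cross pairs |0 - 10| = 10, no within spread:
  # (16/8) * (2*10 - 0 - 0) = 40
  expect_equal(energy_divergence(rep(0, 4), rep(10, 4), alpha = 1), 40)
  expect_error(energy_divergence(numeric(0), 1:3), "nonempty")
  expect_error(energy_divergence(1:3, 1:3, alpha = 3), "alpha")
})

test_that("energy divergence is symmetric on random input", {
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(sample(3:25, 1))
    y <- rnorm(sample(3:25, 1), mean = runif(1, -2, 2))
    a <- runif(1, 0.3, 2)
    expect_equal(energy_divergence(x, y, a), energy_divergence(y, x, a))
  }
  # well-separated samples give a clearly positive divergence
  expect_gt(energy_divergence(rnorm(20), rnorm(20, 10), 1), 0)
})

test_that("segment summaries use the sample SD with n - 1", {
  expect_equal(summarize_segment(c(10, 10, 10), 0, 3),
               c(mean = 10, sd = 0, duration = 3))
  expect_equal(summarize_segment(c(0, 600), 0, 2),
               c(mean = 300, sd = 600 / sqrt(2), duration = 2))
  expect_equal(summarize_segment(42, 0, 1),
               c(mean = 42, sd = 0, duration = 1))
  expect_error(summarize_segment(1:5, 2, 2), "empty")
})

test_that("a homogeneous bout stays one segment", {
  seg <- segment_bout(rep(500, 200), seg_config(seed = 3))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$mean, 500)
  expect_equal(seg$sd, 0)
  expect_equal(seg$duration, 200)
})

test_that("a clear two-regime bout splits once at the true boundary", {
  set.seed(11)
  x <- c(pmax(0, round(rnorm(120, 200, 30))),
         pmax(0, round(rnorm(120, 2000, 300))))
  seg <- segment_bout(x, seg_config(seed = 5))
  expect_equal(nrow(seg), 2)
  expect_lte(abs(seg$end[1] - 120), 3)
  expect_equal(seg$start, c(0, seg$end[1]))
  expect_equal(sum(seg$duration), 240)
})

test_that("the first accepted split equals the brute-force divergence argmax", {
  set.seed(21)
  for (i in 1:5) {
    brk <- sample(40:80, 1)
    x <- c(rnorm(brk, 100, 10), rnorm(120 - brk, 1000, 50))
    seg <- segment_bout(x, seg_config(seed = i))
    oracle <- oracle_best_split(x, min_size = 5L)
    # with a single true change the first split is the only boundary
    expect_equal(nrow(seg), 2)
    expect_equal(seg$end[1], oracle$tau)
  }
})

test_that("segmentation is deterministic and tiles the bout", {
  set.seed(41)
  for (i in 1:5) {
    x <- pmax(0, round(rnorm(300, rep(sample(c(100, 900, 2500), 3),
                                      each = 100), 150)))
    a <- segment_bout(x, seg_config(seed = 99), offset = 37L)
    b <- segment_bout(x, seg_config(seed = 99), offset = 37L)
    expect_identical(a, b)
    expect_equal(a$start[1], 37)
    expect_equal(a$end[nrow(a)], 37 + 300)
    expect_true(all(diff(a$start) > 0))
    expect_equal(a$start[-1], a$end[-nrow(a)])      # exact tiling
    expect_equal(sum(a$duration), 300)
    expect_true(all(a$duration >= 5))
  }
})

test_that("lowering the significance level never adds segments", {
  set.seed(51)
  for (i in 1:4) {
    x <- pmax(0, round(rnorm(250, 500, 50))) +
      rep(c(0, sample(c(0, 150, 400), 1)), c(125, 125))
    n_strict <- nrow(segment_bout(x, seg_config(significance_level = 0.01,
                                                seed = 7)))
    n_loose <- nrow(segment_bout(x, seg_config(significance_level = 0.05,
                                               seed = 7)))
    expect_lte(n_strict, n_loose)
  }
})

test_that("bouts shorter than twice the minimum size stay whole", {
  x <- c(rep(0, 4), rep(4000, 5))
  seg <- segment_bout(x, seg_config(min_size = 5, seed = 1))
  expect_equal(nrow(seg), 1)
})

test_that("segmentation configs are validated", {
  expect_error(seg_config(min_size = 1), "min_size")
  expect_error(seg_config(n_permutations = 5), "n_permutations")
  expect_error(seg_config(significance_level = 0), "significance_level")
  expect_error(seg_config(significance_level = 1), "significance_level")
})

test_that("cohort segmentation keeps only valid days and conserves wear", {
  cohort <- shared_cohort()
  days <- cohort$days
  segs <- cohort$segments
  expect_true(all(segs$subject_id %in% days$subject_id[days$valid]))
  # per valid day, segment durations sum to the day's wear minutes
  key <- paste(segs$subject_id, segs$day)
  per_day <- tapply(segs$duration, key, sum)
  vd <- days[days$valid, ]
  vkey <- paste(vd$subject_id, vd$day)
  expect_equal(as.numeric(per_day[vkey]), vd$wear_minutes)
})
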