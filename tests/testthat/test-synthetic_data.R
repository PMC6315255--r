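test_that("cohort simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_subjects = 4, days = 2, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$epochs, b$epochs)
  expect_identical(a$capacity, b$capacity)
  expect_identical(a$truth, b$truth)
})

test_that("a degenerate configuration reproduces its inputs exactly", {
  cfg <- sim_config(n_subjects = 1, days = 1, seed = 2,
                    class_means = 500, class_sds = 0, base_weights = 0,
                    beta_profile = 0, wear_hours = c(10, 10),
                    nonwear_blocks = 0)
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$epochs), 600)
  expect_true(all(sim$epochs$count == 500))
})

test_that("generated files pass the I/O validators round-trip", {
  dir <- file.path(tempdir(), "simout")
  sim <- simulate_cohort(sim_config(n_subjects = 4, days = 2, seed = 3),
                         outdir = dir)
  ep <- read_epochs(file.path(dir, "epochs.csv"))
  expect_identical(ep, sim$epochs[order(sim$epochs$subject_id,
                                        sim$epochs$date,
                                        sim$epochs$minute), ])
  cv <- read_covariates(file.path(dir, "covariates.csv"))
  expect_equal(cv$subject_id, sim$covariates$subject_id)
  cp <- read_capacity(file.path(dir, "capacity.csv"))
  expect_equal(cp$walk400_time, sim$capacity$walk400_time)
  expect_true(all(ep$count >= 0 & ep$count <= 9000))
})

test_that("higher latent scores shift dwell time toward intense classes", {
  cfg <- sim_config(n_subjects = 2, days = 1, seed = 1)
  set.seed(55)
  top <- length(cfg$class_means)
  hi <- lo <- 0
  for (d in 1:100) {
    hi <- hi + simulate_subject_day(2, cfg)$class_minutes[top]
    lo <- lo + simulate_subject_day(-2, cfg)$class_minutes[top]
  }
  expect_gt(hi, lo)
})

test_that("dwell proportions converge to the softmax model", {
  cfg <- sim_config(seed = 1)
  probs <- funcprofile:::.dwell_probs(0.7, cfg)
  set.seed(77)
  mins <- numeric(length(probs))
  for (d in 1:200) mins <- mins + simulate_subject_day(0.7, cfg)$class_minutes
  expect_lt(max(abs(mins / sum(mins) - probs)), 0.02)
})

test_that("noiseless capacity is a monotone function of the latent score", {
  cfg <- sim_config(seed = 1, capacity_noise = c(walk400 = 0, walk20 = 0,
                                                 sitstand = 0))
  set.seed(3)
  phi <- rnorm(50)
  cap <- simulate_capacity(phi, cfg)
  expect_true(all(diff(cap$walk400_time[order(phi)]) <= 0))
  expect_true(all(diff(cap$walk20_pace[order(phi)]) >= 0))
  expect_equal(order(cap$walk20_pace), order(cap$sitstand_rate))
  expect_equal(order(cap$walk20_pace), order(-cap$walk400_time))
  expect_true(all(unlist(cap[-1]) > 0))
})

test_that("inserted nonwear blocks are recovered exactly when counts stay high", {
  cfg <- sim_config(n_subjects = 1, days = 1, seed = 4,
                    class_means = c(500, 1500), class_sds = c(50, 100),
                    base_weights = c(0, 0))
  set.seed(21)
  for (i in 1:10) {
    day <- simulate_subject_day(0, cfg)
    mask <- detect_nonwear(day$count, day$minute)
    expect_identical(mask, day$wear_truth)
  }
})

test_that("adversarial sub-100 interruptions stay inside nonwear periods", {
  cfg <- sim_config(preset = "adversarial", n_subjects = 1, days = 1,
                    seed = 4, class_means = c(500, 1500),
                    class_sds = c(50, 100), base_weights = c(0, 0))
  set.seed(22)
  hit <- FALSE
  for (i in 1:10) {
    day <- simulate_subject_day(0, cfg)
    mask <- detect_nonwear(day$count, day$minute)
    expect_identical(mask, day$wear_truth)
    hit <- hit || any(day$count[!day$wear_truth] > 0)
  }
  expect_true(hit)  # the preset really does plant interruptions
})

test_that("the covariate generator echoes the target cohort descriptives", {
  sim <- simulate_cohort(sim_config(n_subjects = 2001, days = 0, seed = 8))
  expect_lt(abs(mean(sim$covariates$bmi) - 28.52), 0.5)
  expect_lt(abs(mean(sim$covariates$sex == "M") - 0.445), 0.05)
  expect_gt(mean(sim$covariates$oa_subcohort == "incidence"), 0.65)
})

test_that("with no activity effect the capacity category is independent of dwell", {
  rejected <- 0
  for (s in 1:20) {
    sim <- simulate_cohort(sim_config(preset = "null", n_subjects = 100,
                                      days = 2, seed = 300 + s))
    top <- sim$truth$observed_minutes_6 + sim$truth$observed_minutes_5
    dwell_band <- cut(rank(top, ties.method = "first"), 3)
    p <- suppressWarnings(
      stats::chisq.test(table(dwell_band,
                              sim$truth$category_walk400))$p.value)
    if (p < 0.01) rejected <- rejected + 1
  }
  expect_lte(rejected, 1)
})
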