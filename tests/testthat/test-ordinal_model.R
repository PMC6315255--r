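test_that("class weights invert prevalence with mean one", {
  expect_equal(class_weights(c(1, 2, 2, 3)), c(4/3, 2/3, 2/3, 4/3))
  expect_equal(class_weights(c(1, 2, 3)), rep(1, 3))
  # quartile design (n, 2n, n): outer quartiles upweighted 4/3, the
  # interquartile class downweighted 2/3, mean weight one
  cats <- rep(c(1, 2, 3), c(25, 50, 25))
  w <- class_weights(cats)
  expect_equal(unique(w[cats == 1]), 4/3)
  expect_equal(unique(w[cats == 2]), 2/3)
  expect_equal(unique(w[cats == 3]), 4/3)
  expect_equal(mean(w), 1)
  # unobserved categories do not enter C
  expect_equal(class_weights(c(1, 1, 3)), c(0.75, 0.75, 1.5))
})

test_that("a linear fit coincides with the brute-force cumulative-logit MLE", {
  set.seed(101)
  n <- 200
  x1 <- rnorm(n)
  x2 <- runif(n, -1, 1)
  y <- draw_polr(1.2 * x1 - 0.7 * x2, t1 = -0.8, t2 = 0.9)
  dat <- data.frame(y = y, x1 = x1, x2 = x2)
  w <- class_weights(y)
  fit <- fit_ordinal_gam(dat, "y", linear = c("x1", "x2"), weights = w)
  oracle <- oracle_fit_polr(cbind(x1, x2), y, w)
  co <- coef(fit$gam)
  expect_lt(abs(co[["x1"]] - oracle$beta[1]), 1e-3)
  expect_lt(abs(co[["x2"]] - oracle$beta[2]), 1e-3)
  # thresholds on the oracle's scale: theta_c - alpha
  alpha <- co[["(Intercept)"]]
  expect_lt(abs((fit$theta[1] - alpha) - oracle$t1), 1e-3)
  expect_lt(abs((fit$theta[2] - alpha) - oracle$t2), 1e-3)
})

test_that("the true slope and thresholds are recovered from simulated data", {
  set.seed(102)
  n <- 500
  x <- rnorm(n)
  y <- draw_polr(1.5 * x, t1 = -1, t2 = 1)
  dat <- data.frame(y = y, x = x)
  fit <- fit_ordinal_gam(dat, "y", linear = "x",
                         weights = class_weights(y))
  co <- coef(fit$gam)
  expect_lt(abs(co[["x"]] - 1.5), 0.25)
  expect_lt(abs((fit$theta[1] - co[["(Intercept)"]]) - (-1)), 0.3)
  expect_lt(abs((fit$theta[2] - co[["(Intercept)"]]) - 1), 0.3)
})

test_that("null predictors shrink to near-linear smooths with no concordance", {
  set.seed(103)
  n <- 500
  dat <- data.frame(y = sample(1:3, n, replace = TRUE),
                    a = rnorm(n), b = runif(n), d = rexp(n))
  fit <- fit_ordinal_gam(dat, "y", smooth = c("a", "b", "d"),
                         weights = class_weights(dat$y))
  edfs <- summary(fit$gam)$s.table[, "edf"]
  expect_true(all(edfs <= 1.2))
  pred <- predict_category(fit, dat)
  g <- suppressWarnings(goodman_kruskal_gamma(pred$category, dat$y))
  expect_true(is.nan(g) || abs(g) <= 0.15)
})

test_that("a noiseless monotone relation yields perfect held-in concordance", {
  set.seed(104)
  n <- 300
  x <- sort(runif(n))
  y <- as.integer(cut(x, breaks = c(-Inf, 0.25, 0.75, Inf)))
  dat <- data.frame(y = y, x = x)
  fit <- suppressWarnings(fit_ordinal_gam(dat, "y", smooth = "x",
                                          weights = class_weights(y)))
  pred <- predict_category(fit, dat)
  expect_equal(goodman_kruskal_gamma(pred$category, y), 1)
})

test_that("predicted probabilities form a simplex ordered by the latent scale", {
  set.seed(105)
  n <- 250
  x <- rnorm(n)
  y <- draw_polr(1.3 * x, -1, 1)
  dat <- data.frame(y = y, x = x)
  fit <- fit_ordinal_gam(dat, "y", smooth = "x",
                         weights = class_weights(y))
  nd <- data.frame(x = seq(-4, 4, length.out = 101))
  pr <- predict_category(fit, nd)
  expect_true(all(pr$p1 >= 0 & pr$p2 >= -1e-12 & pr$p3 >= 0))
  expect_equal(pr$p1 + pr$p2 + pr$p3, rep(1, 101))
  # agreement with the fitting engine's own response-scale probabilities
  # (discrete = FALSE: the discretized prediction path needs mgcv attached)
  pm <- predict(fit$gam, newdata = nd, type = "response", discrete = FALSE)
  expect_equal(unname(as.matrix(pr[, c("p1", "p2", "p3")])),
               unname(as.matrix(pm)), tolerance = 1e-8)
  # P(Y <= c) nonincreasing in eta; extremes pin the outer categories
  ord <- order(pr$eta)
  expect_true(all(diff((pr$p1)[ord]) <= 1e-12))
  expect_true(all(diff((pr$p1 + pr$p2)[ord]) <= 1e-12))
  lo <- which.min(pr$eta)
  hi <- which.max(pr$eta)
  expect_equal(pr$category[lo], 1)
  expect_equal(pr$category[hi], 3)
  expect_gt(pr$p1[lo], 0.95)
})

test_that("duplicating class-2 rows at half weight leaves the fit unchanged", {
  set.seed(106)
  n <- 150
  x <- rnorm(n)
  y <- draw_polr(x, -1, 1)
  dat <- data.frame(y = y, x = x)
  w <- class_weights(y)
  fit1 <- fit_ordinal_gam(dat, "y", linear = "x", weights = w)
  is2 <- dat$y == 2
  dat2 <- rbind(dat, dat[is2, ])
  w2 <- c(ifelse(is2, w / 2, w), w[is2] / 2)
  fit2 <- fit_ordinal_gam(dat2, "y", linear = "x", weights = w2)
  expect_lt(max(abs(coef(fit1$gam) - coef(fit2$gam))), 1e-4)
})

test_that("partial effects cover flat truth and widen when extrapolating", {
  set.seed(107)
  n <- 400
  dat <- data.frame(y = sample(1:3, n, replace = TRUE, prob = c(1, 2, 1)),
                    x = rnorm(n), z = rnorm(n))
  fit <- fit_ordinal_gam(dat, "y", smooth = c("x", "z"),
                         weights = class_weights(dat$y))
  pe <- partial_effects(fit, "x")
  expect_false(any(pe$extrapolated))
  expect_gte(mean(pe$lower <= 0 & pe$upper >= 0), 0.9)

  wide <- partial_effects(fit, "x", range = c(min(dat$x), max(dat$x) + 4))
  out <- wide[wide$extrapolated, ]
  expect_gt(nrow(out), 0)
  expect_true(all(diff(out$se) >= -1e-9))
  expect_gt(out$se[nrow(out)], max(pe$se))
  expect_error(partial_effects(fit, "nope"), "unknown")
})

test_that("a linear-truth smooth stays within its own band", {
  set.seed(108)
  n <- 400
  x <- rnorm(n)
  y <- draw_polr(1.5 * x, -1, 1)
  dat <- data.frame(y = y, x = x)
  fit <- fit_ordinal_gam(dat, "y", smooth = "x",
                         weights = class_weights(y))
  pe <- partial_effects(fit, "x")
  slope <- 1.5
  truth <- slope * (pe$x - mean(x))
  truth <- truth - mean(truth) + mean(pe$estimate)  # both centered
  expect_gte(mean(pe$lower <= truth & truth <= pe$upper), 0.9)
})

test_that("degenerate model requests fail loudly", {
  dat <- data.frame(y = rep(2L, 20), x = rnorm(20))
  expect_error(fit_ordinal_gam(dat, "y", smooth = "x"), "single")
  dat$y <- rep(c(1L, 2L), 10)
  small <- dat[1:6, ]
  expect_error(fit_ordinal_gam(small, "y",
                               smooth = paste0("x", 1:10)), "missing")
  fit <- fit_ordinal_gam(dat, "y", smooth = "x")
  expect_error(predict_category(fit, data.frame(z = 1)), "missing predictor")
})
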