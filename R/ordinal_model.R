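#' Inverse-prevalence observation weights
#'
#' Weights each observation by the inverse prevalence of its ordinal
#' category: `w_i = N / (C * n_c(i))`, where `C` is the number of observed
#' categories. The mean weight is 1, and the quartile design (n, 2n, n)
#' receives the (4/3, 2/3, 4/3) pattern that rebalances the interquartile
#' class against the outer quartiles.
#'
#' @param categories Vector of ordinal categories (values in 1..3).
#' @return Numeric weight vector aligned to `categories`.
#' @examples
#' class_weights(c(1, 2, 2, 3))  # 4/3 2/3 2/3 4/3
#' @export
class_weights <- function(categories) {
  if (length(categories) == 0) stop("at least one observation is required")
  tab <- table(categories)
  C <- length(tab)
  N <- length(categories)
  as.numeric(N / (C * tab[as.character(categories)]))
}

#' Fit a weighted ordered-categorical additive model
#'
#' Fits the cumulative-logit (proportional-odds) additive model
#' \deqn{P(Y \le c \mid X) = \mathrm{logit}^{-1}(\theta_c - \eta(X)), \quad
#'   \eta = \alpha + \sum_p f_p(X_p)}
#' with three ordered response categories, penalized cubic regression
#' spline smooths for continuous predictors and unpenalized level offsets
#' for factors, via `mgcv::gam(family = ocat(R = 3))` with smoothing
#' parameters chosen by REML. Smooths are centered (the intercept is
#' absorbed into the latent scale along with the estimated thresholds).
#'
#' Basis dimensions adapt to the data: each smooth's `k` is capped by the
#' number of unique predictor values, predictors with fewer than 4 unique
#' values enter linearly, and all `k`s are reduced (floor 3) if the total
#' coefficient count would otherwise reach the sample size.
#'
#' @param data Data frame holding response and predictors.
#' @param response Name of the response column (integer categories 1 < 2 < 3;
#'   at least two categories must be observed).
#' @param smooth Character vector of continuous predictors to model with
#'   penalized smooths.
#' @param linear Character vector of predictors entering linearly.
#' @param factors Character vector of categorical predictors (level
#'   offsets).
#' @param weights Optional observation weights (see [class_weights()]).
#' @param k Basis dimension per smooth before adaptation; a single number
#'   or a named per-term vector.
#' @param method Smoothing-selection criterion passed to `mgcv::gam`. Fits
#'   without smooth terms use plain maximum likelihood, which is the exact
#'   weighted cumulative-logit MLE.
#' @param select Apply the double-penalty shrinkage that lets whole smooth
#'   terms be penalized away (recommended with many candidate profile
#'   predictors).
#' @param gamma Inflation of the effective degrees-of-freedom cost in
#'   smoothing selection; the conventional 1.4 guards against occasional
#'   undersmoothing of noise predictors.
#' @return An object of class `"ordinal_gam"`: list with the underlying
#'   `gam` fit, estimated latent thresholds `theta` (increasing), and the
#'   term bookkeeping.
#' @export
fit_ordinal_gam <- function(data, response, smooth = character(),
                            linear = character(), factors = character(),
                            weights = NULL, k = 10, method = "REML",
                            select = TRUE, gamma = 1.4) {
  stopifnot(is.data.frame(data), response %in% names(data))
  y <- data[[response]]
  if (!all(y %in% 1:3)) stop("response categories must take values in 1..3")
  if (length(unique(y)) < 2)
    stop("a single observed category cannot be fit")
  n <- nrow(data)
  miss <- setdiff(c(smooth, linear, factors), names(data))
  if (length(miss)) stop("missing predictor column(s): ",
                         paste(miss, collapse = ", "))

  # adaptive basis sizes; k may be a single number or a named per-term vector
  smooth <- unique(smooth)
  kreq <- if (length(k) == 1 && is.null(names(k)))
    stats::setNames(rep(k, length(smooth)), smooth) else k
  ks <- integer(0)
  for (v in smooth) {
    nu <- length(unique(data[[v]]))
    kv <- if (v %in% names(kreq)) kreq[[v]] else 10
    if (nu < 4) linear <- c(linear, v) else ks[v] <- min(kv, nu - 1L)
  }
  smooth <- names(ks)
  factors <- factors[vapply(factors, function(v)
    length(unique(data[[v]])) >= 2, TRUE)]
  nfac <- sum(vapply(factors, function(v)
    length(unique(data[[v]])) - 1L, 1L))
  # keep the total coefficient count well below n: smooths on top of a
  # near-saturated design are slow and numerically fragile
  cap <- max(20L, as.integer(floor(0.7 * n)))
  budget <- function(ks) sum(ks) + length(linear) + nfac + 3L
  while (budget(ks) > cap && length(ks) && any(ks > 3L))
    ks <- pmax(ks - 1L, 3L)  # ks first: pmax keeps the first arg's names
  # still over: degrade the trailing smooths (the sparsest profile columns
  # come last) to linear terms
  while (budget(ks) > cap && length(ks)) {
    linear <- c(linear, names(ks)[length(ks)])
    ks <- ks[-length(ks)]
  }
  smooth <- names(ks)
  if (budget(ks) >= n - 1L)
    stop("too many predictors for ", n, " observations")

  sterms <- sprintf("s(%s, bs = 'cr', k = %d)", smooth, ks)
  rhs <- c(sterms, linear, factors)
  if (length(rhs) == 0) stop("no predictors supplied")
  fml <- stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
  dat <- data
  dat$.w <- if (is.null(weights)) rep(1, n) else weights
  if (length(smooth) == 0) {
    # nothing to select; plain ML is the exact weighted cumulative-logit
    # MLE, free of REML's determinant correction
    if (method == "REML") method <- "ML"
    fit <- mgcv::gam(fml, family = mgcv::ocat(R = 3), data = dat,
                     weights = .w, method = method,
                     control = mgcv::gam.control(epsilon = 1e-9,
                                                 maxit = 400))
  } else {
    # smooth fits use bam's discretized fast-REML machinery: full-Newton
    # smoothing selection is prohibitively slow (and fragile, e.g. under
    # complete separation) for the ordered-categorical family once a model
    # carries the dozen-plus profile smooths these analyses routinely use;
    # the extended Fellner-Schall optimizer is the fallback
    fit <- tryCatch(
      mgcv::bam(fml, family = mgcv::ocat(R = 3), data = dat,
                weights = .w, discrete = TRUE,
                select = select, gamma = gamma),
      error = function(e)
        mgcv::gam(fml, family = mgcv::ocat(R = 3), data = dat,
                  weights = .w, method = method, optimizer = "efs",
                  select = select, gamma = gamma,
                  control = mgcv::gam.control(epsilon = 1e-9,
                                              maxit = 200)))
  }
  theta <- sort(fit$family$getTheta(TRUE))
  structure(list(gam = fit, theta = theta, response = response,
                 smooth = smooth, ks = ks, linear = unique(linear),
                 factors = factors, n = n),
            class = "ordinal_gam")
}

#' @export
print.ordinal_gam <- function(x, ...) {
  cat(sprintf(paste0("Ordered-categorical additive model (%d obs): %d",
                     " smooth, %d linear, %d factor term(s)\n",
                     "  latent thresholds: %.3f < %.3f\n"),
              x$n, length(x$smooth), length(x$linear), length(x$factors),
              x$theta[1], x$theta[2]))
  invisible(x)
}

#' Predict ordinal categories from a fitted model
#'
#' Evaluates the latent predictor and converts it to category probabilities
#' through the estimated thresholds: `p1 = logit^-1(theta1 - eta)`,
#' `p2 = logit^-1(theta2 - eta) - p1`, `p3 = 1 - logit^-1(theta2 - eta)`.
#' The predicted category is the probability argmax.
#'
#' @param fit An [fit_ordinal_gam()] object.
#' @param newdata Data frame with all predictors used by the fit.
#' @return Data frame with `category`, `eta`, `p1`, `p2`, `p3`.
#' @export
predict_category <- function(fit, newdata) {
  stopifnot(inherits(fit, "ordinal_gam"))
  need <- c(fit$smooth, fit$linear, fit$factors)
  miss <- setdiff(need, names(newdata))
  if (length(miss))
    stop("newdata is missing predictor(s): ", paste(miss, collapse = ", "))
  # factor levels absent from the training partition carry no estimated
  # offset; such rows are scored at the reference level
  for (f in names(fit$gam$xlevels)) {
    if (!f %in% names(newdata)) next
    v <- as.character(newdata[[f]])
    known <- fit$gam$xlevels[[f]]
    if (any(!v %in% known)) {
      warning("factor ", f, ": level(s) ",
              paste(unique(v[!v %in% known]), collapse = ", "),
              " unseen in training; scored at the reference level")
      v[!v %in% known] <- known[1]
    }
    newdata[[f]] <- factor(v, levels = known)
  }
  eta <- as.numeric(predict(fit$gam, newdata = newdata, type = "link"))
  th <- fit$theta
  p1 <- stats::plogis(th[1] - eta)
  p12 <- stats::plogis(th[2] - eta)
  p2 <- p12 - p1
  p3 <- 1 - p12
  # deterministic tie-break: ties go to the lower category
  data.frame(category = max.col(cbind(p1, p2, p3), ties.method = "first"),
             eta = eta, p1 = p1, p2 = p2, p3 = p3)
}

#' Partial-effect curve of a continuous predictor
#'
#' Evaluates a fitted centered smooth (or linear term) on a grid, with a
#' pointwise approximate 95% band (+/- 2 standard errors) from the
#' coefficient covariance. Evaluation points outside the observed training
#' range are flagged as extrapolation, where the band widens.
#'
#' @param fit An [fit_ordinal_gam()] object.
#' @param term Name of a continuous predictor in the fit.
#' @param n_points Grid resolution.
#' @param range Optional length-2 evaluation range (defaults to the observed
#'   training range).
#' @return Data frame with `x`, `estimate`, `se`, `lower`, `upper`,
#'   `extrapolated`.
#' @export
partial_effects <- function(fit, term, n_points = 100, range = NULL) {
  stopifnot(inherits(fit, "ordinal_gam"))
  if (!term %in% c(fit$smooth, fit$linear))
    stop("unknown continuous predictor: ", term)
  mf <- fit$gam$model
  obs <- mf[[term]]
  if (is.null(obs)) stop("term not found in the model frame: ", term)
  if (is.null(range)) range <- base::range(obs)
  xs <- seq(range[1], range[2], length.out = n_points)
  new <- mf[rep(1L, n_points), , drop = FALSE]
  for (v in c(fit$smooth, fit$linear))
    new[[v]] <- rep(stats::median(mf[[v]]), n_points)
  for (v in fit$factors) {
    tab <- table(mf[[v]])
    new[[v]] <- factor(rep(names(tab)[which.max(tab)], n_points),
                       levels = levels(mf[[v]]))
  }
  new[[term]] <- xs
  pr <- predict(fit$gam, newdata = new, type = "terms", se.fit = TRUE)
  cn <- colnames(pr$fit)
  hit <- cn == sprintf("s(%s)", term) | cn == term
  if (!any(hit)) stop("could not locate the term column for ", term)
  est <- pr$fit[, which(hit)[1]]
  se <- pr$se.fit[, which(hit)[1]]
  data.frame(x = xs, estimate = est, se = se,
             lower = est - 2 * se, upper = est + 2 * se,
             extrapolated = xs < min(obs) | xs > max(obs))
}
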