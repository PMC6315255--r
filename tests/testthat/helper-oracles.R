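# Independent oracles used to freeze expected values. These deliberately use
# brute-force enumeration or generic optimization, never the package's own
# computational path.

# Goodman-Kruskal Gamma by exhaustive enumeration of all unordered pairs.
oracle_gamma <- function(predicted, true) {
  n <- length(predicted)
  C <- 0L
  D <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dp <- sign(predicted[j] - predicted[i])
      dt <- sign(true[j] - true[i])
      if (dp == 0 || dt == 0) next
      if (dp == dt) C <- C + 1L else D <- D + 1L
    }
  }
  if (C + D == 0) return(NaN)
  (C - D) / (C + D)
}

# Best single split by scanning every admissible split point with the
# two-sample energy divergence.
oracle_best_split <- function(x, min_size = 5L, alpha = 1) {
  n <- length(x)
  taus <- min_size:(n - min_size)
  stats <- vapply(taus, function(tau)
    energy_divergence(x[1:tau], x[(tau + 1):n], alpha), 0)
  list(tau = taus[which.max(stats)], stat = max(stats))
}

# Weighted cumulative-logit likelihood maximized with a generic optimizer:
# P(Y <= c) = plogis(t_c - X beta), thresholds ordered via t2 = t1 + exp(d).
oracle_fit_polr <- function(X, y, w = rep(1, length(y))) {
  X <- as.matrix(X)
  nll <- function(par) {
    t1 <- par[1]
    t2 <- t1 + exp(par[2])
    beta <- par[-(1:2)]
    eta <- drop(X %*% beta)
    p <- cbind(stats::plogis(t1 - eta),
               stats::plogis(t2 - eta) - stats::plogis(t1 - eta),
               1 - stats::plogis(t2 - eta))[cbind(seq_along(y), y)]
    -sum(w * log(pmax(p, 1e-290)))
  }
  init <- c(-0.5, 0.5, rep(0, ncol(X)))
  fit <- stats::optim(init, nll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  list(t1 = fit$par[1], t2 = fit$par[1] + exp(fit$par[2]),
       beta = fit$par[-(1:2)], value = fit$value)
}

# Draw ordinal responses from a proportional-odds model.
draw_polr <- function(eta, t1, t2) {
  u <- stats::runif(length(eta))
  1L + (u > stats::plogis(t1 - eta)) + (u > stats::plogis(t2 - eta))
}
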