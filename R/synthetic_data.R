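#' Synthetic cohort configuration
#'
#' Defines the generative model for synthetic free-living activity cohorts.
#' Each subject carries a latent standard-normal function score `phi`. A
#' day is a semi-Markov sequence of activity bouts: a bout's class is drawn
#' with probability proportional to
#' `exp(base_weight + beta_profile * phi * class_score)` (class scores are
#' centered intensity ranks in \[-1, 1\]), its length is geometric with the
#' configured mean (minimum 2 minutes), and its counts are Normal(mean,
#' SD^2) draws rounded, clipped to \[0, 9000\]. All-zero nonwear blocks
#' longer than 90 minutes are inserted per day; total wear time is drawn
#' uniformly from `wear_hours`. Capacity measures are monotone in `phi`
#' with additive Gaussian noise. Covariate distributions echo a typical
#' knee-osteoarthritis accelerometer cohort (BMI mean 28.52, SD 4.87;
#' 44.5% male; subcohort mix about 74.5/25.2/0.3%).
#'
#' Presets: `"default"` (activity carries the function signal),
#' `"null"` (`beta_profile = 0`: capacity is independent of activity),
#' `"adversarial"` (nonwear blocks contain 1-2-minute sub-100-count
#' interruptions, exercising the nonwear rule), `"table1"` (defaults; used
#' for covariate-echo checks) and `"separated"` (class means spaced 800
#' counts/min apart with common SD 800, so pattern classes separate at an
#' interval width of 700).
#'
#' @param preset Scenario preset (see Details).
#' @param n_subjects Number of subjects.
#' @param days Days of observation per subject.
#' @param seed Master integer seed.
#' @param class_means,class_sds Per-class count distribution parameters
#'   (counts/min).
#' @param base_weights Per-class log dwell weights at `phi = 0`.
#' @param mean_bout_minutes Mean activity-bout duration (minutes).
#' @param beta_profile Strength of the latent-score tilt on class dwell.
#' @param wear_hours Length-2 range of daily wear time (hours).
#' @param nonwear_blocks Integer vector of possible nonwear-block counts
#'   per day.
#' @param nonwear_minutes Length-2 range of nonwear-block durations
#'   (minutes; must exceed 90 for the blocks to be recoverable).
#' @param capacity_noise Named noise SDs for `walk400` (s), `walk20` (m/s),
#'   `sitstand` (reps/s).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(preset = c("default", "null", "adversarial",
                                  "table1", "separated"),
                       n_subjects = 150, days = 7, seed = 1,
                       class_means = c(50, 400, 1100, 2000, 3150, 4500),
                       class_sds = c(30, 200, 500, 800, 350, 1000),
                       base_weights = c(2, 1, 0.2, -0.6, -1.2, -2),
                       mean_bout_minutes = 45,
                       beta_profile = 0.8,
                       wear_hours = c(10, 14),
                       nonwear_blocks = c(1, 2),
                       nonwear_minutes = c(100, 240),
                       capacity_noise = c(walk400 = 12, walk20 = 0.07,
                                          sitstand = 0.05)) {
  preset <- match.arg(preset)
  if (preset == "null") beta_profile <- 0
  if (preset == "separated") {
    # means at odd multiples of 350: centered in width-700 bins, exactly on
    # width-350 bin edges; SD 450 keeps every class in the first SD bin at
    # width 700, so the classes separate cleanly at width 700 only
    class_means <- c(1050, 1750, 2450, 3150, 3850, 4550)
    class_sds <- rep(450, 6)
  }
  stopifnot(length(class_means) == length(class_sds),
            length(base_weights) == length(class_means),
            all(class_means >= 0), all(class_sds >= 0),
            length(wear_hours) == 2, wear_hours[1] <= wear_hours[2],
            mean_bout_minutes >= 2)
  nc <- length(class_means)
  score <- if (nc > 1) (seq_len(nc) - (nc + 1) / 2) / ((nc - 1) / 2) else 0
  structure(list(preset = preset, n_subjects = n_subjects, days = days,
                 seed = seed, class_means = class_means,
                 class_sds = class_sds, base_weights = base_weights,
                 class_score = score,
                 mean_bout_minutes = mean_bout_minutes,
                 beta_profile = beta_profile, wear_hours = wear_hours,
                 nonwear_blocks = nonwear_blocks,
                 nonwear_minutes = nonwear_minutes,
                 capacity_noise = capacity_noise,
                 interruption_noise = preset == "adversarial"),
            class = "sim_config")
}

# softmax dwell probabilities for a subject with latent score phi
.dwell_probs <- function(phi, config) {
  w <- config$base_weights + config$beta_profile * phi * config$class_score
  e <- exp(w - max(w))
  e / sum(e)
}

#' Simulate one subject-day of minute counts
#'
#' Draws one day's activity trace from the semi-Markov bout model described
#' in [sim_config()]. Uses the current R RNG state; seed upstream for
#' reproducibility.
#'
#' @param phi Latent function score.
#' @param config A [sim_config()].
#' @return A list with `minute` (minute-of-day stamps), `count` (integer
#'   counts), `wear_truth` (logical: minute belongs to a wear bout, not an
#'   inserted nonwear block) and `class_minutes` (true minutes per class).
#' @export
simulate_subject_day <- function(phi, config) {
  stopifnot(inherits(config, "sim_config"))
  nc <- length(config$class_means)
  probs <- .dwell_probs(phi, config)
  wear_target <- round(stats::runif(1, config$wear_hours[1],
                                    config$wear_hours[2]) * 60)
  counts <- integer(wear_target)
  class_min <- numeric(nc)
  filled <- 0L
  while (filled < wear_target) {
    j <- sample.int(nc, 1, prob = probs)
    len <- 2L + stats::rgeom(1, 1 / max(1, config$mean_bout_minutes - 1))
    len <- min(len, wear_target - filled)
    if (len <= 0) break
    counts[(filled + 1L):(filled + len)] <- as.integer(pmin(9000, pmax(
      0, round(stats::rnorm(len, config$class_means[j],
                            config$class_sds[j])))))
    filled <- filled + len
    class_min[j] <- class_min[j] + len
  }
  n_wear <- filled
  # nonwear blocks: all-zero runs > 90 minutes
  nb <- config$nonwear_blocks[sample.int(length(config$nonwear_blocks), 1)]
  nw_len <- if (nb > 0)
    round(stats::runif(nb, config$nonwear_minutes[1],
                       config$nonwear_minutes[2])) else integer(0)
  while (n_wear + sum(nw_len) > 1440L && length(nw_len))
    nw_len <- nw_len[-length(nw_len)]
  cuts <- if (length(nw_len))
    sort(sample.int(n_wear + 1L, length(nw_len), replace = TRUE) - 1L)
  else integer(0)
  seq_counts <- integer(0)
  wear_truth <- logical(0)
  prev <- 0L
  for (b in seq_along(cuts)) {
    if (cuts[b] > prev) {
      seq_counts <- c(seq_counts, counts[(prev + 1L):cuts[b]])
      wear_truth <- c(wear_truth, rep(TRUE, cuts[b] - prev))
    }
    blk <- integer(nw_len[b])
    if (config$interruption_noise) {
      # a short sub-100-count interruption inside the block; the block
      # still satisfies the nonwear rule
      ilen <- sample.int(2L, 1)
      ipos <- sample.int(nw_len[b] - ilen - 1L, 1) + 1L
      blk[ipos:(ipos + ilen - 1L)] <- sample.int(99L, ilen, replace = TRUE)
    }
    seq_counts <- c(seq_counts, blk)
    wear_truth <- c(wear_truth, rep(FALSE, nw_len[b]))
    prev <- cuts[b]
  }
  if (prev < n_wear) {
    seq_counts <- c(seq_counts, counts[(prev + 1L):n_wear])
    wear_truth <- c(wear_truth, rep(TRUE, n_wear - prev))
  }
  total <- length(seq_counts)
  start <- sample.int(1440L - total + 1L, 1) - 1L
  list(minute = start + seq_len(total) - 1L, count = seq_counts,
       wear_truth = wear_truth, class_minutes = class_min)
}

#' Simulate capacity measures from latent function scores
#'
#' Capacity is monotone in the latent score: 400-m walk time decreases with
#' `phi` (better function, faster completion), while 20-m walk pace and
#' sit-stand rate increase, each with additive Gaussian noise and clipped
#' strictly positive. Uses the current R RNG state.
#'
#' @param phi Numeric vector of latent scores.
#' @param config A [sim_config()].
#' @return Data frame with `walk400_time` (s), `walk20_pace` (m/s),
#'   `sitstand_rate` (reps/s).
#' @export
simulate_capacity <- function(phi, config) {
  stopifnot(inherits(config, "sim_config"))
  ns <- config$capacity_noise
  n <- length(phi)
  data.frame(
    walk400_time = pmax(60, 290 - 35 * phi +
                          stats::rnorm(n, 0, ns[["walk400"]])),
    walk20_pace = pmax(0.2, 1.30 + 0.18 * phi +
                         stats::rnorm(n, 0, ns[["walk20"]])),
    sitstand_rate = pmax(0.05, 0.45 + 0.10 * phi +
                           stats::rnorm(n, 0, ns[["sitstand"]])))
}

# covariates echoing a typical knee-OA accelerometer cohort
.simulate_covariates <- function(n, config) {
  sex <- factor(ifelse(stats::runif(n) < 0.4453, "M", "F"),
                levels = c("F", "M"))
  height <- ifelse(sex == "M", stats::rnorm(n, 175, 7),
                   stats::rnorm(n, 162, 6))
  data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    bmi = pmax(15, stats::rnorm(n, 28.52, 4.87)),
    age = pmin(90, pmax(45, stats::rnorm(n, 65, 9))),
    sex = sex,
    height = round(height, 1),
    oa_subcohort = factor(
      sample(c("control", "incidence", "progression"), n, replace = TRUE,
             prob = c(0.0030, 0.7446, 0.2524)),
      levels = c("control", "incidence", "progression")),
    stringsAsFactors = FALSE)
}

#' Simulate a full synthetic cohort
#'
#' Draws latent function scores, covariates, daily activity traces and
#' capacity measures for a cohort, in the exact tabular formats the I/O
#' module reads and writes. The returned ground truth records each
#' subject's latent score, true dwell probabilities, true expected daily
#' minutes per class, and capacity categories obtained by applying the
#' pipeline's quartile rule to the realized capacity values.
#'
#' @param config A [sim_config()].
#' @param outdir Optional directory; when given, `epochs.csv`,
#'   `covariates.csv`, `capacity.csv` and `ground_truth.csv` are written
#'   there.
#' @return A list with `epochs`, `covariates`, `capacity`, `truth` and the
#'   `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 3, days = 2))
#' head(cohort$epochs)
#' @export
simulate_cohort <- function(config = sim_config(), outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  phi <- stats::rnorm(n)
  covariates <- .simulate_covariates(n, config)
  capacity <- cbind(data.frame(subject_id = covariates$subject_id,
                               stringsAsFactors = FALSE),
                    simulate_capacity(phi, config))
  base_date <- as.Date("2020-03-02")
  nd <- n * config$days
  min_list <- vector("list", nd)
  cnt_list <- vector("list", nd)
  len <- integer(nd)
  dayix <- integer(nd)
  subjix <- integer(nd)
  dwell <- matrix(0, n, length(config$class_means))
  for (i in seq_len(n)) {
    for (d in seq_len(config$days)) {
      day <- simulate_subject_day(phi[i], config)
      k <- (i - 1L) * config$days + d
      min_list[[k]] <- day$minute
      cnt_list[[k]] <- day$count
      len[k] <- length(day$minute)
      dayix[k] <- d
      subjix[k] <- i
      dwell[i, ] <- dwell[i, ] + day$class_minutes
    }
  }
  epochs <- data.frame(
    subject_id = rep(covariates$subject_id[subjix], len),
    date = base_date + rep(dayix - 1L, len),
    minute = unlist(min_list), count = unlist(cnt_list),
    stringsAsFactors = FALSE)
  rownames(epochs) <- NULL
  probs <- t(vapply(phi, .dwell_probs, numeric(length(config$class_means)),
                    config = config))
  expected_wear <- mean(config$wear_hours) * 60
  truth <- data.frame(subject_id = covariates$subject_id, phi = phi,
                      stringsAsFactors = FALSE)
  for (j in seq_along(config$class_means)) {
    truth[[sprintf("dwell_prob_%d", j)]] <- probs[, j]
    truth[[sprintf("expected_minutes_%d", j)]] <- expected_wear * probs[, j]
    truth[[sprintf("observed_minutes_%d", j)]] <- dwell[, j] / config$days
  }
  if (n >= 4) {
    truth$category_walk400 <- as.integer(
      quartile_categorize(capacity$walk400_time))
    truth$category_walk20 <- as.integer(
      quartile_categorize(capacity$walk20_pace))
    truth$category_sitstand <- as.integer(
      quartile_categorize(capacity$sitstand_rate))
  } else {
    truth$category_walk400 <- truth$category_walk20 <-
      truth$category_sitstand <- NA_integer_
  }
  out <- list(epochs = epochs, covariates = covariates,
              capacity = capacity, truth = truth, config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_epochs(epochs, file.path(outdir, "epochs.csv"))
    write_table(covariates, file.path(outdir, "covariates.csv"))
    write_table(capacity, file.path(outdir, "capacity.csv"))
    write_table(truth, file.path(outdir, "ground_truth.csv"))
  }
  out
}
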