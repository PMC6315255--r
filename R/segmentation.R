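#' Segmentation configuration
#'
#' Tuning parameters of the divisive energy-statistic change-point
#' segmentation. Defaults follow the cited divisive method's conventional
#' settings: candidate splits must leave at least `min_size` minutes on each
#' side, each split is validated by a permutation test with `n_permutations`
#' random shufflings and accepted when the add-one p-value
#' `(r + 1)/(R + 1)` falls below `significance_level`.
#'
#' @param min_size Minimum segment duration in minutes (>= 2).
#' @param n_permutations Number of permutations per split test (>= 19).
#' @param significance_level Acceptance threshold for the permutation
#'   p-value, in (0, 1).
#' @param seed Master integer seed; every split test derives its permutation
#'   stream deterministically from this seed and the segment's location.
#' @return A list of class `"seg_config"`.
#' @export
seg_config <- function(min_size = 5L, n_permutations = 199L,
                       significance_level = 0.05, seed = 1L) {
  min_size <- as.integer(min_size)
  n_permutations <- as.integer(n_permutations)
  if (is.na(min_size) || min_size < 2L)
    stop("min_size must be an integer >= 2")
  if (is.na(n_permutations) || n_permutations < 19L)
    stop("n_permutations must be an integer >= 19")
  if (!is.numeric(significance_level) || significance_level <= 0 ||
      significance_level >= 1)
    stop("significance_level must lie strictly between 0 and 1")
  structure(list(min_size = min_size, n_permutations = n_permutations,
                 significance_level = significance_level,
                 seed = as.integer(seed)),
            class = "seg_config")
}

#' Energy divergence between two count samples
#'
#' Scaled sample energy divergence between the empirical distributions of
#' `x` and `y`:
#' \deqn{\frac{|x||y|}{|x|+|y|}\left(2 E|X-Y|^\alpha - E|X-X'|^\alpha -
#'   E|Y-Y'|^\alpha\right)}
#' with each expectation estimated by the U-statistic over all pairs. The
#' population divergence is nonnegative for \eqn{0 < \alpha < 2} and zero
#' iff the distributions coincide; the unbiased U-statistic estimate can dip
#' slightly below zero in small samples. This is the statistic maximized by
#' the divisive split search.
#'
#' @param x,y Nonempty numeric vectors.
#' @param alpha Exponent in (0, 2].
#' @return A nonnegative scalar.
#' @examples
#' energy_divergence(rep(0, 4), rep(10, 4))  # 40
#' @export
energy_divergence <- function(x, y, alpha = 1) {
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be nonempty")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 2)
    stop("alpha must lie in (0, 2]")
  cpp_energy_divergence(as.numeric(x), as.numeric(y), alpha)
}

#' Summarize a segment by mean, SD and duration
#'
#' @param counts Numeric vector of a bout's counts.
#' @param start,end Half-open 0-based range `[start, end)` within `counts`.
#' @return Named numeric vector `c(mean, sd, duration)`; the SD uses the
#'   sample (n - 1) denominator and is 0 for a single minute.
#' @export
summarize_segment <- function(counts, start, end) {
  if (end - start < 1) stop("empty segment range")
  if (start < 0 || end > length(counts)) stop("segment range out of bounds")
  v <- counts[(start + 1):end]
  s <- if (length(v) > 1) stats::sd(v) else 0
  c(mean = mean(v), sd = s, duration = length(v))
}

#' Segment one wear bout by divisive change-point analysis
#'
#' Recursively partitions a counts-per-minute sequence into maximal
#' homogeneous segments. At each step the split point maximizing the
#' energy divergence (exponent 1) between the two sides is located, subject
#' to `min_size`; the split is accepted iff a seeded permutation test yields
#' `p < significance_level`, and the recursion then descends into both
#' children. Segments are returned in temporal order and exactly tile the
#' bout.
#'
#' @param counts Numeric vector of the bout's counts per minute.
#' @param config A [seg_config()] object.
#' @param offset Minute-of-day of the bout's first minute (used to report
#'   day coordinates and to key the deterministic permutation streams).
#' @return A data frame with columns `start`, `end` (half-open, in day
#'   coordinates), `mean`, `sd`, `duration`.
#' @export
segment_bout <- function(counts, config = seg_config(), offset = 0L) {
  if (!inherits(config, "seg_config")) stop("config must be a seg_config")
  n <- length(counts)
  if (n == 0)
    return(data.frame(start = integer(), end = integer(), mean = numeric(),
                      sd = numeric(), duration = integer()))
  counts <- as.numeric(counts)
  lo_acc <- integer(0)
  hi_acc <- integer(0)
  recurse <- function(lo, hi) {
    len <- hi - lo + 1L
    if (len >= 2L * config$min_size) {
      res <- cpp_split_test(counts[lo:hi], config$min_size,
                            config$n_permutations,
                            config$significance_level,
                            as.numeric(config$seed),
                            as.numeric(offset + lo),
                            as.numeric(offset + hi))
      if (isTRUE(res$significant)) {
        tau <- res$tau
        recurse(lo, lo + tau - 1L)
        recurse(lo + tau, hi)
        return(invisible(NULL))
      }
    }
    lo_acc[[length(lo_acc) + 1L]] <<- lo
    hi_acc[[length(hi_acc) + 1L]] <<- hi
    invisible(NULL)
  }
  recurse(1L, n)
  mu <- vapply(seq_along(lo_acc), function(i)
    mean(counts[lo_acc[i]:hi_acc[i]]), 0)
  sg <- vapply(seq_along(lo_acc), function(i) {
    v <- counts[lo_acc[i]:hi_acc[i]]
    if (length(v) > 1) stats::sd(v) else 0
  }, 0)
  data.frame(start = offset + lo_acc - 1L, end = offset + hi_acc,
             mean = mu, sd = sg, duration = hi_acc - lo_acc + 1L)
}

#' Segment a cohort's valid wear days
#'
#' Applies the full pre-processing chain to epoch records: per subject-day
#' nonwear detection ([detect_nonwear()]), the 10-hour valid-day rule
#' ([valid_day()]), extraction of contiguous wear bouts
#' ([extract_bouts()]), and divisive segmentation of each bout
#' ([segment_bout()]). Segmentation operates strictly per wear bout; excised
#' nonwear gaps are never spliced. Each (subject, day, bout) receives its
#' own deterministic seed derived from the master seed, so results are
#' independent of processing order.
#'
#' @param epochs Epoch data frame from [read_epochs()] or
#'   [simulate_cohort()].
#' @param config A [seg_config()] object.
#' @return A list with `segments` (data frame: `subject_id`, `date`, `day`,
#'   `start`, `end`, `mean`, `sd`, `duration`; valid days only) and `days`
#'   (data frame: `subject_id`, `date`, `day`, `wear_minutes`, `valid` for
#'   every observed subject-day).
#' @export
segment_activity <- function(epochs, config = seg_config()) {
  stopifnot(all(c("subject_id", "date", "minute", "count") %in%
                  names(epochs)))
  epochs <- epochs[order(epochs$subject_id, epochs$date, epochs$minute), ,
                   drop = FALSE]
  subjects <- sort(unique(epochs$subject_id))
  by_subj <- split(seq_len(nrow(epochs)), epochs$subject_id)
  seg_list <- list()
  day_list <- list()
  dates_all <- vector("list", length(subjects))
  for (si in seq_along(subjects)) {
    sdat <- epochs[by_subj[[subjects[si]]], , drop = FALSE]
    by_date <- split(seq_len(nrow(sdat)), sdat$date)
    dates <- as.Date(names(by_date))
    dates_all[[si]] <- dates
    for (di in seq_along(dates)) {
      ddat <- sdat[by_date[[di]], , drop = FALSE]
      mask <- detect_nonwear(ddat$count, ddat$minute)
      wear <- sum(mask)
      ok <- wear >= 600L
      day_list[[length(day_list) + 1L]] <-
        data.frame(subject_id = subjects[si], date = dates[di], day = di,
                   wear_minutes = wear, valid = ok)
      if (!ok) next
      bouts <- extract_bouts(ddat$count, mask, ddat$minute)
      for (bi in seq_along(bouts)) {
        bcfg <- config
        bcfg$seed <- .bout_seed(config$seed, si, di, bi)
        segs <- segment_bout(bouts[[bi]]$counts, bcfg,
                             offset = bouts[[bi]]$start)
        seg_list[[length(seg_list) + 1L]] <-
          list(si = si, di = di, segs = segs)
      }
    }
  }
  days <- do.call(rbind, day_list)
  rownames(days) <- NULL
  if (length(seg_list)) {
    nper <- vapply(seg_list, function(b) nrow(b$segs), 0L)
    segments <- data.frame(
      subject_id = rep(subjects[vapply(seg_list, `[[`, 0L, "si")], nper),
      date = rep(as.Date(vapply(seg_list, function(b)
        as.character(dates_all[[b$si]][b$di]), "")), nper),
      day = rep(vapply(seg_list, `[[`, 0L, "di"), nper),
      start = unlist(lapply(seg_list, function(b) b$segs$start)),
      end = unlist(lapply(seg_list, function(b) b$segs$end)),
      mean = unlist(lapply(seg_list, function(b) b$segs$mean)),
      sd = unlist(lapply(seg_list, function(b) b$segs$sd)),
      duration = unlist(lapply(seg_list, function(b) b$segs$duration)),
      stringsAsFactors = FALSE)
    rownames(segments) <- NULL
  } else {
    segments <- data.frame(subject_id = character(),
                           date = as.Date(character()), day = integer(),
                           start = integer(), end = integer(),
                           mean = numeric(), sd = numeric(),
                           duration = integer())
  }
  list(segments = segments, days = days)
}

# deterministic per-(subject, day, bout) seed below 2^31
.bout_seed <- function(master, si, di, bi) {
  h <- (as.numeric(master) * 2654435761 + si * 975313579 +
          di * 192837465 + bi * 1299709) %% 2147483629
  as.integer(h)
}
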