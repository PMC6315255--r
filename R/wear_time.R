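#' Flag nonwear minutes in one day of activity counts
#'
#' Applies the standard counts-per-minute nonwear rule: a continuous run of
#' zero counts spanning more than 90 minutes is nonwear, where the run may
#' contain interruptions of at most 2 consecutive minutes each with counts
#' below 100. A minute with count >= 100, an interruption of 3 or more
#' consecutive minutes, or a timestamp gap always terminates a run. The span
#' of a flagged run (including its interior interruption minutes) is marked
#' nonwear; trailing interruption minutes after the last zero are not part of
#' the run. Runs never bridge calendar days. Runs touching the day edges are
#' eligible.
#'
#' @param counts Integer vector of one day's counts per minute (in temporal
#'   order, length <= 1440).
#' @param minutes Optional integer vector of minute-of-day stamps aligned to
#'   `counts`; non-consecutive stamps break runs (missing minutes are gaps,
#'   not zeros).
#' @return Logical wear mask aligned to `counts`: `TRUE` = wear,
#'   `FALSE` = nonwear.
#' @examples
#' detect_nonwear(c(rep(500, 10), rep(0, 95), rep(500, 10)))
#' @export
detect_nonwear <- function(counts, minutes = NULL) {
  n <- length(counts)
  if (n == 0) return(logical(0))
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be nonnegative and non-missing")
  if (!is.null(minutes)) {
    if (length(minutes) != n) stop("minutes must align with counts")
    gap_before <- c(FALSE, diff(minutes) != 1L)
  } else {
    gap_before <- rep(FALSE, n)
  }
  nonwear <- logical(n)
  i <- 1L
  while (i <= n) {
    if (counts[i] == 0) {
      run_start <- i
      last_zero <- i
      j <- i + 1L
      interrupt <- 0L
      while (j <= n) {
        if (gap_before[j]) break
        if (counts[j] == 0) {
          last_zero <- j
          interrupt <- 0L
        } else if (counts[j] < 100) {
          interrupt <- interrupt + 1L
          if (interrupt > 2L) break
        } else break
        j <- j + 1L
      }
      if (last_zero - run_start + 1L > 90L)
        nonwear[run_start:last_zero] <- TRUE
      i <- last_zero + 1L
    } else {
      i <- i + 1L
    }
  }
  !nonwear
}

#' Is a day valid for analysis?
#'
#' A day is valid when its inferred wear time is at least 10 hours
#' (600 minutes).
#'
#' @param mask Logical wear mask from [detect_nonwear()].
#' @return `TRUE` iff the day has at least 600 wear minutes.
#' @export
valid_day <- function(mask) {
  if (!is.logical(mask)) stop("mask must be logical")
  sum(mask) >= 600L
}

#' Extract contiguous wear bouts
#'
#' Splits one day's counts into maximal contiguous runs of wear minutes.
#' Nonwear minutes and timestamp gaps separate bouts; concatenating the bout
#' counts reproduces the day's wear-minute subsequence in order.
#'
#' @inheritParams detect_nonwear
#' @param mask Logical wear mask aligned to `counts`.
#' @return A list of bouts, each a list with `start` (first minute-of-day),
#'   `end` (half-open end minute), and `counts`.
#' @export
extract_bouts <- function(counts, mask, minutes = NULL) {
  n <- length(counts)
  if (length(mask) != n) stop("mask must align with counts")
  if (is.null(minutes)) minutes <- seq_len(n) - 1L
  idx <- which(mask)
  if (length(idx) == 0) return(list())
  new_bout <- c(TRUE, diff(idx) != 1L | diff(minutes[idx]) != 1L)
  grp <- cumsum(new_bout)
  unname(lapply(split(idx, grp), function(ii) {
    list(start = minutes[ii[1]], end = minutes[ii[length(ii)]] + 1L,
         counts = unname(counts[ii]))
  }))
}
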