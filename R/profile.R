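#' Build a pattern-class grid over segment (mean, SD) space
#'
#' Partitions the feature space spanned by segment means and SDs into
#' half-open rectangular pattern classes of equal width on both axes. The
#' extents `M` and `S` are the maximum segment mean and SD over the supplied
#' reference segments; bins are `[i*w, (i+1)*w)` from origin 0 with the top
#' bin closed above so that `M` and `S` are representable. When the grid is
#' built from training segments only, held-out segments beyond `M` or `S`
#' clip to the edge bins (see [assign_class()]).
#'
#' @param segments Nonempty data frame with `mean` and `sd` columns (from
#'   [segment_activity()]).
#' @param interval_width Common bin width on both axes (counts/min, > 0).
#' @return An object of class `"pattern_grid"` with elements `width`, `M`,
#'   `S`, `n_mean_bins`, `n_sd_bins`, `J` and `labels`.
#' @examples
#' segs <- data.frame(mean = c(100, 4100), sd = c(10, 2000))
#' build_grid(segs, 700)  # 6 x 3 grid, J = 18
#' @export
build_grid <- function(segments, interval_width) {
  if (!is.numeric(interval_width) || length(interval_width) != 1 ||
      interval_width <= 0)
    stop("interval_width must be a single positive number")
  if (!is.data.frame(segments) || nrow(segments) == 0)
    stop("a nonempty reference segment collection is required")
  M <- max(segments$mean)
  S <- max(segments$sd)
  n_mean <- max(1L, as.integer(ceiling(M / interval_width)))
  n_sd <- max(1L, as.integer(ceiling(S / interval_width)))
  labels <- character(n_mean * n_sd)
  for (mi in 0:(n_mean - 1L)) {
    for (sj in 0:(n_sd - 1L)) {
      labels[mi * n_sd + sj + 1L] <- sprintf("pc_m%d_s%d", mi, sj)
    }
  }
  structure(list(width = interval_width, M = M, S = S,
                 n_mean_bins = n_mean, n_sd_bins = n_sd,
                 J = n_mean * n_sd, labels = labels),
            class = "pattern_grid")
}

#' @export
print.pattern_grid <- function(x, ...) {
  cat(sprintf(paste0("Pattern-class grid: width %g counts/min, %d mean x %d",
                     " SD bins (J = %d)\n  extents M = %.1f, S = %.1f\n"),
              x$width, x$n_mean_bins, x$n_sd_bins, x$J, x$M, x$S))
  invisible(x)
}

#' Assign segments to pattern classes
#'
#' Maps segment (mean, SD) pairs to grid cells by floor division by the
#' interval width. Values above the grid extents (possible when the grid was
#' built on training segments only) clip to the top bin; `M` and `S`
#' themselves fall in the top bin (closed upper edge).
#'
#' @param mean,sd Numeric vectors of segment means and SDs (nonnegative).
#' @param grid A [build_grid()] object.
#' @return A data frame with `mean_bin` and `sd_bin` (0-based bin indices),
#'   `class_index` (1-based flat index into `grid$labels`) and `label`.
#' @export
assign_class <- function(mean, sd, grid) {
  if (!inherits(grid, "pattern_grid")) stop("grid must be a pattern_grid")
  if (any(mean < 0) || any(sd < 0))
    stop("segment mean and sd must be nonnegative")
  mb <- pmin(floor(mean / grid$width), grid$n_mean_bins - 1L)
  sb <- pmin(floor(sd / grid$width), grid$n_sd_bins - 1L)
  idx <- as.integer(mb * grid$n_sd_bins + sb + 1L)
  data.frame(mean_bin = as.integer(mb), sd_bin = as.integer(sb),
             class_index = idx, label = grid$labels[idx],
             stringsAsFactors = FALSE)
}

#' Function profile for one subject
#'
#' Computes the length-`J` vector of average daily minutes per pattern
#' class, `a_j = (1/K) * sum_k t_jk`, where `t_jk` is the minutes subject
#' spent in class `j` on valid day `k`. Days with no segments contribute
#' zeros. The entries sum exactly to the subject's mean daily wear minutes
#' over valid days.
#'
#' @param segments Data frame of one subject's segments on valid days
#'   (columns `mean`, `sd`, `duration`).
#' @param grid A [build_grid()] object.
#' @param K Number of valid days (>= 1).
#' @return Named numeric vector of length `grid$J`.
#' @export
function_profile <- function(segments, grid, K) {
  if (!inherits(grid, "pattern_grid")) stop("grid must be a pattern_grid")
  if (length(K) != 1 || is.na(K) || K < 1)
    stop("K must be a positive valid-day count (subject excluded upstream)")
  a <- numeric(grid$J)
  names(a) <- grid$labels
  if (nrow(segments)) {
    cls <- assign_class(segments$mean, segments$sd, grid)$class_index
    tot <- tapply(segments$duration, cls, sum)
    a[as.integer(names(tot))] <- as.numeric(tot) / K
  }
  a
}

#' Function profiles for a whole cohort
#'
#' Applies [function_profile()] to every subject with at least one valid
#' day.
#'
#' @param segments Segment data frame from [segment_activity()].
#' @param days Day table from [segment_activity()].
#' @param grid A [build_grid()] object.
#' @return A data frame with `subject_id`, `K` (valid days) and one column
#'   per pattern class (named as in `grid$labels`).
#' @export
function_profiles <- function(segments, days, grid) {
  vd <- days[days$valid, , drop = FALSE]
  if (nrow(vd) == 0)
    stop("no valid days in the cohort")
  Ktab <- table(vd$subject_id)
  subjects <- names(Ktab)
  mat <- matrix(0, nrow = length(subjects), ncol = grid$J,
                dimnames = list(subjects, grid$labels))
  for (i in seq_along(subjects)) {
    segs <- segments[segments$subject_id == subjects[i], , drop = FALSE]
    mat[i, ] <- function_profile(segs, grid, as.integer(Ktab[[i]]))
  }
  out <- data.frame(subject_id = subjects, K = as.integer(Ktab),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(mat, optional = TRUE))
}

#' Chebyshev tail bounds for a pattern class
#'
#' Treats the midinterval values of a class's mean and SD intervals as mu
#' and sigma and applies Chebyshev's inequality
#' \eqn{P(|X - \mu| > k\sigma) < 1/k^2}: at least a fraction
#' \eqn{1 - 1/k^2} of the class's counts per minute lie between
#' \eqn{\mu - k\sigma} and \eqn{\mu + k\sigma}.
#'
#' @param mean_interval Numeric length-2 vector, the class's mean interval.
#' @param sd_interval Numeric length-2 vector, the class's SD interval.
#' @param k Positive multiplier.
#' @return A list with `lower`, `upper` (counts/min) and
#'   `prob_lower_bound` (`1 - 1/k^2`).
#' @examples
#' chebyshev_bounds(c(2800, 3500), c(0, 700), k = 1.8)  # 2520 .. 3780
#' @export
chebyshev_bounds <- function(mean_interval, sd_interval, k) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0)
    stop("k must be a single positive number")
  if (length(mean_interval) != 2 || length(sd_interval) != 2)
    stop("mean_interval and sd_interval must be length-2 numeric vectors")
  mu <- mean(mean_interval)
  sigma <- mean(sd_interval)
  list(lower = mu - k * sigma, upper = mu + k * sigma,
       prob_lower_bound = 1 - 1 / k^2)
}
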