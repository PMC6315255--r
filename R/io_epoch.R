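#' Read minute-epoch activity counts
#'
#' Reads a long-format CSV of minute-level activity counts with columns
#' `subject_id`, `timestamp` (ISO-8601 to the minute, e.g.
#' `"2020-03-02T08:15"`; a space separator is also accepted) and `count`
#' (nonnegative integer activity counts per minute). Records are returned in
#' canonical order (subject, date, minute) regardless of file order. A
#' subject-day is the calendar date of the timestamp's local clock; missing
#' minutes are gaps, not zeros.
#'
#' @param path Path to the epoch CSV file.
#' @return A data frame with columns `subject_id` (character), `date`
#'   (`Date`), `minute` (integer minute-of-day, 0-1439) and `count`
#'   (integer), ordered by subject, date and minute.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("subject_id,timestamp,count",
#'              "s1,2020-03-02T08:00,0",
#'              "s1,2020-03-02T08:01,100"), f)
#' read_epochs(f)
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop("epoch file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timestamp", "count")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("epoch file is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(raw) == 0) {
    warning("epoch file has no records")
    return(data.frame(subject_id = character(), date = as.Date(character()),
                      minute = integer(), count = integer()))
  }
  cnt <- raw$count
  bad <- which(is.na(cnt) | cnt < 0 | cnt != floor(cnt))
  if (length(bad))
    stop("invalid count (must be a nonnegative integer) at row ", bad[1],
         ": ", raw$count[bad[1]])
  ts <- as.character(raw$timestamp)
  date <- as.Date(substr(ts, 1, 10))
  hm <- sub("^.{10}[T ]", "", ts)
  hh <- suppressWarnings(as.integer(substr(hm, 1, 2)))
  mm <- suppressWarnings(as.integer(substr(hm, 4, 5)))
  if (anyNA(date) || anyNA(hh) || anyNA(mm))
    stop("unparseable timestamp at row ",
         which(is.na(date) | is.na(hh) | is.na(mm))[1])
  minute <- hh * 60L + mm
  key <- paste(raw$subject_id, date, minute)
  if (anyDuplicated(key))
    stop("duplicate subject/timestamp at row ", which(duplicated(key))[1])
  out <- data.frame(subject_id = as.character(raw$subject_id), date = date,
                    minute = minute, count = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out <- out[order(out$subject_id, out$date, out$minute), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write minute-epoch activity counts
#'
#' Writes epoch records (as returned by [read_epochs()] or
#' [simulate_cohort()]) to the long-format CSV interchange file with columns
#' `subject_id,timestamp,count`.
#'
#' @param epochs Data frame with columns `subject_id`, `date`, `minute`,
#'   `count`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(all(c("subject_id", "date", "minute", "count") %in% names(epochs)))
  ts <- sprintf("%sT%02d:%02d", format(epochs$date, "%Y-%m-%d"),
                epochs$minute %/% 60L, epochs$minute %% 60L)
  out <- data.frame(subject_id = epochs$subject_id, timestamp = ts,
                    count = epochs$count)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read subject covariates
#'
#' Reads the covariate CSV with columns `subject_id`, `bmi` (kg/m^2), `age`
#' (years), `sex` (`"F"`/`"M"`), `height` (cm) and `oa_subcohort` (one of
#' `"control"`, `"incidence"`, `"progression"`).
#'
#' @param path Path to the covariate CSV file.
#' @return A data frame, one row per subject, with `sex` and `oa_subcohort`
#'   as factors over their closed vocabularies.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("covariate file not found: ", path)
  # read as character first: "F" sex labels must not become logicals
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  for (v in intersect(c("bmi", "age", "height"), names(raw)))
    raw[[v]] <- suppressWarnings(as.numeric(raw[[v]]))
  need <- c("subject_id", "bmi", "age", "sex", "height", "oa_subcohort")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("covariate file is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(raw) == 0) {
    warning("covariate file has no records")
  } else {
    for (v in c("bmi", "age", "height")) {
      bad <- which(is.na(raw[[v]]) | raw[[v]] <= 0)
      if (length(bad))
        stop("invalid ", v, " (must be strictly positive) at row ", bad[1])
    }
    badsex <- which(!raw$sex %in% c("F", "M"))
    if (length(badsex))
      stop("unknown sex label at row ", badsex[1], ": ", raw$sex[badsex[1]])
    badoa <- which(!raw$oa_subcohort %in%
                     c("control", "incidence", "progression"))
    if (length(badoa))
      stop("unknown oa_subcohort label at row ", badoa[1], ": ",
           raw$oa_subcohort[badoa[1]])
    if (anyDuplicated(raw$subject_id))
      stop("duplicate subject_id in covariate file")
  }
  out <- data.frame(subject_id = as.character(raw$subject_id),
                    bmi = as.numeric(raw$bmi), age = as.numeric(raw$age),
                    sex = factor(raw$sex, levels = c("F", "M")),
                    height = as.numeric(raw$height),
                    oa_subcohort = factor(raw$oa_subcohort,
                                          levels = c("control", "incidence",
                                                     "progression")),
                    stringsAsFactors = FALSE)
  out[order(out$subject_id), , drop = FALSE]
}

#' Read physical-capacity measurements
#'
#' Reads the capacity CSV with columns `subject_id`, `walk400_time`
#' (400-m walk completion time, seconds), `walk20_pace` (20-m walk average
#' pace, m/s) and `sitstand_rate` (sit-to-stands per second over 5
#' repetitions). Empty cells are missing values; present values must be
#' strictly positive.
#'
#' @param path Path to the capacity CSV file.
#' @return A data frame, one row per subject.
#' @export
read_capacity <- function(path) {
  if (!file.exists(path)) stop("capacity file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "walk400_time", "walk20_pace", "sitstand_rate")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("capacity file is missing required column(s): ",
         paste(miss, collapse = ", "))
  for (v in need[-1]) {
    bad <- which(!is.na(raw[[v]]) & raw[[v]] <= 0)
    if (length(bad))
      stop("invalid ", v, " (present values must be strictly positive) ",
           "at row ", bad[1])
  }
  out <- data.frame(subject_id = as.character(raw$subject_id),
                    walk400_time = as.numeric(raw$walk400_time),
                    walk20_pace = as.numeric(raw$walk20_pace),
                    sitstand_rate = as.numeric(raw$sitstand_rate),
                    stringsAsFactors = FALSE)
  out[order(out$subject_id), , drop = FALSE]
}

#' Write a derived tabular artifact
#'
#' Writes any derived table (segments, function profiles, predictions) as
#' CSV. Numeric columns are serialized with 17 significant digits so that
#' `read_table(write_table(x))` round-trips field-for-field at full stored
#' precision.
#'
#' @param records Data frame to write.
#' @param path Output path.
#' @param allow_empty Permit writing a header-only file for an empty table.
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path, allow_empty = FALSE) {
  if (!is.data.frame(records)) stop("records must be a data frame")
  if (nrow(records) == 0 && !allow_empty)
    stop("refusing to write an empty table (set allow_empty = TRUE)")
  out <- records
  for (v in names(out)) {
    if (is.double(out[[v]]))
      out[[v]] <- formatC(out[[v]], digits = 17, format = "g")
    if (inherits(records[[v]], "Date"))
      out[[v]] <- format(records[[v]], "%Y-%m-%d")
  }
  status <- try(utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
                silent = TRUE)
  if (inherits(status, "try-error"))
    stop("could not write table to ", path, ": ",
         attr(status, "condition")$message)
  invisible(path)
}

#' Read back a derived tabular artifact
#'
#' Counterpart of [write_table()].
#'
#' @param path Path of a CSV written by [write_table()].
#' @return A data frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("table not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
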