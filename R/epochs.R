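# Minute-epoch accelerometry input, wear-time validity and inclusion filters.
#
# The day grid runs noon-to-noon so that a night's sleep period is never
# split across day boundaries.  A day is valid when it is complete (1440
# minutes inside the recording) and has strictly more than 16 h (960 min)
# of wear; subjects enter the analysis with at least `min_valid_days`
# valid days.

EPOCH_TIME_FORMATS <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                        "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")

#' Construct a minute-epoch series for one subject
#'
#' @param subject_id subject identifier (coerced to character).
#' @param start POSIXct (or parseable string) timestamp of the first minute.
#' @param counts numeric vector of non-negative activity counts, one per
#'   minute.
#' @param wear logical vector parallel to `counts`; `TRUE` where the device
#'   was worn.  Defaults to all worn.
#' @return An object of class `epoch_series`.
#' @export
epoch_series <- function(subject_id, start, counts, wear = NULL) {
  if (is.character(start)) start <- parse_epoch_time(start)
  stopifnot(inherits(start, "POSIXct"), length(start) == 1L)
  counts <- as.numeric(counts)
  if (length(counts) < 1L) stop("empty count series", call. = FALSE)
  if (anyNA(counts)) stop("NA counts are not allowed; encode missing data as wear = FALSE",
                          call. = FALSE)
  if (any(counts < 0)) stop("negative counts are not allowed", call. = FALSE)
  wear <- if (is.null(wear)) rep(TRUE, length(counts)) else as.logical(wear)
  if (length(wear) != length(counts)) stop("counts and wear must have equal length",
                                           call. = FALSE)
  wear[is.na(wear)] <- FALSE
  structure(list(subject_id = as.character(subject_id), start = start,
                 counts = counts, wear = wear),
            class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> subject %s: %d minutes from %s (%.1f%% worn)\n",
              x$subject_id, length(x$counts),
              format(x$start, "%Y-%m-%d %H:%M"), 100 * mean(x$wear)))
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$counts)

parse_epoch_time <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in EPOCH_TIME_FORMATS) {
    todo <- which(is.na(out))
    if (!length(todo)) break
    out[todo] <- as.POSIXct(x[todo], tz = "UTC", format = fmt)
  }
  out
}

# Minutes since midnight of the first epoch.
start_minute_of_day <- function(series) {
  lt <- as.POSIXlt(series$start, tz = "UTC")
  lt$hour * 60L + lt$min
}

#' Clock minute (0..1439, midnight-based) of each epoch in a series
#' @param series an [epoch_series()].
#' @return integer vector parallel to `series$counts`.
#' @export
clock_minutes <- function(series) {
  (start_minute_of_day(series) + seq_along(series$counts) - 1L) %% 1440L
}

#' Read minute-epoch accelerometry from CSV
#'
#' Expects columns `subject`, `timestamp`, `count` and optionally `wear`
#' (logical or 0/1), with ISO-8601 timestamps at minute resolution and one
#' row per minute.  When the `wear` column is absent every observed minute
#' is treated as worn.  Gaps in a subject's timestamp grid are filled with
#' `count = 0`, `wear = FALSE`.
#'
#' @param path path to the CSV file.
#' @return Named list of [epoch_series()], one per subject.
#' @export
read_epochs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "timestamp", "count")
  if (!all(need %in% names(df)))
    stop("epoch CSV must have columns subject, timestamp, count", call. = FALSE)
  ts <- parse_epoch_time(df$timestamp)
  if (anyNA(ts)) stop_rows("unparseable timestamp", which(is.na(ts)))
  cnt <- suppressWarnings(as.numeric(df$count))
  if (anyNA(cnt)) stop_rows("non-numeric count", which(is.na(cnt)))
  if (any(cnt < 0)) stop_rows("negative count", which(cnt < 0))
  wear <- if ("wear" %in% names(df)) as.logical(df$wear) else rep(TRUE, nrow(df))
  wear[is.na(wear)] <- FALSE

  out <- list()
  for (sid in unique(as.character(df$subject))) {
    idx <- which(as.character(df$subject) == sid)
    o <- order(ts[idx])
    idx <- idx[o]
    tsi <- ts[idx]
    mins <- as.numeric(difftime(tsi, tsi[1L], units = "mins"))
    if (any(abs(mins - round(mins)) > 1e-6))
      stop_rows("timestamp not on the minute grid", idx[abs(mins - round(mins)) > 1e-6])
    mins <- as.integer(round(mins))
    if (anyDuplicated(mins))
      stop_rows("duplicated minute", idx[duplicated(mins)])
    n <- mins[length(mins)] + 1L
    counts <- numeric(n)
    worn <- logical(n)
    counts[mins + 1L] <- cnt[idx]
    worn[mins + 1L] <- wear[idx]
    out[[sid]] <- epoch_series(sid, tsi[1L], counts, worn)
  }
  out
}

#' Write minute-epoch accelerometry to CSV
#'
#' Inverse of [read_epochs()]; emits one row per minute with the
#' `subject,timestamp,count,wear` dialect.
#'
#' @param series list of [epoch_series()].
#' @param path output path.
#' @export
write_epochs <- function(series, path) {
  if (inherits(series, "epoch_series")) series <- list(series)
  parts <- lapply(series, function(s) {
    n <- length(s$counts)
    data.frame(subject = s$subject_id,
               timestamp = format(s$start + 60 * (seq_len(n) - 1L),
                                  "%Y-%m-%d %H:%M:%S", tz = "UTC"),
               count = s$counts, wear = s$wear)
  })
  utils::write.csv(do.call(rbind, parts), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Segment a series into noon-to-noon day windows
#'
#' Windows tile the series without overlap: every minute belongs to exactly
#' one window.  Leading/trailing partial windows are marked invalid; a
#' complete window is valid iff its wear time strictly exceeds 960 minutes
#' (16 h).
#'
#' @param series an [epoch_series()].
#' @param min_wear_minutes validity threshold; a day is valid when
#'   `wear_minutes > min_wear_minutes`.  Default 960.
#' @return data.frame with one row per window: `subject`, `day_index`,
#'   `start_idx`, `end_idx` (1-based, inclusive), `n_minutes`,
#'   `wear_minutes`, `complete`, `valid`.
#' @export
segment_days <- function(series, min_wear_minutes = 960L) {
  stopifnot(inherits(series, "epoch_series"))
  n <- length(series$counts)
  md <- start_minute_of_day(series)
  pos0 <- (md - 720L) %% 1440L           # offset of first epoch in its noon-day
  starts <- unique(c(1L, seq.int(1L + (1440L - pos0) %% 1440L, n, by = 1440L)))
  starts <- starts[starts <= n]
  ends <- c(starts[-1L] - 1L, n)
  n_min <- ends - starts + 1L
  wear_min <- vapply(seq_along(starts), function(i)
    sum(series$wear[starts[i]:ends[i]]), integer(1L))
  complete <- n_min == 1440L
  data.frame(subject = series$subject_id,
             day_index = seq_along(starts) - 1L,
             start_idx = starts, end_idx = ends, n_minutes = n_min,
             wear_minutes = wear_min, complete = complete,
             valid = complete & (wear_min > min_wear_minutes))
}

#' Apply the minimum-valid-days inclusion filter
#'
#' @param windows data.frame of day windows from [segment_days()] (possibly
#'   row-bound across subjects).
#' @param min_valid_days minimum number of valid days required; default 7.
#' @return list with `included` (character vector of retained subject ids)
#'   and `counts` (data.frame `subject`, `valid_days`, `included`).
#' @export
apply_inclusion <- function(windows, min_valid_days = 7L) {
  vd <- tapply(windows$valid, windows$subject, sum)
  counts <- data.frame(subject = names(vd), valid_days = as.integer(vd),
                       included = as.integer(vd) >= min_valid_days,
                       row.names = NULL)
  if (!any(counts$included))
    stop(sprintf("no subjects with >= %d valid days; cohort is empty after filtering",
                 min_valid_days), call. = FALSE)
  list(included = counts$subject[counts$included], counts = counts)
}

#' Read a subject covariate table
#'
#' Expects columns `subject, age, sex, bmi, group, anxiety, sud` and
#' optionally `medication`.  `sex` must be `female`/`male`; `group` must be
#' one of `none`, `current`, `remitted` (the three diagnosis strata; the
#' lifetime contrast pools `current` and `remitted`).
#'
#' @param path path to the CSV file.
#' @return data.frame with typed columns.
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "age", "sex", "bmi", "group", "anxiety", "sud")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("covariate CSV missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$subject)) stop_rows("duplicated subject",
                                           which(duplicated(df$subject)))
  bad <- which(!df$sex %in% c("female", "male"))
  if (length(bad)) stop_rows("sex must be 'female' or 'male'", bad)
  bad <- which(!df$group %in% c("none", "current", "remitted"))
  if (length(bad)) stop_rows("group must be 'none', 'current' or 'remitted'", bad)
  df$subject <- as.character(df$subject)
  df$sex <- factor(df$sex, levels = c("female", "male"))
  df$group <- factor(df$group, levels = c("none", "current", "remitted"))
  for (col in intersect(c("anxiety", "sud", "medication"), names(df)))
    df[[col]] <- as.logical(df[[col]])
  df
}

#' Write a subject covariate table
#' @param covariates data.frame as returned by [read_covariates()].
#' @param path output path.
#' @export
write_covariates <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
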