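# Nightly sleep-period detection and the seven sleep-domain features:
# Onset, Wakeup, Midpoint, Duration, Efficiency, NWB, NSB.
#
# Detection is a count-based heuristic on the noon-to-noon day window:
# counts are smoothed with a running median, thresholded into rest/active,
# rest runs separated by short active gaps are merged into rest-dominated
# blocks, and the sleep period is the longest such block.  Within the
# period, minute-level sleep/wake flags come from the raw (unsmoothed)
# counts.  Duration is actual sleep time within the period, so
# Efficiency = Duration / (Wakeup - Onset) can be well below 1 even for an
# uninterrupted period boundary.

#' Detect the nightly sleep period within one noon-to-noon day
#'
#' @param counts numeric vector of at least 1440 contiguous minute counts
#'   (one noon-to-noon window).
#' @param theta_sleep count threshold below which a minute is rest/sleep;
#'   default 10.
#' @param smooth_width running-median width in minutes (odd); default 11.
#' @param min_period minimum sleep-period length in minutes; shorter
#'   candidate blocks yield a missing night.  Default 180.
#' @param max_gap active gaps shorter than this (minutes) are absorbed when
#'   merging rest runs into rest-dominated blocks; default 30.
#' @return A `sleep_record` list with `onset` and `wakeup` in hours on the
#'   continuous 12-36 noon-to-noon axis, and `sleep_flags` (logical, one per
#'   minute of the period), or `NULL` when no rest block of at least
#'   `min_period` minutes exists.
#' @export
detect_sleep_period <- function(counts, theta_sleep = 10, smooth_width = 11,
                                min_period = 180, max_gap = 30) {
  stopifnot(length(counts) >= 1440L, theta_sleep > 0)
  counts <- counts[seq_len(1440L)]
  sm <- stats::runmed(counts, k = smooth_width, endrule = "median")
  rest <- sm < theta_sleep
  runs <- logical_runs(rest)
  if (nrow(runs) == 0L) return(NULL)
  # merge rest runs separated by active gaps shorter than max_gap
  blocks <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) for (i in 2L:nrow(runs)) {
    gap <- runs$start[i] - blocks$end[nrow(blocks)] - 1L
    if (gap < max_gap) {
      blocks$end[nrow(blocks)] <- runs$end[i]
    } else {
      blocks <- rbind(blocks, runs[i, ])
    }
  }
  blocks$length <- blocks$end - blocks$start + 1L
  best <- blocks[which.max(blocks$length), ]
  if (best$length < min_period) return(NULL)
  flags <- counts[best$start:best$end] < theta_sleep
  # trim to the first/last raw sleep minute so flags never start or end
  # with wake (period edges are rest by construction)
  if (!any(flags)) return(NULL)
  lo <- best$start + which(flags)[1L] - 1L
  hi <- best$start + which(flags)[sum(flags)] - 1L
  if (hi - lo + 1L < min_period) return(NULL)
  structure(list(onset = 12 + (lo - 1L) / 60,
                 wakeup = 12 + hi / 60,
                 start_idx = lo, end_idx = hi,
                 sleep_flags = counts[lo:hi] < theta_sleep),
            class = "sleep_record")
}

# Per-night feature arithmetic on a sleep record.
night_features <- function(record, nwb_min_wake = 5L, nsb_min_wake = 1L) {
  flags <- record$sleep_flags
  if (!length(flags) || !any(flags)) stop("zero-length sleep period", call. = FALSE)
  spt <- record$wakeup - record$onset
  duration <- sum(flags) / 60
  wake_runs <- logical_runs(!flags)
  nwb <- sum(wake_runs$length >= nwb_min_wake)
  # NSB: number of sleep blocks; by default any wake minute splits blocks,
  # optionally only wake runs of >= nsb_min_wake minutes split them.
  splitting <- sum(wake_runs$length >= nsb_min_wake)
  nsb <- splitting + 1L
  c(Onset = record$onset, Wakeup = record$wakeup,
    Duration = duration,
    Midpoint = record$onset + spt / 2,
    Efficiency = duration / spt,
    NWB = nwb, NSB = nsb)
}

#' Summarise per-night sleep records into subject-level sleep features
#'
#' Features are computed per night and averaged across non-missing nights.
#' Onset, Wakeup and Midpoint are averaged on the continuous 12-36 h
#' noon-to-noon axis and reported modulo 24.  Duration is actual sleep time
#' (hours); Efficiency = Duration / (Wakeup - Onset); NWB counts maximal
#' wake runs of at least `nwb_min_wake` minutes inside the period; NSB
#' counts maximal runs of sleep minutes.
#'
#' @param records list of `sleep_record` objects (NULL entries = missing
#'   nights, dropped).
#' @param nwb_min_wake minimum wake-run length (minutes) counted as a wake
#'   bout; default 5.
#' @param nsb_min_wake minimum wake-run length that splits sleep blocks;
#'   default 1 (any wake minute).
#' @return named numeric vector `Onset, Wakeup, Duration, Midpoint,
#'   Efficiency, NWB, NSB`, plus attribute `n_nights`.
#' @export
sleep_summary <- function(records, nwb_min_wake = 5L, nsb_min_wake = 1L) {
  records <- Filter(Negate(is.null), records)
  if (!length(records)) stop("no non-missing nights", call. = FALSE)
  per_night <- t(vapply(records, night_features, numeric(7L),
                        nwb_min_wake = nwb_min_wake, nsb_min_wake = nsb_min_wake))
  out <- colMeans(per_night)
  out[c("Onset", "Wakeup", "Midpoint")] <- out[c("Onset", "Wakeup", "Midpoint")] %% 24
  attr(out, "n_nights") <- length(records)
  out
}

#' Read per-night sleep annotations (GGIR-style summary CSV)
#'
#' Dual input path that bypasses [detect_sleep_period()].  Expects columns
#' `subject, date, onset_hhmm, wakeup_hhmm` and optionally `efficiency`.
#' Onset/wakeup are clock times `HH:MM`; onsets before noon are interpreted
#' as after midnight (mapped to the 24-36 range of the noon-to-noon axis).
#'
#' @param path path to the CSV file.
#' @return data.frame `subject, date, onset, wakeup` with hours on the
#'   12-36 noon-to-noon axis (plus `efficiency` when present).
#' @export
read_sleep_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "date", "onset_hhmm", "wakeup_hhmm")
  if (!all(need %in% names(df)))
    stop("annotation CSV must have columns subject, date, onset_hhmm, wakeup_hhmm",
         call. = FALSE)
  hhmm_to_hours <- function(x, rows) {
    parts <- strsplit(x, ":", fixed = TRUE)
    ok <- lengths(parts) == 2L
    if (any(!ok)) stop_rows("unparseable HH:MM time", rows[!ok])
    h <- as.numeric(vapply(parts, `[`, "", 1L)) +
      as.numeric(vapply(parts, `[`, "", 2L)) / 60
    ifelse(h < 12, h + 24, h)
  }
  out <- data.frame(subject = as.character(df$subject), date = df$date,
                    onset = hhmm_to_hours(df$onset_hhmm, seq_len(nrow(df))),
                    wakeup = hhmm_to_hours(df$wakeup_hhmm, seq_len(nrow(df))))
  if (any(out$wakeup <= out$onset))
    stop_rows("wakeup must be after onset", which(out$wakeup <= out$onset))
  if ("efficiency" %in% names(df)) out$efficiency <- as.numeric(df$efficiency)
  out
}

# Build a sleep_record from an annotated window using epoch counts for the
# minute-level sleep/wake flags.
annotation_to_record <- function(day_counts, onset, wakeup, theta_sleep = 10) {
  lo <- max(1L, round((onset - 12) * 60) + 1L)
  hi <- min(1440L, round((wakeup - 12) * 60))
  if (hi <= lo) return(NULL)
  structure(list(onset = 12 + (lo - 1L) / 60, wakeup = 12 + hi / 60,
                 start_idx = lo, end_idx = hi,
                 sleep_flags = day_counts[lo:hi] < theta_sleep),
            class = "sleep_record")
}

# Sleep records for one subject across valid days: detected from counts or
# taken from annotations when provided.
subject_sleep_records <- function(series, windows, annotations = NULL,
                                  theta_sleep = 10, smooth_width = 11,
                                  min_period = 180, max_gap = 30) {
  vw <- windows[windows$valid, , drop = FALSE]
  ann <- if (!is.null(annotations))
    annotations[annotations$subject == series$subject_id, , drop = FALSE]
  lapply(seq_len(nrow(vw)), function(i) {
    day <- series$counts[vw$start_idx[i]:vw$end_idx[i]]
    if (!is.null(ann) && nrow(ann) >= i) {
      annotation_to_record(day, ann$onset[i], ann$wakeup[i], theta_sleep)
    } else {
      detect_sleep_period(day, theta_sleep = theta_sleep,
                          smooth_width = smooth_width,
                          min_period = min_period, max_gap = max_gap)
    }
  })
}
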