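# Cohort-level feature extraction: applies wear/inclusion filters and
# assembles the subjects x features table partitioned into the SL (7),
# PA (7) and CR (14) blocks.

SL_FEATURES <- c("Onset", "Wakeup", "Duration", "Midpoint", "Efficiency",
                 "NWB", "NSB")
PA_FEATURES <- c("TAC", "TLAC", "TST", "LiPA", "MVPA", "SATP", "ASTP")
CR_FEATURES <- c("fPC1", "fPC2", "fPC3", "fPC4", "RA", "IV", "IS",
                 "Mesor", "Amp", "Acro", "L5", "M10", "L5Time", "M10Time")

#' Extract the full accelerometry feature battery for a cohort
#'
#' Runs day segmentation, the valid-day inclusion filter, sleep-period
#' detection (or annotation ingestion), and the per-domain feature
#' computations, then assembles the subject x feature table.  Per-day
#' features are averaged across valid days; fPC scores are computed across
#' subjects from the log-scale diurnal profiles.
#'
#' @param series list of [epoch_series()] (one per subject).
#' @param annotations optional per-night sleep annotations from
#'   [read_sleep_annotations()]; when present they bypass detection.
#' @param min_valid_days inclusion threshold (default 7).
#' @param theta_sleep,smooth_width,min_period,max_gap sleep-detection
#'   parameters, see [detect_sleep_period()].
#' @param theta_sed,theta_mvpa activity count thresholds, see
#'   [pa_composition()].
#' @param wake_only compute fragmentation over wake time only (outside the
#'   sleep period) instead of the full 24-h day.  Default `FALSE`.
#' @param n_fpc number of diurnal fPC scores (default 4).
#' @param fpc_smooth smoothing width for the fPCA (minutes, default 30).
#' @return list with `features` (data.frame: `subject` + 28 feature
#'   columns, plus centered `L5Time_c`/`M10Time_c` variants), `inclusion`
#'   (per-subject valid-day counts), `fpca` (component curves and variance
#'   shares) and `windows` (the pooled day-window table).
#' @export
extract_features <- function(series, annotations = NULL, min_valid_days = 7L,
                             theta_sleep = 10, smooth_width = 11,
                             min_period = 180, max_gap = 30,
                             theta_sed = 50, theta_mvpa = 1000,
                             wake_only = FALSE, n_fpc = 4L, fpc_smooth = 30L) {
  stopifnot(length(series) >= 1L)
  windows_list <- lapply(series, segment_days)
  windows <- do.call(rbind, windows_list)
  incl <- apply_inclusion(windows, min_valid_days)
  keep <- vapply(series, function(s) s$subject_id %in% incl$included, logical(1L))
  series <- series[keep]
  windows_list <- windows_list[keep]

  rows <- vector("list", length(series))
  profiles <- matrix(0, length(series), 1440L)
  for (i in seq_along(series)) {
    s <- series[[i]]
    w <- windows_list[[i]]
    recs <- subject_sleep_records(s, w, annotations, theta_sleep,
                                  smooth_width, min_period, max_gap)
    sl <- tryCatch(sleep_summary(recs),
                   error = function(e) {
                     out <- rep(NA_real_, 7L)
                     names(out) <- SL_FEATURES
                     out
                   })
    # timing features on the continuous noon-to-noon axis (23.4 h onset
    # and 0.2 h onset stay 1440 min apart, not adjacent after z-scoring);
    # values below noon map back to the 24-36 range
    for (v in c("Onset", "Wakeup", "Midpoint"))
      if (is.finite(sl[v]) && sl[v] < 12) sl[v] <- sl[v] + 24
    pa <- subject_pa_features(s, w, theta_sed, theta_mvpa,
                              wake_only = wake_only, sleep_records = recs)
    prof <- subject_diurnal_profile(s, w)
    hr <- subject_hourly(s, w)
    cr1 <- cosinor_fit(s$counts, ((start_minute_of_day(s) + seq_along(s$counts) - 1L) %% 1440L) / 60,
                       wear = s$wear & in_valid_day(s, w))
    cr2 <- iv_is(hr$hourly, hr$hour)
    cr3 <- l5_m10(prof$count)
    profiles[i, ] <- prof$log
    rows[[i]] <- c(sl[SL_FEATURES], pa[PA_FEATURES], cr1, cr2, cr3)
  }
  feat <- as.data.frame(do.call(rbind, rows))
  fp <- diurnal_fpca(profiles, k = n_fpc, smooth_width = fpc_smooth)
  for (j in seq_len(n_fpc)) feat[[paste0("fPC", j)]] <- fp$scores[, j]
  feat$subject <- vapply(series, `[[`, "", "subject_id")
  feat$L5Time_c <- feat$L5Time - mean(feat$L5Time, na.rm = TRUE)
  feat$M10Time_c <- feat$M10Time - mean(feat$M10Time, na.rm = TRUE)
  feat <- feat[, c("subject", SL_FEATURES, PA_FEATURES, CR_FEATURES,
                   "L5Time_c", "M10Time_c")]
  rownames(feat) <- NULL
  list(features = feat, inclusion = incl$counts, fpca = fp, windows = windows)
}

# Logical mask: minutes belonging to a valid day window.
in_valid_day <- function(series, windows) {
  ok <- logical(length(series$counts))
  vw <- windows[windows$valid, , drop = FALSE]
  for (i in seq_len(nrow(vw))) ok[vw$start_idx[i]:vw$end_idx[i]] <- TRUE
  ok
}

#' Partition a feature table into the SL/PA/CR blocks
#'
#' @param features data.frame with a `subject` column and the 28 feature
#'   columns named as in [extract_features()] (extra columns are ignored).
#' @return An object of class `feature_blocks`: list with `subjects` and
#'   `blocks` (named list of matrices `SL` n x 7, `PA` n x 7, `CR` n x 14).
#' @export
feature_blocks <- function(features) {
  miss <- setdiff(c(SL_FEATURES, PA_FEATURES, CR_FEATURES), names(features))
  if (length(miss)) stop("missing feature columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  as_block <- function(cols) {
    m <- as.matrix(features[, cols, drop = FALSE])
    rownames(m) <- features$subject
    m
  }
  structure(list(subjects = as.character(features$subject),
                 blocks = list(SL = as_block(SL_FEATURES),
                               PA = as_block(PA_FEATURES),
                               CR = as_block(CR_FEATURES))),
            class = "feature_blocks")
}

#' @export
print.feature_blocks <- function(x, ...) {
  dims <- vapply(x$blocks, ncol, integer(1L))
  cat(sprintf("<feature_blocks> %d subjects; blocks: %s\n", length(x$subjects),
              paste(sprintf("%s (%d)", names(dims), dims), collapse = ", ")))
  invisible(x)
}

#' Write the feature table to CSV (one row per subject, Table-style names)
#' @param features feature data.frame.
#' @param path output path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
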