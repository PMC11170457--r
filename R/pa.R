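# Physical-activity features: volume (TAC, TLAC), composition
# (TST, LiPA, MVPA) and fragmentation (SATP, ASTP).
#
# All features are computed per day over worn minutes only (non-wear
# minutes are excluded from numerators and denominators, not imputed) and
# averaged across valid days.  TST here is total sedentary time over the
# full 24-h day, including the sleep period; a `wake_only` switch restricts
# fragmentation to minutes outside the detected sleep period.

#' Daily activity volume
#'
#' @param counts numeric minute counts for one day window.
#' @param wear parallel logical wear vector (default: all worn).
#' @return named vector `TAC` (sum of counts over worn minutes) and
#'   `TLAC` (sum of `log(1 + count)`).
#' @export
pa_volume <- function(counts, wear = NULL) {
  if (is.null(wear)) wear <- rep(TRUE, length(counts))
  x <- counts[wear]
  c(TAC = sum(x), TLAC = sum(log1p(x)))
}

#' Daily activity composition
#'
#' Classifies each worn minute as sedentary (`count < theta_sed`), light
#' (`theta_sed <= count < theta_mvpa`) or moderate-to-vigorous
#' (`count >= theta_mvpa`) and returns minutes per class.  The three class
#' counts sum exactly to the number of worn minutes (1440 for a fully worn
#' day).
#'
#' @inheritParams pa_volume
#' @param theta_sed sedentary/light count threshold (default 50).
#' @param theta_mvpa light/MVPA count threshold (default 1000).
#' @return named vector `TST`, `LiPA`, `MVPA` in minutes.
#' @export
pa_composition <- function(counts, wear = NULL, theta_sed = 50, theta_mvpa = 1000) {
  if (!(theta_sed > 0 && theta_sed < theta_mvpa))
    stop("thresholds must satisfy 0 < theta_sed < theta_mvpa", call. = FALSE)
  if (is.null(wear)) wear <- rep(TRUE, length(counts))
  x <- counts[wear]
  c(TST = sum(x < theta_sed),
    LiPA = sum(x >= theta_sed & x < theta_mvpa),
    MVPA = sum(x >= theta_mvpa))
}

#' Daily activity fragmentation
#'
#' Two-state (sedentary/active by `theta_sed`) transition probabilities:
#' `SATP` = sedentary-to-active transitions / sedentary minutes, `ASTP` =
#' active-to-sedentary transitions / active minutes.  Transitions are
#' counted between consecutive in-scope minutes only; the final minute of a
#' run of in-scope minutes contributes to the denominator but has no
#' transition.
#'
#' @inheritParams pa_composition
#' @param scope optional logical vector restricting the minutes considered
#'   (e.g. wake-time only); combined with `wear`.
#' @return named vector `SATP`, `ASTP`; `NA` when the day has no sedentary
#'   or no active minute in scope.
#' @export
pa_fragmentation <- function(counts, wear = NULL, theta_sed = 50, scope = NULL) {
  if (is.null(wear)) wear <- rep(TRUE, length(counts))
  keep <- wear & (scope %||% rep(TRUE, length(counts)))
  active <- counts >= theta_sed
  n_sed <- sum(keep & !active)
  n_act <- sum(keep & active)
  if (n_sed == 0L || n_act == 0L) return(c(SATP = NA_real_, ASTP = NA_real_))
  i <- seq_len(length(counts) - 1L)
  pair <- keep[i] & keep[i + 1L]              # adjacent in-scope pairs only
  sa <- sum(pair & !active[i] & active[i + 1L])
  as_ <- sum(pair & active[i] & !active[i + 1L])
  c(SATP = sa / n_sed, ASTP = as_ / n_act)
}

# Per-subject PA feature vector averaged over valid days.
subject_pa_features <- function(series, windows, theta_sed = 50,
                                theta_mvpa = 1000, wake_only = FALSE,
                                sleep_records = NULL) {
  vw <- windows[windows$valid, , drop = FALSE]
  rows <- lapply(seq_len(nrow(vw)), function(i) {
    idx <- vw$start_idx[i]:vw$end_idx[i]
    counts <- series$counts[idx]
    wear <- series$wear[idx]
    scope <- NULL
    if (wake_only) {
      rec <- if (!is.null(sleep_records)) sleep_records[[i]]
      scope <- rep(TRUE, length(counts))
      if (!is.null(rec)) scope[rec$start_idx:rec$end_idx] <- FALSE
    }
    c(pa_volume(counts, wear),
      pa_composition(counts, wear, theta_sed, theta_mvpa),
      pa_fragmentation(counts, wear, theta_sed, scope))
  })
  m <- do.call(rbind, rows)
  colMeans(m, na.rm = TRUE)
}
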