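# Circadian-rhythm features: single-harmonic cosinor (Mesor, Amp, Acro),
# nonparametric rhythm metrics (IV, IS, RA, L5, M10, L5Time, M10Time) and
# functional principal component scores of the diurnal activity profile
# (fPC1-fPC4).

#' Single-harmonic cosinor fit
#'
#' Least-squares fit of \eqn{x(t) = M + \beta_c \cos(\omega t) + \beta_s
#' \sin(\omega t)} with \eqn{\omega = 2\pi/24\,h^{-1}}.  The acrophase is
#' reported as negative radians: a peak at clock hour \eqn{h} gives
#' \eqn{Acro = -2\pi h/24 \in (-2\pi, 0]}, so the population value
#' \eqn{-3.65} corresponds to a peak shortly before 2 PM.
#'
#' @param counts numeric counts.
#' @param t_hours clock time of each count, in hours.
#' @param wear optional logical wear vector; non-worn minutes are dropped.
#' @return named vector `Mesor`, `Amp`, `Acro` (`Acro` is `NA` for constant
#'   input, where the phase is undefined).
#' @export
cosinor_fit <- function(counts, t_hours, wear = NULL) {
  if (!is.null(wear)) {
    counts <- counts[wear]
    t_hours <- t_hours[wear]
  }
  stopifnot(length(counts) == length(t_hours), length(counts) >= 3L)
  w <- 2 * pi / 24
  X <- cbind(1, cos(w * t_hours), sin(w * t_hours))
  beta <- stats::lm.fit(X, counts)$coefficients
  amp <- sqrt(beta[2L]^2 + beta[3L]^2)
  if (!is.finite(amp) || amp < 1e-12) {
    return(c(Mesor = unname(beta[1L]), Amp = 0, Acro = NA_real_))
  }
  t_peak <- unname(atan2(beta[3L], beta[2L]) * 24 / (2 * pi)) %% 24
  c(Mesor = unname(beta[1L]), Amp = unname(amp),
    Acro = -2 * pi * t_peak / 24)
}

#' Intradaily variability and interdaily stability
#'
#' Computed on an hourly-binned series.  With \eqn{x_i} the chronological
#' hourly means (\eqn{N} values) and \eqn{\bar x_h} the mean over days at
#' clock hour \eqn{h}:
#' \deqn{IV = N \sum_{i\ge 2} (x_i - x_{i-1})^2 / ((N-1)\sum_i (x_i-\bar x)^2)}
#' \deqn{IS = N \sum_h (\bar x_h - \bar x)^2 / (24 \sum_i (x_i - \bar x)^2)}
#'
#' @param hourly numeric vector of hourly means in chronological order
#'   (NA allowed; pairs with an NA are dropped from the IV numerator).
#' @param hour_of_day integer 0-23 clock hour of each entry.
#' @return named vector `IV`, `IS`; `NA` for a constant series.
#' @export
iv_is <- function(hourly, hour_of_day) {
  stopifnot(length(hourly) == length(hour_of_day), length(hourly) >= 48L)
  ok <- is.finite(hourly)
  x <- hourly[ok]
  h <- hour_of_day[ok]
  n <- length(x)
  ss <- sum((x - mean(x))^2)
  if (ss < 1e-12) return(c(IV = NA_real_, IS = NA_real_))
  d <- diff(hourly)                       # NA where either neighbour is NA
  contiguous <- d[is.finite(d)]
  iv <- n * sum(contiguous^2) / ((n - 1) * ss)
  hm <- tapply(x, factor(h, levels = 0:23), mean)
  hm <- hm[is.finite(hm)]
  is_ <- n * sum((hm - mean(x))^2) / (24 * ss)
  c(IV = iv, IS = unname(is_))
}

#' L5/M10 window statistics and relative amplitude
#'
#' Scans all wrap-around windows of the 1440-minute average day: `M10` is
#' the maximum mean over 600-minute windows, `L5` the minimum mean over
#' 300-minute windows; times are window midpoints in clock hours (ties
#' resolved to the earliest midpoint).  `RA = (M10 - L5)/(M10 + L5)`.
#'
#' @param profile numeric vector of length 1440: mean counts at each clock
#'   minute (index 1 = 00:00).
#' @return named vector `L5`, `M10`, `L5Time`, `M10Time`, `RA` (`RA` is
#'   `NA` for an all-zero profile).
#' @export
l5_m10 <- function(profile) {
  stopifnot(length(profile) == 1440L)
  pick <- function(w, maximise) {
    means <- circular_roll_mean(profile, w)
    target <- if (maximise) max(means) else min(means)
    cand <- which(abs(means - target) < 1e-12)
    mids <- ((cand - 1 + w / 2) %% 1440) / 60
    i <- cand[which.min(mids)]
    c(value = means[i], time = ((i - 1 + w / 2) %% 1440) / 60)
  }
  m10 <- pick(600L, TRUE)
  l5 <- pick(300L, FALSE)
  ra <- if (m10[["value"]] + l5[["value"]] > 0)
    (m10[["value"]] - l5[["value"]]) / (m10[["value"]] + l5[["value"]])
  else NA_real_
  c(L5 = l5[["value"]], M10 = m10[["value"]],
    L5Time = l5[["time"]], M10Time = m10[["time"]], RA = ra)
}

# Mean diurnal profiles for one subject across valid days: per clock
# minute, mean of count and of log1p(count) over worn minutes.
subject_diurnal_profile <- function(series, windows) {
  vw <- windows[windows$valid, , drop = FALSE]
  cm <- clock_minutes(series)
  sum_cnt <- numeric(1440L); sum_log <- numeric(1440L); n_obs <- numeric(1440L)
  for (i in seq_len(nrow(vw))) {
    idx <- vw$start_idx[i]:vw$end_idx[i]
    idx <- idx[series$wear[idx]]
    if (!length(idx)) next
    g <- cm[idx] + 1L                     # each clock minute at most once per day
    sum_cnt[g] <- sum_cnt[g] + series$counts[idx]
    sum_log[g] <- sum_log[g] + log1p(series$counts[idx])
    n_obs[g] <- n_obs[g] + 1
  }
  list(count = ifelse(n_obs > 0, sum_cnt / n_obs, 0),
       log = ifelse(n_obs > 0, sum_log / n_obs, 0))
}

# Chronological hourly means over valid days for one subject (NA for hours
# with no worn minutes), plus the clock hour of each entry.
subject_hourly <- function(series, windows) {
  vw <- windows[windows$valid, , drop = FALSE]
  cm <- clock_minutes(series)
  vals <- c(); hrs <- c()
  for (i in seq_len(nrow(vw))) {
    idx <- vw$start_idx[i]:vw$end_idx[i]
    hh <- cm[idx] %/% 60L
    # within a noon-to-noon window hours run 12..23,0..11; keep chronology
    ord <- ((hh - 12L) %% 24L)
    worn <- series$wear[idx]
    x <- series$counts[idx]
    hm <- vapply(sort(unique(ord)), function(o) {
      j <- ord == o & worn
      if (any(j)) mean(x[j]) else NA_real_
    }, numeric(1L))
    vals <- c(vals, hm)
    hrs <- c(hrs, (sort(unique(ord)) + 12L) %% 24L)
  }
  list(hourly = vals, hour = hrs)
}

#' Functional PCA of diurnal activity profiles
#'
#' Profiles (one row per subject, 1440 clock-minute grid, log scale) are
#' smoothed with a circular moving average, column-centered across
#' subjects, and decomposed by SVD.  Scores are the projections onto the
#' top-`k` right singular vectors; each component's sign is fixed so that
#' its loading curve has positive integral over 10:00-14:00.
#'
#' @param profiles numeric matrix, subjects x 1440.
#' @param k number of components (default 4).
#' @param smooth_width circular moving-average width in minutes (default 30).
#' @return list with `scores` (n x k), `loadings` (1440 x k, unit norm),
#'   `varshare` (length k) and `mean` (the column means).
#' @export
diurnal_fpca <- function(profiles, k = 4L, smooth_width = 30L) {
  stopifnot(is.matrix(profiles), ncol(profiles) == 1440L)
  n <- nrow(profiles)
  if (n < k + 1L) stop("need at least k + 1 subjects", call. = FALSE)
  sm <- t(apply(profiles, 1L, circular_smooth, width = smooth_width))
  mu <- colMeans(sm)
  xc <- sweep(sm, 2L, mu)
  s <- svd(xc, nu = 0L)
  if (sum(s$d > 1e-12) < k)
    stop(sprintf("requested %d components but centered profiles have rank %d",
                 k, sum(s$d > 1e-12)), call. = FALSE)
  V <- s$v[, seq_len(k), drop = FALSE]
  window <- 601:840                       # 10:00-14:00 on the minute grid
  signs <- ifelse(colSums(V[window, , drop = FALSE]) >= 0, 1, -1)
  V <- sweep(V, 2L, signs, `*`)
  scores <- xc %*% V
  colnames(scores) <- colnames(V) <- paste0("fPC", seq_len(k))
  list(scores = scores, loadings = V,
       varshare = s$d[seq_len(k)]^2 / sum(s$d^2), mean = mu)
}
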