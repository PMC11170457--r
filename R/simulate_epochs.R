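# Epoch-tier synthetic cohort: minute-level count streams with planted
# sleep periods (onset/wakeup with >= 5-min wake bouts), two-state
# sedentary/active Markov dynamics during wake time, and a diurnal cosinor
# envelope modulating active-minute counts.
#
# Count construction (one scale for all features):
#   sleep minutes        ~ round(Uniform(0, sleep_max)), below theta_sleep;
#   wake-bout minutes    ~ round(Uniform(bout_lo, bout_hi)), above theta_sleep;
#   wake sedentary       ~ round(Uniform(sed_lo, sed_hi)), between
#                          theta_sleep and theta_sed;
#   wake active          ~ round(active_floor + a_i(t) * Gamma(shape)/shape),
# where a_i(t) is chosen so that the expected wake-minute count equals the
# subject's cosinor envelope C_i(t) = m_i + a_i cos(omega (t - peak_i)).
# Because the sleep period carves a low-count trough that is not centered
# on the envelope trough, the population acrophase of the *generated*
# counts differs slightly from the envelope peak; the generator therefore
# calibrates the envelope peak numerically (from the plan alone) so that
# the plan's `acro` is the acrophase of the population mean count curve.

#' Plan for an epoch-tier synthetic cohort
#'
#' Defaults are calibrated to the reference cohort scale: sleep onset
#' 23.5 h (between-subject SD 1.0), sleep-period time 7.74 h, about two
#' >=5-min wake bouts per night, wake-time fragmentation p(S->A) = 0.07 and
#' p(A->S) = 0.25, acrophase -3.65 rad (peak just before 2 PM) and a mean
#' envelope giving roughly 42,600 counts/day.
#'
#' @param n_subjects,n_days cohort dimensions (days per subject).
#' @param onset_mean,onset_sd between-subject sleep-onset distribution
#'   (hours, noon-to-noon axis).
#' @param night_sd within-subject night-to-night onset jitter (hours).
#' @param spt_mean,spt_sd sleep-period time distribution (hours).
#' @param nwb_rate expected number of >=5-min wake bouts per night.
#' @param bout_min,bout_geom_p wake-bout length: `bout_min` plus a
#'   geometric tail.
#' @param flicker_rate expected number of short (1-4 min) wake blocks per
#'   night; these fragment the sleep period (driving NSB and Efficiency)
#'   without counting as >=5-min wake bouts.
#' @param flicker_min,flicker_max,flicker_lo,flicker_hi length (minutes)
#'   and count ranges of the short wake blocks.
#' @param day_scale_sd,day_jitter_sd day-to-day variation: log-normal SD
#'   of a daily activity multiplier (mean 1) and SD (hours) of a daily
#'   envelope-phase jitter; both lower interdaily stability toward
#'   realistic values.
#' @param p_sa,p_sa_sd,p_as,p_as_sd wake-time Markov transition
#'   probabilities per minute (between-subject mean and SD).
#' @param mesor,mesor_sd,amp_ratio,amp_ratio_sd envelope level and
#'   amplitude/mesor ratio across subjects (count scale).
#' @param acro,acro_sd population acrophase (negative radians) and
#'   between-subject SD.
#' @param gamma_shape shape of the mean-1 gamma noise on active counts.
#' @param sed_lo,sed_hi,sleep_max,bout_lo,bout_hi,active_floor count
#'   ranges for the non-active states (see construction above).
#' @param theta_sleep,theta_sed thresholds consistent with the count
#'   scale; stored in the plan so extraction can reuse them.
#' @param pure_cosinor when `TRUE`, emit noise-free counts equal to the
#'   envelope `C_i(t)` (no sleep, no states) - a closed-form check mode.
#' @param dropout_frac fraction of subjects planted with fewer than 7
#'   valid days (via trailing non-wear days).
#' @param start timestamp of the first epoch (a noon).
#' @return An `epoch_plan` list (with the calibrated envelope peak in
#'   `peak_cal`).
#' @export
epoch_plan <- function(n_subjects = 200L, n_days = 14L,
                       onset_mean = 23.5, onset_sd = 1.0, night_sd = 0.25,
                       spt_mean = 7.74, spt_sd = 0.5,
                       nwb_rate = 2, bout_min = 5L, bout_geom_p = 0.35,
                       flicker_rate = 12, flicker_min = 2L, flicker_max = 4L,
                       flicker_lo = 10, flicker_hi = 25,
                       day_scale_sd = 0.25, day_jitter_sd = 0.75,
                       p_sa = 0.07, p_sa_sd = 0.015,
                       p_as = 0.25, p_as_sd = 0.05,
                       mesor = 29.57, mesor_sd = 6,
                       amp_ratio = 0.828, amp_ratio_sd = 0.05,
                       acro = -3.65, acro_sd = 0.32,
                       gamma_shape = 5,
                       sed_lo = 11, sed_hi = 19, sleep_max = 8,
                       bout_lo = 15, bout_hi = 60, active_floor = 30,
                       theta_sleep = 10, theta_sed = 25,
                       pure_cosinor = FALSE, dropout_frac = 0,
                       start = "2020-01-01 12:00:00") {
  plan <- structure(as.list(environment()), class = "epoch_plan")
  plan$peak_cal <- calibrate_envelope_peak(plan)
  plan
}

# Population mean count curve on the 1440-minute clock grid implied by the
# plan, for a given envelope peak hour.
population_mean_curve <- function(plan, peak) {
  t_clock <- (0:1439) / 60
  tau <- ifelse(t_clock < 12, t_clock + 24, t_clock)   # noon-to-noon axis
  sd_on <- sqrt(plan$onset_sd^2 + plan$night_sd^2)
  p_sleep <- stats::pnorm(tau, plan$onset_mean, sd_on) -
    stats::pnorm(tau, plan$onset_mean + plan$spt_mean,
                 sqrt(sd_on^2 + plan$spt_sd^2))
  mean_bout_len <- plan$bout_min + (1 - plan$bout_geom_p) / plan$bout_geom_p
  p_bout <- min(1, plan$nwb_rate * mean_bout_len / (plan$spt_mean * 60))
  p_flick <- min(1, plan$flicker_rate * (plan$flicker_min + plan$flicker_max) / 2 /
                   (plan$spt_mean * 60))
  mu_sleep <- (1 - p_bout - p_flick) * plan$sleep_max / 2 +
    p_bout * (plan$bout_lo + plan$bout_hi) / 2 +
    p_flick * (plan$flicker_lo + plan$flicker_hi) / 2
  pi_act <- plan$p_sa / (plan$p_sa + plan$p_as)
  sed_mean <- (plan$sed_lo + plan$sed_hi) / 2
  # between-subject and day-level phase jitter smear the first harmonic
  smear <- plan$acro_sd^2 + (plan$day_jitter_sd * 2 * pi / 24)^2
  amp_eff <- plan$mesor * plan$amp_ratio * exp(-smear / 2)
  env <- plan$mesor + amp_eff * cos(2 * pi * (t_clock - peak) / 24)
  a_t <- pmax((env - (1 - pi_act) * sed_mean - pi_act * plan$active_floor) / pi_act, 0)
  mu_wake <- pi_act * (plan$active_floor + a_t) + (1 - pi_act) * sed_mean
  p_sleep * mu_sleep + (1 - p_sleep) * mu_wake
}

# Solve for the envelope peak hour that makes the population mean-curve
# acrophase equal the plan's target.  Uses only plan parameters.
calibrate_envelope_peak <- function(plan) {
  target_peak <- (-plan$acro * 24 / (2 * pi)) %% 24
  t_clock <- (0:1439) / 60
  f <- function(peak) {
    fit <- cosinor_fit(population_mean_curve(plan, peak), t_clock)
    dh <- ((-fit[["Acro"]] * 24 / (2 * pi)) - target_peak + 12) %% 24 - 12
    dh
  }
  stats::uniroot(f, c(target_peak - 3, target_peak + 3), tol = 1e-4)$root
}

# Exact two-state Markov sequence of length n via alternating geometric
# sojourns; state 1 = active, 0 = sedentary.
markov_states <- function(n, p_sa, p_as) {
  pi_act <- p_sa / (p_sa + p_as)
  n_runs <- max(20L, ceiling(n * (p_sa + p_as) * 1.5) + 20L)
  repeat {
    first <- stats::runif(1) < pi_act
    len_a <- stats::rgeom(n_runs, p_as) + 1L
    len_s <- stats::rgeom(n_runs, p_sa) + 1L
    lens <- as.vector(rbind(if (first) len_a else len_s,
                            if (first) len_s else len_a))
    vals <- rep(c(first, !first), length.out = length(lens))
    if (sum(lens) >= n) break
    n_runs <- n_runs * 2L
  }
  rep(vals, lens)[seq_len(n)]
}

#' Generate an epoch-tier synthetic cohort
#'
#' @param plan an [epoch_plan()].
#' @param seed integer RNG seed; `(plan, seed)` regenerates the identical
#'   cohort.
#' @return list with `series` (list of [epoch_series()]), `annotations`
#'   (per-night true onset/wakeup, in the sleep-annotation CSV dialect
#'   columns plus numeric hours) and `truth` (per-subject planted
#'   parameters and the plan).
#' @export
generate_epoch_cohort <- function(plan, seed = 1L) {
  stopifnot(inherits(plan, "epoch_plan"))
  set.seed(seed)
  n_min <- plan$n_days * 1440L
  t_clock <- rep((c(720:1439, 0:719)) / 60, plan$n_days)   # start at noon
  start <- as.POSIXct(plan$start, tz = "UTC")

  subj_ids <- sprintf("P%04d", seq_len(plan$n_subjects))
  n_drop <- round(plan$dropout_frac * plan$n_subjects)
  dropouts <- if (n_drop > 0) sample(seq_len(plan$n_subjects), n_drop) else integer(0L)

  series <- vector("list", plan$n_subjects)
  ann <- list()
  truth_sub <- list()
  for (i in seq_len(plan$n_subjects)) {
    onset_i <- stats::rnorm(1, plan$onset_mean, plan$onset_sd)
    spt_i <- max(stats::rnorm(1, plan$spt_mean, plan$spt_sd), 4)
    p_sa_i <- min(max(stats::rnorm(1, plan$p_sa, plan$p_sa_sd), 0.02), 0.3)
    p_as_i <- min(max(stats::rnorm(1, plan$p_as, plan$p_as_sd), 0.08), 0.6)
    mesor_i <- max(stats::rnorm(1, plan$mesor, plan$mesor_sd), 12)
    ratio_i <- min(max(stats::rnorm(1, plan$amp_ratio, plan$amp_ratio_sd), 0.5), 0.95)
    peak_i <- plan$peak_cal + stats::rnorm(1, 0, plan$acro_sd) * 24 / (2 * pi)

    if (plan$pure_cosinor) {
      env <- mesor_i + mesor_i * ratio_i * cos(2 * pi * (t_clock - peak_i) / 24)
      series[[i]] <- epoch_series(subj_ids[i], start, env)
      truth_sub[[i]] <- data.frame(subject = subj_ids[i], mesor = mesor_i,
                                   amp = mesor_i * ratio_i,
                                   acro = -2 * pi * (peak_i %% 24) / 24)
      next
    }
    # day-specific envelope: phase jitter and a mean-1 activity multiplier
    day_of <- rep(seq_len(plan$n_days), each = 1440L)
    peak_d <- peak_i + stats::rnorm(plan$n_days, 0, plan$day_jitter_sd)
    scale_d <- stats::rlnorm(plan$n_days, -plan$day_scale_sd^2 / 2,
                             plan$day_scale_sd)
    env <- mesor_i + mesor_i * ratio_i *
      cos(2 * pi * (t_clock - peak_d[day_of]) / 24)

    pi_i <- p_sa_i / (p_sa_i + p_as_i)
    sed_mean <- (plan$sed_lo + plan$sed_hi) / 2
    counts <- numeric(n_min)
    sleep_mask <- logical(n_min)
    bout_mask <- logical(n_min)
    flick_mask <- logical(n_min)
    for (d in seq_len(plan$n_days)) {
      on_d <- min(max(onset_i + stats::rnorm(1, 0, plan$night_sd), 20), 27)
      off_d <- min(on_d + max(spt_i + stats::rnorm(1, 0, 0.3), 4), 35.5)
      lo <- (d - 1L) * 1440L + round((on_d - 12) * 60) + 1L
      hi <- (d - 1L) * 1440L + round((off_d - 12) * 60)
      hi <- min(hi, n_min)
      sleep_mask[lo:hi] <- TRUE
      # store the minute-grid values actually planted
      on_d <- 12 + (lo - (d - 1L) * 1440L - 1L) / 60
      off_d <- 12 + (hi - (d - 1L) * 1440L) / 60
      ann[[length(ann) + 1L]] <- data.frame(
        subject = subj_ids[i], date = format(start + (d - 1) * 86400, "%Y-%m-%d"),
        onset = on_d, wakeup = off_d)
      span <- hi - lo + 1L
      nb <- stats::rpois(1, plan$nwb_rate)
      if (nb > 0) for (b in seq_len(nb)) {
        len <- plan$bout_min + stats::rgeom(1, plan$bout_geom_p)
        if (span <= len + 20L) next
        st <- lo + 10L + sample.int(span - len - 20L, 1L)
        if (any(bout_mask[st:(st + len - 1L)])) next
        bout_mask[st:(st + len - 1L)] <- TRUE
      }
      nf <- stats::rpois(1, plan$flicker_rate)
      if (nf > 0) for (b in seq_len(nf)) {
        len <- sample(plan$flicker_min:plan$flicker_max, 1L)
        if (span <= len + 20L) next
        st <- lo + 10L + sample.int(span - len - 20L, 1L)
        if (any(bout_mask[st:(st + len - 1L)]) || any(flick_mask[st:(st + len - 1L)])) next
        flick_mask[st:(st + len - 1L)] <- TRUE
      }
    }
    wake <- !sleep_mask
    n_wake <- sum(wake)
    state <- markov_states(n_wake, p_sa_i, p_as_i)

    counts[sleep_mask] <- stats::runif(sum(sleep_mask), 0, plan$sleep_max)
    counts[bout_mask] <- stats::runif(sum(bout_mask), plan$bout_lo, plan$bout_hi)
    counts[flick_mask] <- stats::runif(sum(flick_mask), plan$flicker_lo,
                                       plan$flicker_hi)
    wk_idx <- which(wake)
    sed_idx <- wk_idx[!state]
    act_idx <- wk_idx[state]
    counts[sed_idx] <- stats::runif(length(sed_idx), plan$sed_lo, plan$sed_hi)
    a_t <- pmax((env[act_idx] - (1 - pi_i) * sed_mean - pi_i * plan$active_floor) / pi_i, 0)
    counts[act_idx] <- plan$active_floor +
      a_t * scale_d[day_of[act_idx]] *
        stats::rgamma(length(act_idx), shape = plan$gamma_shape,
                      rate = plan$gamma_shape)
    counts <- round(counts)

    wear <- rep(TRUE, n_min)
    if (i %in% dropouts) {
      n_valid <- sample(3:6, 1L)                 # planted below the 7-day rule
      wear[(n_valid * 1440L + 1L):n_min] <- FALSE
    }
    series[[i]] <- epoch_series(subj_ids[i], start, counts, wear)
    truth_sub[[i]] <- data.frame(subject = subj_ids[i], onset = onset_i,
                                 spt = spt_i, p_sa = p_sa_i, p_as = p_as_i,
                                 mesor = mesor_i, amp = mesor_i * ratio_i,
                                 peak = peak_i %% 24,
                                 dropout = i %in% dropouts)
  }
  names(series) <- subj_ids
  annotations <- if (length(ann)) do.call(rbind, ann) else NULL
  if (!is.null(annotations)) {
    hh <- function(h) sprintf("%02d:%02d", floor(h %% 24), round((h %% 1) * 60) %% 60)
    annotations$onset_hhmm <- hh(annotations$onset)
    annotations$wakeup_hhmm <- hh(annotations$wakeup)
  }
  list(series = series, annotations = annotations,
       truth = list(plan = plan, seed = seed,
                    subjects = do.call(rbind, truth_sub)))
}
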