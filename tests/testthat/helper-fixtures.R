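# Fixture builders and independent brute-force oracles used across tests.

# Tiny epoch CSV with three subjects of stated lengths, starting at noon.
write_epoch_fixture <- function(path, lengths = c(A = 2880L, B = 1500L, C = 4320L),
                                start = "2020-03-01 12:00:00") {
  start <- as.POSIXct(start, tz = "UTC")
  set.seed(42)
  rows <- lapply(names(lengths), function(sid) {
    n <- lengths[[sid]]
    data.frame(subject = sid,
               timestamp = format(start + 60 * (seq_len(n) - 1L),
                                  "%Y-%m-%d %H:%M:%S"),
               count = rpois(n, 20),
               wear = TRUE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  path
}

# One noon-to-noon day of counts with a planted sleep window [onset, wakeup)
# given in hours on the 12-36 axis; day counts high, sleep counts zero.
planted_day <- function(onset, wakeup, day_count = 200, sleep_count = 0) {
  counts <- rep(day_count, 1440L)
  lo <- round((onset - 12) * 60) + 1L
  hi <- round((wakeup - 12) * 60)
  counts[lo:hi] <- sleep_count
  counts
}

# Brute-force run counter for sleep/wake flag sequences.
brute_runs <- function(flags) {
  if (!length(flags)) return(list(n_sleep = 0L, wake_lengths = integer(0L)))
  r <- rle(flags)
  list(n_sleep = sum(r$values),
       wake_lengths = r$lengths[!r$values])
}

# Exhaustive wrap-around window scan for L5/M10 (independent of the
# cumulative-sum implementation).
brute_l5m10 <- function(profile) {
  n <- length(profile)
  scan <- function(w, maximise) {
    best_val <- if (maximise) -Inf else Inf
    best_mid <- Inf
    for (s in seq_len(n)) {
      idx <- ((s - 1L + 0:(w - 1L)) %% n) + 1L
      v <- mean(profile[idx])
      mid <- ((s - 1 + w / 2) %% n) / 60
      better <- if (maximise) v > best_val + 1e-12 else v < best_val - 1e-12
      tie <- abs(v - best_val) <= 1e-12 && mid < best_mid
      if (better || tie) {
        best_val <- v
        best_mid <- mid
      }
    }
    c(value = best_val, time = best_mid)
  }
  list(m10 = scan(600L, TRUE), l5 = scan(300L, FALSE))
}

# Random raw feature blocks (no planted structure) for property tests.
random_blocks <- function(n = 80L, p = c(SL = 5L, PA = 4L, CR = 6L), seed = 1L) {
  set.seed(seed)
  blocks <- lapply(p, function(pk) {
    m <- matrix(rnorm(n * pk), n, pk)
    colnames(m) <- paste0("f", seq_len(pk))
    m
  })
  structure(list(subjects = sprintf("R%03d", seq_len(n)), blocks = blocks),
            class = "feature_blocks")
}

expect_frob_small <- function(x, tol) expect_lt(sqrt(sum(x^2)), tol)
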