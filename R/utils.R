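# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

frob2 <- function(x) sum(x^2)

#' Runs of TRUE values in a logical vector
#'
#' @param flags logical vector (NA treated as FALSE).
#' @return data.frame with columns `start`, `end`, `length`, one row per
#'   maximal run of TRUE.
#' @keywords internal
logical_runs <- function(flags) {
  flags[is.na(flags)] <- FALSE
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

# Rolling mean over wrap-around windows of length `w`.  Element i is the mean
# of x[i], x[i+1], ..., x[i+w-1] with circular indexing.
circular_roll_mean <- function(x, w) {
  n <- length(x)
  stopifnot(w >= 1, w <= n)
  cs <- cumsum(c(0, x, x[seq_len(w - 1)]))
  (cs[(w + 1):(n + w)] - cs[seq_len(n)]) / w
}

# Circular centered moving average (smoothing for diurnal profiles).
circular_smooth <- function(x, width) {
  if (width <= 1) return(x)
  n <- length(x)
  half <- floor(width / 2)
  w <- 2 * half + 1
  xx <- c(x[(n - half + 1):n], x, x[1:half])
  cs <- cumsum(c(0, xx))
  (cs[(w + 1):(n + w)] - cs[seq_len(n)]) / w
}

# Deterministic sub-seed derived from a master seed (kept below 2^31).
derive_seed <- function(seed, k) {
  (as.integer(seed) + 104729L * as.integer(k)) %% 2147483647L
}

stop_rows <- function(msg, rows) {
  stop(sprintf("%s (row%s %s)", msg, if (length(rows) > 1) "s" else "",
               paste(utils::head(rows, 5L), collapse = ", ")), call. = FALSE)
}
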