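test_that("epoch CSV round-trips and validates its contract", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_epoch_fixture(f, lengths = c(A = 2880L, B = 1500L, C = 4320L))
  series <- read_epochs(f)
  expect_named(series, c("A", "B", "C"))
  expect_equal(vapply(series, length, integer(1L)),
               c(A = 2880L, B = 1500L, C = 4320L))

  f2 <- withr::local_tempfile(fileext = ".csv")
  write_epochs(series, f2)
  again <- read_epochs(f2)
  expect_equal(lapply(again, `[[`, "counts"), lapply(series, `[[`, "counts"))
  expect_equal(lapply(again, `[[`, "wear"), lapply(series, `[[`, "wear"))
  expect_equal(again$A$start, series$A$start)
})

test_that("malformed epoch rows are rejected with row-addressed messages", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(subject = "A",
                   timestamp = format(as.POSIXct("2020-01-01 12:00", tz = "UTC") +
                                        60 * 0:4, "%Y-%m-%d %H:%M:%S"),
                   count = c(1, 2, -3, 4, 5))
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_epochs(f), "negative count.*row 3")

  df$count <- 1:5
  df$timestamp[2] <- "not-a-time"
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_epochs(f), "unparseable timestamp.*row 2")

  df$timestamp[2] <- df$timestamp[1]           # duplicated minute
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_epochs(f), "duplicated minute")
})

test_that("gaps are filled as non-wear zero-count minutes", {
  f <- withr::local_tempfile(fileext = ".csv")
  ts <- as.POSIXct("2020-01-01 12:00", tz = "UTC") + 60 * c(0, 1, 5)
  utils::write.csv(data.frame(subject = "A",
                              timestamp = format(ts, "%Y-%m-%d %H:%M:%S"),
                              count = c(3, 4, 9)), f, row.names = FALSE)
  s <- read_epochs(f)$A
  expect_length(s$counts, 6L)
  expect_equal(s$counts, c(3, 4, 0, 0, 0, 9))
  expect_equal(s$wear, c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
})

test_that("day segmentation partitions the series on the noon grid", {
  # starts 10:00, i.e. 120 minutes before its day ends at noon
  s <- epoch_series("A", "2020-01-01 10:00:00", rpois(3000, 5))
  w <- segment_days(s)
  expect_equal(w$start_idx[1L], 1L)
  expect_equal(w$end_idx[nrow(w)], 3000L)
  expect_equal(sum(w$n_minutes), 3000L)
  # contiguity: each window starts where the previous ended
  expect_equal(w$start_idx[-1L], w$end_idx[-nrow(w)] + 1L)
  expect_equal(w$n_minutes[1L], 120L)           # leading partial
  expect_false(w$valid[1L])
  expect_true(all(w$n_minutes[c(2L, 3L)] == 1440L))
})

test_that("day validity uses the strict 16-hour wear rule", {
  base <- epoch_series("A", "2020-01-01 12:00:00", rep(10, 1440L))
  wear961 <- c(rep(TRUE, 961L), rep(FALSE, 479L))
  s <- epoch_series("A", "2020-01-01 12:00:00", rep(10, 1440L), wear961)
  expect_true(segment_days(s)$valid)
  wear960 <- c(rep(TRUE, 960L), rep(FALSE, 480L))
  s <- epoch_series("A", "2020-01-01 12:00:00", rep(10, 1440L), wear960)
  expect_false(segment_days(s)$valid)
  expect_true(all(segment_days(base)$valid))
})

test_that("inclusion filter applies the 7-valid-day boundary and is monotone", {
  mk <- function(days) epoch_series("X", "2020-01-01 12:00:00",
                                    rep(5, days * 1440L))
  w6 <- segment_days(mk(6)); w6$subject <- "six"
  w7 <- segment_days(mk(7)); w7$subject <- "seven"
  w14 <- segment_days(mk(14)); w14$subject <- "fourteen"
  windows <- rbind(w6, w7, w14)
  incl <- apply_inclusion(windows)
  expect_setequal(incl$included, c("seven", "fourteen"))
  expect_equal(incl$counts$valid_days[incl$counts$subject == "six"], 6L)

  # monotone: raising the threshold never adds subjects
  prev <- incl$included
  for (k in 8:14) {
    cur <- tryCatch(apply_inclusion(windows, k)$included,
                    error = function(e) character(0L))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  expect_error(apply_inclusion(w6, 7L), "empty")
})

test_that("a 14-day generated subject spans exactly 20160 minutes", {
  co <- generate_epoch_cohort(epoch_plan(n_subjects = 1L, n_days = 14L), seed = 2)
  expect_length(co$series[[1L]]$counts, 14L * 1440L)
  w <- segment_days(co$series[[1L]])
  expect_equal(nrow(w), 14L)
  expect_true(all(w$valid))
})

test_that("covariate reader enforces types and levels", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(subject = c("a", "b"), age = c(50, 60),
                              sex = c("female", "male"), bmi = c(24, 28),
                              group = c("none", "current"),
                              anxiety = c(FALSE, TRUE), sud = FALSE),
                   f, row.names = FALSE)
  cv <- read_covariates(f)
  expect_s3_class(cv$group, "factor")
  expect_equal(levels(cv$group), c("none", "current", "remitted"))

  utils::write.csv(data.frame(subject = "a", age = 50, sex = "f", bmi = 24,
                              group = "none", anxiety = FALSE, sud = FALSE),
                   f, row.names = FALSE)
  expect_error(read_covariates(f), "sex")
})
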