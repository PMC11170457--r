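test_that("cosinor recovers a noise-free cosine to machine precision", {
  t <- (0:20159) / 60
  x <- 30 + 20 * cos(2 * pi * (t - 14) / 24)
  fit <- cosinor_fit(x, t %% 24)
  expect_equal(fit[["Mesor"]], 30, tolerance = 1e-10)
  expect_equal(fit[["Amp"]], 20, tolerance = 1e-10)
  expect_equal(fit[["Acro"]], -2 * pi * 14 / 24, tolerance = 1e-10)
  # constant input: amplitude zero, phase undefined
  flat <- cosinor_fit(rep(5, 2880L), ((0:2879) / 60) %% 24)
  expect_equal(flat[["Amp"]], 0)
  expect_true(is.na(flat[["Acro"]]))
})

test_that("cosinor recovery under Gaussian noise is within 3 linear-model SEs", {
  set.seed(21)
  t <- (0:(14 * 1440 - 1)) / 60
  w <- 2 * pi / 24
  for (i in 1:5) {
    M <- runif(1, 20, 40); A <- runif(1, 10, M - 2); peak <- runif(1, 10, 16)
    x <- M + A * cos(w * (t - peak)) + rnorm(length(t), 0, 15)
    X <- cbind(1, cos(w * (t %% 24)), sin(w * (t %% 24)))
    ls <- stats::lsfit(X, x, intercept = FALSE)
    se <- sqrt(diag(chol2inv(chol(crossprod(X))) * sum(ls$residuals^2) /
                      (length(x) - 3)))
    fit <- cosinor_fit(x, t %% 24)
    expect_lt(abs(fit[["Mesor"]] - M), 3 * se[1L])
    # amplitude SE approximated by the (conservative) max of the two
    # harmonic coefficient SEs
    expect_lt(abs(fit[["Amp"]] - A), 3 * max(se[2:3]))
    expect_lt(abs(fit[["Acro"]] - (-w * peak)), 3 * max(se[2:3]) / A * 1.5)
  }
})

test_that("IV and IS match their closed-form and structural limits", {
  # exactly repeated daily pattern: zero within-hour variance, IS = 1
  pat <- c(5, 3, 2, 2, 4, 9, 20, 35, 40, 42, 38, 36,
           35, 37, 40, 42, 41, 38, 30, 22, 15, 10, 8, 6)
  x <- rep(pat, 14L)
  r <- iv_is(x, rep(0:23, 14L))
  expect_equal(r[["IS"]], 1)

  # long pure 24-h sinusoid: IV -> 2(1 - cos(2*pi/24))
  n <- 24L * 500L
  xs <- 30 + 20 * cos(2 * pi * (seq_len(n) - 1) / 24)
  r <- iv_is(xs, (seq_len(n) - 1L) %% 24L)
  expect_equal(r[["IV"]], 2 * (1 - cos(2 * pi / 24)), tolerance = 1e-3)

  # i.i.d. noise: IV ~ 2, IS ~ 1/days
  set.seed(4)
  n <- 10000L
  xn <- rnorm(n)
  r <- iv_is(xn, (seq_len(n) - 1L) %% 24L)
  expect_equal(r[["IV"]], 2, tolerance = 0.1)
  expect_equal(r[["IS"]], 24 / n, tolerance = 24 / n)
  expect_true(all(is.na(iv_is(rep(3, 100L), (0:99) %% 24L))))
})

test_that("L5/M10 geometry on a rectangular profile", {
  p <- numeric(1440L)
  p[(8 * 60 + 1):(18 * 60)] <- 100                # active 08:00-18:00
  r <- l5_m10(p)
  expect_equal(r[["M10"]], 100)
  expect_equal(r[["M10Time"]], 13)
  expect_equal(r[["L5"]], 0)
  expect_equal(r[["RA"]], 1)                      # L5 = 0 with M10 > 0
  expect_true(is.na(l5_m10(numeric(1440L))[["RA"]]))
})

test_that("L5/M10 agrees with the exhaustive window scan, ties to earliest", {
  set.seed(9)
  for (i in 1:8) {
    prof <- as.numeric(arima.sim(list(ar = 0.95), 1440L)) + 10
    fast <- l5_m10(prof)
    slow <- brute_l5m10(prof)
    expect_equal(fast[["M10"]], slow$m10[["value"]])
    expect_equal(fast[["M10Time"]], slow$m10[["time"]])
    expect_equal(fast[["L5"]], slow$l5[["value"]])
    expect_equal(fast[["L5Time"]], slow$l5[["time"]])
  }
  # exact ties across windows resolve to the earliest midpoint: on a flat
  # profile some wrap-around window has midpoint 00:00
  r <- l5_m10(rep(7, 1440L))
  expect_equal(r[["M10Time"]], 0)
  expect_equal(r[["L5Time"]], 0)
})

test_that("RA is monotone in M10 for fixed L5", {
  prof <- numeric(1440L) + 2
  ra <- vapply(c(20, 50, 120), function(h) {
    p <- prof; p[400:1000] <- h
    l5_m10(p)[["RA"]]
  }, numeric(1L))
  expect_true(all(diff(ra) > 0))
  expect_true(all(ra >= 0 & ra <= 1))
})

test_that("diurnal fPCA centers, orthogonalises and orients components", {
  set.seed(13)
  grid <- (0:1439) / 60
  base <- 3 + 2 * sin(2 * pi * grid / 24)
  # identical profiles: all scores zero
  same <- matrix(rep(base, 10L), 10L, byrow = TRUE)
  fp0 <- diurnal_fpca(same + rnorm(length(same), 0, 1e-9), k = 2L)
  expect_lt(max(abs(fp0$scores)), 1e-6)

  # two groups differing only in profile height: fPC1 separates them with
  # the 10:00-14:00 positive-integral sign convention
  n <- 40L
  height <- c(rep(0, n / 2), rep(2, n / 2))
  profs <- t(vapply(seq_len(n), function(i)
    base + height[i] + rnorm(1440L, 0, 0.05), numeric(1440L)))
  fp <- diurnal_fpca(profs, k = 3L)
  expect_gt(abs(cor(fp$scores[, 1L], height)), 0.95)
  expect_gt(sum(fp$loadings[601:840, 1L]), 0)
  expect_gt(mean(fp$scores[height == 2, 1L]), mean(fp$scores[height == 0, 1L]))

  # scores are column-centered and mutually orthogonal
  expect_lt(max(abs(colMeans(fp$scores))), 1e-8)
  cp <- crossprod(fp$scores)
  expect_lt(max(abs(cp[upper.tri(cp)])) / max(diag(cp)), 1e-8)
})

test_that("a planted timing shift loads on an early functional component", {
  set.seed(17)
  grid <- (0:1439) / 60
  n <- 40L
  shift <- rnorm(n, 0, 1.5)
  profs <- t(vapply(seq_len(n), function(i)
    3 + 2 * sin(2 * pi * (grid - shift[i]) / 24) + rnorm(1440L, 0, 0.05),
    numeric(1440L)))
  fp <- diurnal_fpca(profs, k = 2L)
  expect_gt(max(abs(cor(fp$scores, shift))), 0.8)
})
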