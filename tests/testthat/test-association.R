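test_that("descriptive table reproduces known group summaries and tests", {
  set.seed(19)
  df <- data.frame(group = factor(rep(c("none", "current", "remitted"),
                                      times = c(60, 30, 50))),
                   age = c(rnorm(60, 60, 5), rnorm(30, 55, 5), rnorm(50, 58, 5)),
                   sex = factor(sample(c("female", "male"), 140, replace = TRUE)))
  tab <- descriptive_table(df, "group", continuous = "age", categorical = "sex")
  age_row <- tab[tab$variable == "age", ]
  expect_equal(age_row$mean_none, mean(df$age[df$group == "none"]))
  expect_equal(age_row$p_value,
               summary(aov(age ~ group, df))[[1]][["Pr(>F)"]][1])
  sex_rows <- tab[tab$variable == "sex", ]
  expect_equal(sum(sex_rows$n_none), 60)
  expect_equal(sex_rows$p_value[1],
               suppressWarnings(chisq.test(table(df$sex, df$group))$p.value))
  # percentages are computed on group denominators
  expect_equal(sum(sex_rows$pct_current), 100)
})

test_that("identical groups give F ~ 0 signal and chi-square p near 1", {
  df <- data.frame(group = factor(rep(c("a", "b"), each = 50)),
                   x = rep(seq_len(50), 2L),
                   cat = factor(rep(rep(c("u", "v"), each = 25), 2L)))
  tab <- descriptive_table(df, "group", continuous = "x", categorical = "cat")
  expect_gt(tab$p_value[tab$variable == "x"], 0.99)
  expect_equal(tab$p_value[tab$variable == "cat"][1L], 1)
})

test_that("a planted 2-SD mean shift is detected at p < 0.001", {
  set.seed(23)
  df <- data.frame(group = factor(rep(c("none", "current"), each = 100)),
                   x = c(rnorm(100), rnorm(100, 2)))
  tab <- descriptive_table(df, "group", continuous = "x")
  expect_lt(tab$p_value, 0.001)
})

test_that("cohort margin summaries pool groups by size", {
  m <- data.frame(group = c("none", "current", "remitted"),
                  n = c(100, 20, 80), female = c(40, 15, 50),
                  white = c(90, 18, 70), age_mean = c(60, 50, 55),
                  bmi_mean = c(25, 26, 27))
  s <- cohort_summary(m)
  expect_equal(s$n_total, 200)
  expect_equal(s$female_pct, 100 * 105 / 200)
  expect_equal(s$lifetime_pct, 50)
  expect_equal(s$mean_age, (100 * 60 + 20 * 50 + 80 * 55) / 200)
})

test_that("null scores give odds ratios near 1 with covering CIs", {
  plan <- feature_plan(n = 5000L, logor = c(Joint_1 = 0),
                       cov_logor = c(age = 0, female = 0, bmi = 0,
                                     anxiety = 0, sud = 0))
  co <- generate_feature_cohort(plan, seed = 25)
  fit <- fit_jive(preprocess_blocks(co$blocks), plan$r_joint, plan$r_indiv)
  res <- jive_logistic(extract_scores(fit), co$covariates,
                       contrast = "lifetime", covariate_names = character())
  expect_true(all(res$or > 0.9 & res$or < 1.1))
  expect_true(all(res$ci_low <= 1 & res$ci_high >= 1))
  expect_true(all(res$ci_low <= res$or & res$or <= res$ci_high))
})

test_that("contrasts select the documented case/control groups", {
  co <- generate_feature_cohort(feature_plan(n = 800L), seed = 26)
  fit <- fit_jive(preprocess_blocks(co$blocks), 3L, c(SL = 1L, PA = 2L, CR = 3L))
  sc <- extract_scores(fit)
  tabs <- table(co$covariates$group)
  for (ct in c("lifetime", "current", "remitted")) {
    res <- jive_logistic(sc, co$covariates, contrast = ct)
    expect_equal(attr(res, "n_control"), unname(tabs[["none"]]))
    expected_cases <- if (ct == "lifetime") sum(tabs[c("current", "remitted")])
      else tabs[[ct]]
    expect_equal(attr(res, "n_case"), unname(expected_cases))
    expect_equal(nrow(res), 9L)
  }
})

test_that("estimates are invariant to score column order", {
  co <- generate_feature_cohort(feature_plan(n = 600L), seed = 27)
  fit <- fit_jive(preprocess_blocks(co$blocks), 3L, c(SL = 1L, PA = 2L, CR = 3L))
  sc <- extract_scores(fit)
  r1 <- jive_logistic(sc, co$covariates, contrast = "lifetime")
  perm <- sc[, c("subject", sample(setdiff(names(sc), "subject")))]
  r2 <- jive_logistic(perm, co$covariates, contrast = "lifetime")
  r2 <- r2[match(r1$predictor, r2$predictor), ]
  expect_equal(r1$or, r2$or, tolerance = 1e-10)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-8)
})

test_that("covariate adjustment removes planted confounding by age", {
  set.seed(28)
  n <- 4000L
  age <- rnorm(n)
  score <- 0.8 * age + rnorm(n, 0, sqrt(1 - 0.64))
  eta <- 0.9 * age                                # outcome depends on age only
  y <- rbinom(n, 1L, plogis(eta))
  sc <- data.frame(subject = as.character(seq_len(n)), S = scale(score)[, 1L])
  cov <- data.frame(subject = as.character(seq_len(n)), age = age,
                    sex = factor("female", levels = c("female", "male")),
                    bmi = 25, anxiety = FALSE, sud = FALSE,
                    group = factor(ifelse(y == 1L, "current", "none"),
                                   levels = c("none", "current", "remitted")))
  raw <- jive_logistic(sc, cov, contrast = "current",
                       covariate_names = character())
  adj <- jive_logistic(sc, cov, contrast = "current",
                       covariate_names = "age")
  expect_gt(raw$or, 1.3)                          # confounded estimate is biased
  expect_true(adj$ci_low <= 1 && adj$ci_high >= 1)
  expect_lt(abs(log(adj$or)), abs(log(raw$or)) / 3)
})

test_that("fitted probabilities average to the observed outcome rate", {
  co <- generate_feature_cohort(feature_plan(n = 700L), seed = 29)
  fit <- fit_jive(preprocess_blocks(co$blocks), 3L, c(SL = 1L, PA = 2L, CR = 3L))
  sc <- extract_scores(fit)
  df <- merge(sc, co$covariates, by = "subject")
  df$outcome <- as.integer(df$group != "none")
  g <- glm(outcome ~ . - subject - group, family = binomial(),
           data = df[, c(setdiff(names(sc), "subject"), "age", "sex", "bmi",
                         "anxiety", "sud", "outcome", "subject", "group")])
  expect_equal(mean(fitted(g)), mean(df$outcome), tolerance = 1e-10)
})

test_that("medication flag adds the optional covariate", {
  co <- generate_feature_cohort(feature_plan(n = 800L), seed = 30)
  fit <- fit_jive(preprocess_blocks(co$blocks), 3L, c(SL = 1L, PA = 2L, CR = 3L))
  sc <- extract_scores(fit)
  res <- jive_logistic(sc, co$covariates, contrast = "lifetime",
                       medication = TRUE)
  expect_true("medication" %in% attr(res, "covariates"))
})
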