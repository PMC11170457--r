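#!/usr/bin/env Rscript
# Stage 4: group comparisons and JIVE-score logistic regressions --
# descriptive table by diagnosis group (chi-square / ANOVA), then one
# covariate-adjusted logistic model per contrast (lifetime, current,
# remitted vs none) on the nine orthogonal scores, plus the
# medication-adjusted variant.

suppressMessages(library(actijive))

scores <- utils::read.csv("results/scores.csv", stringsAsFactors = FALSE)
cov <- read_covariates("results/covariates.csv")
feats <- utils::read.csv("results/feature_blocks.csv", check.names = FALSE)

dt <- descriptive_table(merge(feats, cov, by = "subject"), "group",
                        continuous = c("age", "bmi", "Onset", "Efficiency",
                                       "TAC", "SATP", "ASTP", "RA", "IV",
                                       "IS", "Acro"),
                        categorical = c("sex", "anxiety", "sud", "medication"))
utils::write.csv(dt, "results/descriptive_table.csv", row.names = FALSE)
message("descriptive comparisons written (chi-square for categories, ANOVA otherwise)")

for (ct in c("lifetime", "current", "remitted")) {
  res <- jive_logistic(scores, cov, contrast = ct)
  utils::write.csv(as.data.frame(res),
                   file.path("results", paste0("associations_", ct, ".csv")),
                   row.names = FALSE)
  print(res)
}

med <- jive_logistic(scores, cov, contrast = "lifetime", medication = TRUE)
utils::write.csv(as.data.frame(med),
                 "results/associations_lifetime_medication.csv",
                 row.names = FALSE)
message("medication-adjusted lifetime model written")
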