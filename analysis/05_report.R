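#!/usr/bin/env Rscript
# Stage 5: collate the run into a one-page summary: variance partition,
# recovered odds ratios against the planted values, and the epoch-tier
# parameter-recovery table.

suppressMessages(library(actijive))

ve <- utils::read.csv("results/varexp.csv")
message("variance explained (percent of block total):")
print(transform(ve, joint = round(100 * joint, 1),
                individual = round(100 * individual, 1),
                residual = round(100 * residual, 1)))

plan <- feature_plan()
planted_or <- exp(plan$logor)
life <- utils::read.csv("results/associations_lifetime.csv")
# JIVE component orientation follows a loading-sign convention, not the
# planted latent direction; align each planted OR with the estimated
# component's orientation before comparing
scores <- utils::read.csv("results/scores.csv", check.names = FALSE)
latents <- utils::read.csv("results/planted_latents.csv", check.names = FALSE)
orient <- vapply(life$predictor, function(cn)
  sign(stats::cor(scores[[cn]], latents[[cn]])), numeric(1L))
life$planted_or <- planted_or[life$predictor]^orient
message("lifetime-contrast odds ratios (per 1 SD of score) vs planted")
message("(planted values orientation-aligned to the estimated components):")
print(data.frame(predictor = life$predictor,
                 or = sprintf("%.2f (%.2f-%.2f)", life$or, life$ci_low,
                              life$ci_high),
                 p = signif(life$p_value, 2),
                 planted = round(life$planted_or, 2)), row.names = FALSE)

rec <- utils::read.csv("results/feature_recovery.csv")
message("epoch-tier parameter recovery:")
print(rec, digits = 4)
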