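# Group-comparison and regression analyses: descriptive tables with
# chi-square / ANOVA tests, and logistic regression of the depression
# contrasts on the nine orthogonal JIVE scores with covariate adjustment.

#' Descriptive comparison table across diagnosis groups
#'
#' Continuous variables get per-group mean (SD) and a one-way ANOVA F-test
#' p-value; categorical variables get counts, column percentages and a
#' chi-square test of independence.
#'
#' @param data data.frame holding the variables and the grouping column.
#' @param group name of the grouping column (factor with >= 2 non-empty
#'   levels).
#' @param continuous character vector of continuous variable names.
#' @param categorical character vector of categorical variable names.
#' @return data.frame: `variable`, `level` (NA for continuous), per-group
#'   `mean_`/`sd_` or `n_`/`pct_` columns, `test` and `p_value`.
#' @export
descriptive_table <- function(data, group, continuous = character(),
                              categorical = character()) {
  g <- droplevels(factor(data[[group]]))
  if (nlevels(g) < 2L) stop("need at least 2 non-empty groups", call. = FALSE)
  lv <- levels(g)
  rows <- list()
  for (v in continuous) {
    x <- data[[v]]
    mu <- tapply(x, g, mean, na.rm = TRUE)
    sd_ <- tapply(x, g, stats::sd, na.rm = TRUE)
    nn <- tapply(!is.na(x), g, sum)
    p <- if (any(nn < 2L)) NA_real_ else
      summary(stats::aov(x ~ g))[[1L]][["Pr(>F)"]][1L]
    row <- data.frame(variable = v, level = NA_character_, test = "anova",
                      p_value = p)
    for (l in lv) {
      row[[paste0("mean_", l)]] <- mu[[l]]
      row[[paste0("sd_", l)]] <- sd_[[l]]
    }
    rows[[length(rows) + 1L]] <- row
  }
  for (v in categorical) {
    x <- droplevels(factor(data[[v]]))
    tab <- table(x, g)
    p <- tryCatch(suppressWarnings(stats::chisq.test(tab)$p.value),
                  error = function(e) NA_real_)
    for (l in rownames(tab)) {
      row <- data.frame(variable = v, level = l, test = "chi-square",
                        p_value = p)
      for (gl in lv) {
        row[[paste0("n_", gl)]] <- tab[l, gl]
        row[[paste0("pct_", gl)]] <- 100 * tab[l, gl] / sum(tab[, gl])
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(unique(unlist(lapply(rows, names))), names(r))
    for (m in miss) r[[m]] <- NA
    r[, unique(unlist(lapply(rows, names)))]
  }))
  rownames(out) <- NULL
  out
}

#' Pooled cohort summaries from per-group margins
#'
#' Recomputes whole-cohort summaries (percentages and sample-size-weighted
#' means) from a per-group margin table with columns `group`, `n`,
#' `female`, `white`, `age_mean`, `bmi_mean`, where `group` distinguishes
#' `none`, `current` and `remitted` depression.
#'
#' @param margins the margin data.frame.
#' @return named list: `n_total`, `female_pct`, `white_pct`,
#'   `lifetime_pct`, `current_pct`, `remitted_pct`, `mean_age`, `mean_bmi`.
#' @export
cohort_summary <- function(margins) {
  stopifnot(all(c("group", "n", "female", "white", "age_mean", "bmi_mean")
                %in% names(margins)))
  n_tot <- sum(margins$n)
  grp <- function(g) margins$n[margins$group == g]
  list(n_total = n_tot,
       female_pct = 100 * sum(margins$female) / n_tot,
       white_pct = 100 * sum(margins$white) / n_tot,
       lifetime_pct = 100 * (grp("current") + grp("remitted")) / n_tot,
       current_pct = 100 * grp("current") / n_tot,
       remitted_pct = 100 * grp("remitted") / n_tot,
       mean_age = sum(margins$n * margins$age_mean) / n_tot,
       mean_bmi = sum(margins$n * margins$bmi_mean) / n_tot)
}

CONTRAST_GROUPS <- list(lifetime = c("current", "remitted"),
                        current = "current", remitted = "remitted")

#' Logistic regression of a depression contrast on JIVE scores
#'
#' Fits one maximum-likelihood logistic model per contrast: cases are the
#' subjects in the contrast's diagnosis group(s) (`lifetime` pools
#' `current` and `remitted`), controls are the `none` group; other
#' subjects are dropped.  All score columns enter simultaneously together
#' with the covariates age, sex, BMI, current anxiety and current SUD
#' (plus medication when `medication = TRUE`).  Scores are standardized,
#' so odds ratios are per 1 SD of score.  Wald 95% CIs and p-values are
#' reported; a Benjamini-Hochberg adjusted column is emitted alongside for
#' transparency but the headline p-values are unadjusted.
#'
#' @param scores data.frame from [extract_scores()] (`subject` + score
#'   columns).
#' @param covariates covariate data.frame (see [read_covariates()]).
#' @param contrast one of `"lifetime"`, `"current"`, `"remitted"`.
#' @param medication also adjust for current medication use; default
#'   `FALSE`.
#' @param covariate_names covariates to adjust for; default
#'   `c("age", "sex", "bmi", "anxiety", "sud")`.  Set to `character()`
#'   for an unadjusted model.
#' @return An `association_result` data.frame: `predictor`, `or`,
#'   `ci_low`, `ci_high`, `p_value`, `p_bh`, with attributes `contrast`,
#'   `n_case`, `n_control`, `covariates`, `converged`.
#' @export
jive_logistic <- function(scores, covariates, contrast = "lifetime",
                          medication = FALSE,
                          covariate_names = c("age", "sex", "bmi",
                                              "anxiety", "sud")) {
  contrast <- match.arg(contrast, names(CONTRAST_GROUPS))
  df <- merge(scores, covariates, by = "subject")
  keep <- df$group %in% c("none", CONTRAST_GROUPS[[contrast]])
  df <- df[keep, , drop = FALSE]
  df$outcome <- as.integer(df$group %in% CONTRAST_GROUPS[[contrast]])
  score_cols <- setdiff(names(scores), "subject")
  covs <- covariate_names
  if (medication) covs <- c(covs, "medication")
  covs <- intersect(covs, names(df))
  fml <- stats::as.formula(paste("outcome ~",
                                 paste(c(score_cols, covs), collapse = " + ")))
  fit <- stats::glm(fml, family = stats::binomial(), data = df)
  sm <- summary(fit)$coefficients
  separation <- any(abs(stats::coef(fit)[score_cols]) > 10, na.rm = TRUE)
  rows <- sm[intersect(score_cols, rownames(sm)), , drop = FALSE]
  out <- data.frame(predictor = rownames(rows),
                    or = exp(rows[, "Estimate"]),
                    ci_low = exp(rows[, "Estimate"] - 1.96 * rows[, "Std. Error"]),
                    ci_high = exp(rows[, "Estimate"] + 1.96 * rows[, "Std. Error"]),
                    p_value = rows[, "Pr(>|z|)"], row.names = NULL)
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  structure(out, class = c("association_result", "data.frame"),
            contrast = contrast,
            n_case = sum(df$outcome == 1L), n_control = sum(df$outcome == 0L),
            covariates = covs,
            converged = fit$converged && !separation)
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("Contrast: %s (%d cases vs %d controls)%s\n",
              attr(x, "contrast"), attr(x, "n_case"), attr(x, "n_control"),
              if (isTRUE(attr(x, "converged"))) ""
              else "  [WARNING: non-convergence or separation]"))
  df <- as.data.frame(x)
  df$or <- sprintf("%.2f (%.2f-%.2f)", df$or, df$ci_low, df$ci_high)
  print(df[, c("predictor", "or", "p_value")], row.names = FALSE)
  invisible(x)
}
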