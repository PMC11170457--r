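# Config-driven pipeline: simulate -> features -> jive -> associate, with
# a deterministic run manifest.  Stage outputs are pure functions of
# (inputs, config, seed); rerunning an identical config reproduces
# identical outputs and an identical manifest hash.

#' Default pipeline configuration
#'
#' @param tier `"feature"` (simulate feature blocks directly) or
#'   `"epoch"` (simulate minute-level streams and extract features).
#' @param seed master seed; every stage derives its randomness from it.
#' @param out_dir output directory for stage CSV/JSON artifacts (created
#'   if needed); `NULL` keeps everything in memory.
#' @param ... overrides for any config entry (`plan`, `ranks`, `alpha`,
#'   `n_perm`, `tol`, `max_iter`, `contrasts`, `medication`,
#'   `covariate_names`, `min_valid_days`, thresholds...).
#' @return A `run_config` list.
#' @export
run_config <- function(tier = c("feature", "epoch"), seed = 1L,
                       out_dir = NULL, ...) {
  tier <- match.arg(tier)
  cfg <- list(tier = tier, seed = as.integer(seed), out_dir = out_dir,
              plan = NULL,
              ranks = NULL,             # NULL = permutation selection
              alpha = 0.05, n_perm = 99L, tol = 1e-8, max_iter = 500L,
              contrasts = c("lifetime", "current", "remitted"),
              medication = FALSE,
              covariate_names = c("age", "sex", "bmi", "anxiety", "sud"),
              min_valid_days = 7L, theta_sleep = 10, theta_sed = 50,
              theta_mvpa = 1000, wake_only = FALSE)
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys as in [run_config()].
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order (`simulate`, `features`,
#' `jive`, `associate`), caching intermediates in the returned object and
#' optionally writing CSV/JSON artifacts plus a run manifest to
#' `config$out_dir`.
#'
#' @param config a [run_config()].
#' @param stages subset of stages to run; default all that apply to the
#'   tier.
#' @return list with `config`, `cohort`, `features`, `blocks`, `ranks`,
#'   `model`, `scores`, `associations`, `descriptives` and `manifest`.
#' @export
run_pipeline <- function(config, stages = c("simulate", "features", "jive",
                                            "associate")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  # YAML-sourced configs carry plain lists; coerce to plan/rank objects
  if (!is.null(config$plan) && !inherits(config$plan, c("feature_plan", "epoch_plan")))
    config$plan <- do.call(if (config$tier == "feature") feature_plan else epoch_plan,
                           config$plan)
  if (!is.null(config$ranks) && is.list(config$ranks$indiv))
    config$ranks$indiv <- unlist(config$ranks$indiv)
  res <- list(config = config)
  manifest <- list(seed = config$seed, tier = config$tier, stages = stages)

  if ("simulate" %in% stages) {
    if (config$tier == "feature") {
      plan <- config$plan %||% feature_plan()
      res$cohort <- generate_feature_cohort(plan, seed = config$seed)
      res$blocks <- res$cohort$blocks
      manifest$n_subjects <- length(res$blocks$subjects)
    } else {
      plan <- config$plan %||% epoch_plan()
      res$cohort <- generate_epoch_cohort(plan, seed = config$seed)
      manifest$n_subjects <- length(res$cohort$series)
    }
  }

  if ("features" %in% stages && config$tier == "epoch") {
    plan <- config$plan %||% epoch_plan()
    fx <- extract_features(res$cohort$series,
                           min_valid_days = config$min_valid_days,
                           theta_sleep = plan$theta_sleep,
                           theta_sed = plan$theta_sed,
                           theta_mvpa = config$theta_mvpa,
                           wake_only = config$wake_only)
    res$features <- fx
    res$blocks <- feature_blocks(fx$features)
    manifest$n_included <- length(res$blocks$subjects)
    manifest$valid_days_total <- sum(fx$inclusion$valid_days[fx$inclusion$included])
  }

  if ("jive" %in% stages) {
    pp <- preprocess_blocks(res$blocks)
    if (is.null(config$ranks)) {
      sel <- select_ranks(pp, alpha = config$alpha, n_perm = config$n_perm,
                          seed = derive_seed(config$seed, 7L))
      ranks <- list(joint = sel$r_joint, indiv = sel$r_indiv)
    } else {
      ranks <- config$ranks
    }
    res$ranks <- ranks
    res$model <- fit_jive(pp, ranks$joint, ranks$indiv,
                          tol = config$tol, max_iter = config$max_iter)
    res$scores <- extract_scores(res$model)
    manifest$ranks <- c(joint = ranks$joint, ranks$indiv)
    manifest$varexp <- lapply(res$model$varexp, round, 4L)
    manifest$converged <- res$model$converged
  }

  if ("associate" %in% stages && !is.null(res$cohort$covariates)) {
    cov <- res$cohort$covariates
    res$associations <- lapply(stats::setNames(config$contrasts, config$contrasts),
                               function(ct)
      jive_logistic(res$scores, cov, contrast = ct,
                    medication = config$medication,
                    covariate_names = config$covariate_names))
    feats <- if (!is.null(res$features)) res$features$features else
      data.frame(subject = res$blocks$subjects,
                 do.call(cbind, res$blocks$blocks), check.names = FALSE)
    dt_data <- merge(feats, cov, by = "subject")
    res$descriptives <- descriptive_table(
      dt_data, "group",
      continuous = intersect(c("age", "bmi", SL_FEATURES, PA_FEATURES,
                               CR_FEATURES), names(dt_data)),
      categorical = intersect(c("sex", "anxiety", "sud", "medication"),
                              names(dt_data)))
    manifest$n_per_group <- as.list(table(cov$group))
  }

  res$manifest <- manifest
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

# Serialise stage outputs: scores/loadings/descriptives/associations as
# CSV, manifest (with a config hash) as JSON.
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  cfg$out_dir <- NULL                    # environment detail, not an input
  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1L))], cfg_file,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest <- res$manifest
  manifest$config_hash <- unname(tools::md5sum(cfg_file))
  if (!is.null(res$scores))
    utils::write.csv(res$scores, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
  if (!is.null(res$model))
    utils::write.csv(loading_table(res$model),
                     file.path(out_dir, "loadings.csv"), row.names = FALSE)
  if (!is.null(res$features))
    write_features(res$features$features, file.path(out_dir, "features.csv"))
  if (!is.null(res$descriptives))
    utils::write.csv(res$descriptives, file.path(out_dir, "descriptives.csv"),
                     row.names = FALSE)
  for (ct in names(res$associations %||% list()))
    utils::write.csv(as.data.frame(res$associations[[ct]]),
                     file.path(out_dir, paste0("associations_", ct, ".csv")),
                     row.names = FALSE)
  if (!is.null(res$model)) {
    manifest$varexp <- res$model$varexp
    fig <- do.call(rbind, lapply(names(res$model$varexp), function(k)
      data.frame(block = k, t(res$model$varexp[[k]]))))
    utils::write.csv(fig, file.path(out_dir, "varexp.csv"), row.names = FALSE)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
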