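# Feature-tier synthetic cohort: subjects x features blocks with planted
# joint + individual low-rank structure, X_k = U S_k W_k' + U_k T_k V_k'
# + E_k, a logistic outcome model on the standardized latent scores, and
# covariates drawn near the reference cohort marginals.  Ground truth is
# stored alongside so every downstream estimate can be checked against
# the planted values.

#' Plan for a feature-tier synthetic cohort
#'
#' Defaults emulate the reference study's conditions: n = 2317 subjects,
#' ranks 3 (joint) / 1, 2, 3 (SL, PA, CR), per-block variance-explained
#' targets 58.5/34.4/7.1 (SL), 79.5/17.6/2.9 (PA), 54.5/25.5/20.0 (CR) in
#' percent, and planted per-SD log odds ratios on the latents matching the
#' published lifetime-contrast odds ratios (Joint-1 0.86, Joint-2 1.12,
#' Joint-3 0.97, SL-1 0.97, PA-1 0.94, PA-2 0.84, CR-1 0.86, CR-2 1.11,
#' CR-3 0.99).
#'
#' @param n number of subjects.
#' @param r_joint joint rank.
#' @param r_indiv named individual ranks for blocks SL, PA, CR.
#' @param p named block dimensions; default `c(SL = 7, PA = 7, CR = 14)`.
#' @param varexp named list of per-block `(joint, individual, residual)`
#'   fraction targets, each summing to 1.
#' @param logor named planted per-SD log odds ratios for the latent
#'   scores, names `Joint_1..`, `SL_1..`, etc.  Components absent from
#'   the plan get log-OR 0.
#' @param prevalence target outcome (lifetime depression) prevalence.
#' @param current_frac fraction of cases labelled `current` (the rest
#'   `remitted`); default 185/1153.
#' @param cov_logor planted covariate log-ORs (on centered age, female
#'   sex, centered BMI, anxiety, SUD).
#' @return A `feature_plan` list.
#' @export
feature_plan <- function(n = 2317L, r_joint = 3L,
                         r_indiv = c(SL = 1L, PA = 2L, CR = 3L),
                         p = c(SL = 7L, PA = 7L, CR = 14L),
                         varexp = list(SL = c(0.585, 0.344, 0.071),
                                       PA = c(0.795, 0.176, 0.029),
                                       CR = c(0.545, 0.255, 0.200)),
                         logor = c(Joint_1 = log(0.86), Joint_2 = log(1.12),
                                   Joint_3 = log(0.97), SL_1 = log(0.97),
                                   PA_1 = log(0.94), PA_2 = log(0.84),
                                   CR_1 = log(0.86), CR_2 = log(1.11),
                                   CR_3 = log(0.99)),
                         prevalence = 1153 / 2317,
                         current_frac = 185 / 1153,
                         cov_logor = c(age = -0.025, female = 0.9,
                                       bmi = 0, anxiety = 0.8, sud = 0.4),
                         weights = c("decreasing", "equal")) {
  weights <- match.arg(weights)
  stopifnot(all(names(r_indiv) == names(p)),
            all(vapply(varexp, function(v) abs(sum(v) - 1) < 1e-8, logical(1L))))
  for (k in names(p))
    if (r_joint + r_indiv[[k]] > p[[k]])
      stop("infeasible ranks for block ", k, call. = FALSE)
  structure(list(n = as.integer(n), r_joint = as.integer(r_joint),
                 r_indiv = r_indiv, p = p, varexp = varexp, logor = logor,
                 prevalence = prevalence, current_frac = current_frac,
                 cov_logor = cov_logor, weights = weights),
            class = "feature_plan")
}

haar_loadings <- function(p, r) {
  if (r == 0L) return(matrix(0, p, 0L))
  q <- qr.Q(qr(matrix(stats::rnorm(p * r), p, r)))
  sweep(q, 2L, ifelse(q[1L, ] >= 0, 1, -1), `*`)
}

# component strength profile: decreasing separates singular values (keeps
# components identifiable); equal maximises detectability of the full rank
component_weights <- function(r, kind = "decreasing") {
  if (r == 0L) return(numeric(0L))
  w <- if (kind == "equal") rep(1, r) else r:1
  w / sum(w)
}

#' Generate a feature-tier synthetic cohort
#'
#' @param plan a [feature_plan()].
#' @param seed integer RNG seed; the same `(plan, seed)` pair regenerates
#'   the identical cohort.
#' @return list with `blocks` (a [feature_blocks()] object, raw scale),
#'   `covariates` (data.frame with `subject, age, sex, bmi, group,
#'   anxiety, sud, medication`) and `truth` (planted latent scores,
#'   loadings, realized variance fractions, linear predictor and labels).
#' @export
generate_feature_cohort <- function(plan, seed = 1L) {
  stopifnot(inherits(plan, "feature_plan"))
  set.seed(seed)
  n <- plan$n
  r <- plan$r_joint
  Z <- matrix(stats::rnorm(n * r), n, r)
  blocks <- list()
  truth_parts <- list()
  Zk_all <- list()
  for (k in names(plan$p)) {
    pk <- plan$p[[k]]
    rk <- plan$r_indiv[[k]]
    fr <- plan$varexp[[k]]
    W <- haar_loadings(pk, r)
    V <- haar_loadings(pk, rk)
    sJ <- sqrt(fr[1L] * pk * component_weights(r, plan$weights))
    sA <- sqrt(fr[2L] * pk * component_weights(rk, plan$weights))
    Zk <- matrix(stats::rnorm(n * rk), n, rk)
    J <- if (r > 0L) Z %*% (sJ * t(W)) else matrix(0, n, pk)
    A <- if (rk > 0L) Zk %*% (sA * t(V)) else matrix(0, n, pk)
    E <- matrix(stats::rnorm(n * pk, sd = sqrt(fr[3L])), n, pk)
    X <- J + A + E
    colnames(X) <- feature_names_for(k, pk)
    blocks[[k]] <- X
    Zk_all[[k]] <- Zk
    tot <- frob2(X)
    truth_parts[[k]] <- list(W = W, V = V, sJ = sJ, sA = sA,
                             realized = c(joint = frob2(J) / tot,
                                          individual = frob2(A) / tot,
                                          residual = frob2(E) / tot))
  }

  # planted latent scores, standardized, in score-table order
  latents <- do.call(cbind, c(list(Z), Zk_all))
  colnames(latents) <- c(if (r > 0L) paste0("Joint_", seq_len(r)),
                         unlist(lapply(names(plan$p), function(k)
                           if (plan$r_indiv[[k]] > 0L)
                             paste0(k, "_", seq_len(plan$r_indiv[[k]])))))
  lat_std <- scale(latents)

  subj <- sprintf("S%04d", seq_len(n))
  age <- pmin(pmax(stats::rnorm(n, 61.79, 9.97), 35), 75)
  sex <- factor(ifelse(stats::runif(n) < 0.5442, "female", "male"),
                levels = c("female", "male"))
  bmi <- pmax(stats::rnorm(n, 26.35, 4.75), 15)
  anxiety <- stats::runif(n) < 0.048
  sud <- stats::runif(n) < 0.006

  beta <- stats::setNames(rep(0, ncol(lat_std)), colnames(lat_std))
  shared <- intersect(names(plan$logor), names(beta))
  beta[shared] <- plan$logor[shared]
  eta <- as.vector(lat_std %*% beta) +
    plan$cov_logor[["age"]] * (age - mean(age)) +
    plan$cov_logor[["female"]] * (sex == "female") +
    plan$cov_logor[["bmi"]] * (bmi - mean(bmi)) +
    plan$cov_logor[["anxiety"]] * anxiety +
    plan$cov_logor[["sud"]] * sud
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta)) - plan$prevalence,
                       c(-20, 20))$root
  case <- stats::runif(n) < stats::plogis(b0 + eta)
  group <- factor(ifelse(!case, "none",
                         ifelse(stats::runif(n) < plan$current_frac,
                                "current", "remitted")),
                  levels = c("none", "current", "remitted"))
  med_p <- c(none = 0.0275, current = 0.3459, remitted = 0.1322)
  medication <- stats::runif(n) < med_p[as.character(group)]

  fb <- structure(list(subjects = subj, blocks = blocks),
                  class = "feature_blocks")
  for (k in names(fb$blocks)) rownames(fb$blocks[[k]]) <- subj
  covariates <- data.frame(subject = subj, age = age, sex = sex, bmi = bmi,
                           group = group, anxiety = anxiety, sud = sud,
                           medication = unname(medication))
  truth <- list(plan = plan, seed = seed, latents = latents,
                latents_std = lat_std, beta = beta, intercept = b0,
                blocks = truth_parts,
                realized_varexp = lapply(truth_parts, `[[`, "realized"))
  list(blocks = fb, covariates = covariates, truth = truth)
}

# Placeholder feature names for feature-tier blocks: the real battery
# names when dimensions match the standard 7/7/14 layout.
feature_names_for <- function(k, pk) {
  std <- switch(k, SL = SL_FEATURES, PA = PA_FEATURES, CR = CR_FEATURES, NULL)
  if (!is.null(std) && length(std) == pk) std else paste0(k, "_f", seq_len(pk))
}
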