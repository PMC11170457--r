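# Joint and Individual Variation Explained (JIVE) for the three feature
# blocks: preprocessing, permutation-based rank selection, alternating
# joint/individual estimation with subject-mode orthogonality, the
# variance-explained partition, and subject scores / loadings.
#
# Model, per block k (subjects in rows):
#   X_k = J_k + A_k + E_k,    J_k = U D V_k',    A_k = U_k D_k W_k',
# with the joint subject basis U shared across blocks and each block's
# individual subject scores orthogonal to U (U' U_k = 0).  Loading columns
# are reported with unit Euclidean norm, so squared loadings sum to 1 per
# component and act as proportional feature importances.

#' Preprocess feature blocks for JIVE
#'
#' Imputes missing feature values by column median, z-scores every column,
#' and divides each block by its Frobenius norm so the three blocks
#' contribute equally.  The transform parameters are stored for the
#' inverse mapping.
#'
#' @param blocks a [feature_blocks()] object.
#' @return A `feature_blocks` object with scaled matrices and a
#'   `preprocess` element (per-block `center`, `scale`, `frob`).
#' @export
preprocess_blocks <- function(blocks) {
  stopifnot(inherits(blocks, "feature_blocks"))
  pp <- list()
  for (k in names(blocks$blocks)) {
    x <- blocks$blocks[[k]]
    for (j in seq_len(ncol(x))) {
      bad <- !is.finite(x[, j])
      if (any(bad)) x[bad, j] <- stats::median(x[, j], na.rm = TRUE)
    }
    ctr <- colMeans(x)
    sdv <- apply(x, 2L, stats::sd)
    if (any(sdv < 1e-12))
      stop("zero-variance feature column: ",
           paste(colnames(x)[sdv < 1e-12], collapse = ", "), call. = FALSE)
    x <- sweep(sweep(x, 2L, ctr), 2L, sdv, `/`)
    fr <- sqrt(frob2(x))
    blocks$blocks[[k]] <- x / fr
    pp[[k]] <- list(center = ctr, scale = sdv, frob = fr)
  }
  blocks$preprocess <- pp
  blocks
}

#' Invert the JIVE preprocessing transform
#' @param x matrix on the preprocessed scale for block `k`.
#' @param blocks preprocessed [feature_blocks()] carrying the parameters.
#' @param k block name.
#' @return matrix on the original feature scale.
#' @export
unpreprocess_block <- function(x, blocks, k) {
  pp <- blocks$preprocess[[k]]
  sweep(sweep(x * pp$frob, 2L, pp$scale, `*`), 2L, pp$center, `+`)
}

svd_trunc <- function(x, r) {
  if (r == 0L) {
    n <- nrow(x)
    return(list(u = matrix(0, n, 0L), d = numeric(0L),
                v = matrix(0, ncol(x), 0L), approx = matrix(0, n, ncol(x))))
  }
  s <- svd(x, nu = r, nv = r)
  d <- s$d[seq_len(r)]
  list(u = s$u, d = d, v = s$v,
       approx = s$u %*% (d * t(s$v)))
}

#' Fit the JIVE decomposition
#'
#' Alternating estimation: the joint part is the best rank-`r_joint`
#' approximation (by SVD) of the column-concatenation of `X_k - A_k`; each
#' individual part is the best rank-`r_k` approximation of
#' `(I - U U')(X_k - J_k)`, which enforces the score orthogonality
#' `U' U_k = 0`.  Iterates until the Frobenius norm of the change in the
#' joint estimate falls below `tol`.
#'
#' @param blocks preprocessed [feature_blocks()] (see
#'   [preprocess_blocks()]); raw blocks are accepted and preprocessed
#'   on the fly.
#' @param r_joint joint rank.
#' @param r_indiv named integer vector of individual ranks (one per block).
#' @param tol convergence tolerance on the joint-estimate change; default
#'   `1e-8`.
#' @param max_iter maximum alternating iterations; default 500.  When
#'   reached the model is returned with `converged = FALSE`.
#' @return An object of class `jive_model`: ranks, joint subject basis `U`
#'   (orthonormal), per-block joint loadings `W` (unit-norm columns),
#'   joint singular values `d_joint`, per-block individual scores/loadings,
#'   fitted `J` and `A` matrices, variance-explained partition `varexp`
#'   (per block: joint/individual/residual fractions summing to 1),
#'   residual-sum-of-squares trace `rss_trace`, and `converged`.
#' @export
fit_jive <- function(blocks, r_joint, r_indiv, tol = 1e-8, max_iter = 500L) {
  if (is.null(blocks$preprocess)) blocks <- preprocess_blocks(blocks)
  X <- blocks$blocks
  K <- length(X)
  if (is.null(names(r_indiv))) names(r_indiv) <- names(X)
  r_indiv <- r_indiv[names(X)]
  n <- nrow(X[[1L]])
  p <- vapply(X, ncol, integer(1L))
  if (r_joint + max(r_indiv) >= min(n, sum(p)))
    stop("ranks infeasible: r_joint + max(r_k) must be < min(n, sum(p))",
         call. = FALSE)
  idx <- split(seq_len(sum(p)), rep(seq_len(K), p))

  A <- lapply(X, function(x) matrix(0, n, ncol(x)))
  J <- matrix(0, n, sum(p))
  U <- matrix(0, n, r_joint)
  d_joint <- numeric(r_joint)
  Vj <- matrix(0, sum(p), r_joint)
  converged <- FALSE
  rss_trace <- numeric(0L)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    R <- do.call(cbind, Map(`-`, X, A))
    sj <- svd_trunc(R, r_joint)
    J_new <- sj$approx
    delta <- sqrt(frob2(J_new - J))
    J <- J_new
    U <- sj$u; d_joint <- sj$d; Vj <- sj$v
    for (k in seq_len(K)) {
      M <- X[[k]] - J[, idx[[k]], drop = FALSE]
      if (r_joint > 0L) M <- M - U %*% crossprod(U, M)
      A[[k]] <- svd_trunc(M, r_indiv[k])$approx
    }
    rss_trace[iter] <- sum(vapply(seq_len(K), function(k)
      frob2(X[[k]] - J[, idx[[k]], drop = FALSE] - A[[k]]), numeric(1L)))
    if (iter > 1L && delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }

  J_k <- lapply(seq_len(K), function(k) J[, idx[[k]], drop = FALSE])
  names(J_k) <- names(X)
  varexp <- lapply(seq_len(K), function(k) {
    tot <- frob2(X[[k]])
    c(joint = frob2(J_k[[k]]) / tot,
      individual = frob2(A[[k]]) / tot,
      residual = frob2(X[[k]] - J_k[[k]] - A[[k]]) / tot)
  })
  names(varexp) <- names(X)

  # joint loadings: block rows of Vj, sign fixed on the concatenated
  # column (largest-magnitude element positive), then unit-normalized per
  # block so squared loadings sum to 1 within each block and component
  if (r_joint > 0L) {
    joint_signs <- apply(Vj, 2L, function(v) {
      v <- as.numeric(v)
      s <- sign(v[which.max(abs(v))]); if (s == 0) 1 else s
    })
    Vj <- sweep(Vj, 2L, joint_signs, `*`)
    U <- sweep(U, 2L, joint_signs, `*`)
  }
  W <- lapply(seq_len(K), function(k) {
    vk <- Vj[idx[[k]], , drop = FALSE]
    nrm <- sqrt(colSums(vk^2))
    vk <- sweep(vk, 2L, pmax(nrm, 1e-300), `/`)
    rownames(vk) <- colnames(X[[k]])
    if (r_joint > 0L) colnames(vk) <- paste0("Joint_", seq_len(r_joint))
    vk
  })
  names(W) <- names(X)

  indiv <- lapply(seq_len(K), function(k) {
    rk <- r_indiv[k]
    s <- svd_trunc(A[[k]], rk)
    if (rk > 0L) {
      sg <- apply(s$v, 2L, function(v) {
        sgn <- sign(v[which.max(abs(v))]); if (sgn == 0) 1 else sgn
      })
      s$v <- sweep(s$v, 2L, sg, `*`)
      s$u <- sweep(s$u, 2L, sg, `*`)
      rownames(s$v) <- colnames(X[[k]])
      colnames(s$v) <- paste0(names(X)[k], "_", seq_len(rk))
    }
    list(scores = s$u, d = s$d, loadings = s$v)
  })
  names(indiv) <- names(X)

  structure(list(ranks = list(joint = r_joint, indiv = r_indiv),
                 subjects = blocks$subjects,
                 U = U, d_joint = d_joint, W = W,
                 indiv = indiv, J = J_k, A = A,
                 varexp = varexp, converged = converged,
                 n_iter = iter, rss_trace = rss_trace,
                 preprocess = blocks$preprocess),
            class = "jive_model")
}

#' @export
print.jive_model <- function(x, ...) {
  cat(sprintf("<jive_model> n = %d; ranks: joint %d, %s; %s after %d iterations\n",
              nrow(x$U), x$ranks$joint,
              paste(sprintf("%s %d", names(x$ranks$indiv), x$ranks$indiv),
                    collapse = ", "),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  ve <- do.call(rbind, x$varexp)
  cat("variance explained (fractions):\n")
  print(round(ve, 3))
  invisible(x)
}

#' Permutation-based JIVE rank selection
#'
#' The joint rank is the number of leading singular values of the
#' column-concatenated matrix exceeding the `(1 - alpha)` quantile of the
#' position-matched singular values under independent row permutation of
#' each block (which breaks the cross-block subject correspondence while
#' preserving within-block structure).  Individual ranks are selected
#' analogously within each block after removing the current joint
#' estimate, against a null that permutes each column independently.
#' Selection and fitting are iterated until the ranks are stable.
#'
#' @inheritParams fit_jive
#' @param alpha test level per rank decision; default 0.05.
#' @param n_perm number of permutations; default 99.
#' @param seed RNG seed for the permutations; default 1.
#' @param max_outer maximum select/fit iterations; default 10 (returns the
#'   last ranks with `converged = FALSE` when exceeded).
#' @return list `r_joint`, `r_indiv` (named), `converged`.
#' @export
select_ranks <- function(blocks, alpha = 0.05, n_perm = 99L, seed = 1L,
                         max_outer = 10L) {
  if (is.null(blocks$preprocess)) blocks <- preprocess_blocks(blocks)
  X <- blocks$blocks
  K <- length(X)
  n <- nrow(X[[1L]])
  p <- vapply(X, ncol, integer(1L))
  max_r <- min(n - 1L, sum(p)) - 1L
  set.seed(seed)

  # Rank = number of observed singular values exceeding the (1 - alpha)
  # quantile of the null's largest singular value; a single threshold per
  # test keeps the decision well-defined under (near-)degenerate spectra.
  perm_rank <- function(obs_sv, null_max) {
    thr <- stats::quantile(null_max, probs = 1 - alpha, names = FALSE)
    min(sum(obs_sv > thr), max_r)
  }

  joint_rank <- function(A) {
    R <- do.call(cbind, Map(`-`, X, A))
    obs <- svd(R, nu = 0L, nv = 0L)$d
    null_max <- vapply(seq_len(n_perm), function(b) {
      Rp <- do.call(cbind, lapply(seq_len(K), function(k)
        (X[[k]] - A[[k]])[sample.int(n), , drop = FALSE]))
      svd(Rp, nu = 0L, nv = 0L)$d[1L]
    }, numeric(1L))
    perm_rank(obs, null_max)
  }

  indiv_rank <- function(M) {
    obs <- svd(M, nu = 0L, nv = 0L)$d
    null_max <- vapply(seq_len(n_perm), function(b)
      svd(apply(M, 2L, sample), nu = 0L, nv = 0L)$d[1L], numeric(1L))
    perm_rank(obs, null_max)
  }

  A <- lapply(X, function(x) matrix(0, n, ncol(x)))
  U <- matrix(0, n, 0L)
  J <- lapply(X, function(x) matrix(0, n, ncol(x)))
  ranks <- NULL
  for (outer in seq_len(max_outer)) {
    rJ <- joint_rank(A)
    if (rJ > 0L) {
      sj <- svd_trunc(do.call(cbind, Map(`-`, X, A)), rJ)
      U <- sj$u
      splits <- split(seq_len(sum(p)), rep(seq_len(K), p))
      J <- lapply(seq_len(K), function(k) sj$approx[, splits[[k]], drop = FALSE])
    } else {
      U <- matrix(0, n, 0L)
      J <- lapply(X, function(x) matrix(0, n, ncol(x)))
    }
    rI <- vapply(seq_len(K), function(k) {
      M <- X[[k]] - J[[k]]
      if (rJ > 0L) M <- M - U %*% crossprod(U, M)
      indiv_rank(M)
    }, integer(1L))
    names(rI) <- names(X)
    new_ranks <- list(joint = rJ, indiv = rI)
    if (identical(new_ranks, ranks))
      return(list(r_joint = rJ, r_indiv = rI, converged = TRUE))
    ranks <- new_ranks
    fit <- fit_jive(blocks, rJ, rI, tol = 1e-6, max_iter = 200L)
    A <- fit$A
  }
  warning("rank selection did not stabilise within max_outer iterations")
  list(r_joint = ranks$joint, r_indiv = ranks$indiv, converged = FALSE)
}

#' Extract standardized JIVE subject scores
#'
#' Returns the joint and individual subject scores, each column
#' standardized to mean 0, SD 1 (so downstream odds ratios are per 1 SD of
#' score).  Joint scores are mutually orthogonal and each block's
#' individual scores are orthogonal to all joint scores; individual scores
#' of different blocks are not constrained.
#'
#' @param model a [fit_jive()] model.
#' @return data.frame: `subject` plus columns `Joint_1..`, `SL_1..`,
#'   `PA_1..`, `CR_1..`.
#' @export
extract_scores <- function(model) {
  stopifnot(inherits(model, "jive_model"))
  std <- function(m) apply(m, 2L, function(x) (x - mean(x)) / stats::sd(x))
  out <- data.frame(subject = model$subjects %||% as.character(seq_len(nrow(model$U))),
                    stringsAsFactors = FALSE)
  if (model$ranks$joint > 0L) {
    js <- std(model$U)
    colnames(js) <- paste0("Joint_", seq_len(ncol(js)))
    out <- cbind(out, js)
  }
  for (k in names(model$indiv)) {
    rk <- model$ranks$indiv[[k]]
    if (rk > 0L) {
      is_ <- std(model$indiv[[k]]$scores)
      colnames(is_) <- paste0(k, "_", seq_len(rk))
      out <- cbind(out, is_)
    }
  }
  out
}

#' Loading table in the published layout
#'
#' One row per (feature, component): signed loading and squared loading
#' (proportional importance; squares sum to 1 within block and component),
#' with a flag for features contributing more than `threshold` of the
#' proportional variation.
#'
#' @param model a [fit_jive()] model.
#' @param threshold importance flag threshold on the squared loading;
#'   default 0.05.
#' @return data.frame `block`, `feature`, `component`, `loading`,
#'   `squared`, `important`.
#' @export
loading_table <- function(model, threshold = 0.05) {
  rows <- list()
  for (k in names(model$W)) {
    w <- model$W[[k]]
    for (j in seq_len(ncol(w)))
      rows[[length(rows) + 1L]] <- data.frame(
        block = k, feature = rownames(w), component = colnames(w)[j],
        loading = w[, j], squared = w[, j]^2,
        important = w[, j]^2 > threshold, row.names = NULL)
    v <- model$indiv[[k]]$loadings
    if (!is.null(v) && ncol(v) > 0L) for (j in seq_len(ncol(v)))
      rows[[length(rows) + 1L]] <- data.frame(
        block = k, feature = rownames(v), component = colnames(v)[j],
        loading = v[, j], squared = v[, j]^2,
        important = v[, j]^2 > threshold, row.names = NULL)
  }
  do.call(rbind, rows)
}
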