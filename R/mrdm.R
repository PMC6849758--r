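# align a list of dist_matrix objects to common labels, in the order of the
# first; errors on mismatched label sets
align_dists <- function(mats) {
  labs <- rownames(mats[[1]])
  for (m in mats) {
    if (is.null(rownames(m)) || !setequal(rownames(m), labs))
      stopf("distance matrices have mismatched population labels")
  }
  lapply(mats, function(m) m[labs, labs])
}

#' Multiple regression on distance matrices
#'
#' OLS of the vectorized strict lower triangle of the response matrix on
#' those of the predictor matrices, with permutation inference: the null is
#' generated by simultaneously permuting rows and columns of the response
#' (the valid scheme for distance-matrix dependence). One-sided upper-tail
#' p-values are reported for the overall R^2/F and, per predictor, for the
#' absolute pseudo-t under the same permutations;
#' p = (#\{perm >= observed\} + 1) / (n_perm + 1).
#'
#' @param response a [dist_matrix()].
#' @param predictors named list of [dist_matrix()]s.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return Object of class `mrdm_fit`: `coefficients`, `r_squared`, `f`,
#'   `p_overall`, `p_predictors`, `residual_matrix` (symmetric, zero
#'   diagonal), `n_perm`, `seed`.
#' @export
mrdm_fit <- function(response, predictors, n_perm = 10000L, seed = 1L) {
  if (n_perm < 1L) stopf("n_perm must be >= 1")
  if (!is.list(predictors)) predictors <- list(x = predictors)
  if (is.null(names(predictors)) || any(!nzchar(names(predictors))))
    names(predictors) <- sprintf("x%d", seq_along(predictors))
  k <- nrow(response)
  if (k < 4L) stopf("need >= 4 populations for MRDM")
  all_m <- align_dists(c(list(response), predictors))
  response <- all_m[[1]]; predictors <- all_m[-1]

  y <- lower_vec(response)
  X <- cbind(1, vapply(predictors, lower_vec, numeric(length(y))))
  colnames(X) <- c("(Intercept)", names(predictors))
  if (any(apply(X[, -1, drop = FALSE], 2, sd) == 0)) stopf("constant predictor")
  n <- length(y); p <- ncol(X)

  qrX <- qr(X)
  xtx_inv <- chol2inv(qr.R(qrX))
  hat_mult <- xtx_inv %*% t(X)               # p x n; beta = hat_mult %*% y

  fit_stats <- function(yv) {
    beta <- hat_mult %*% yv
    res <- yv - X %*% beta
    rss <- sum(res^2)
    tss <- sum((yv - mean(yv))^2)
    r2 <- 1 - rss / tss
    sigma2 <- rss / (n - p)
    tvals <- beta[-1] / sqrt(sigma2 * diag(xtx_inv)[-1])
    list(beta = beta, r2 = r2,
         f = (r2 / (p - 1)) / ((1 - r2) / (n - p)),
         t = abs(tvals), res = res)
  }
  obs <- fit_stats(y)

  set.seed(seed)
  ge_overall <- 0L
  ge_t <- integer(p - 1)
  for (b in seq_len(n_perm)) {
    perm <- sample(k)
    yp <- lower_vec(response[perm, perm])
    st <- fit_stats(yp)
    ge_overall <- ge_overall + (st$r2 >= obs$r2)
    ge_t <- ge_t + (st$t >= obs$t)
  }
  p_overall <- (ge_overall + 1) / (n_perm + 1)
  p_pred <- setNames((ge_t + 1) / (n_perm + 1), names(predictors))

  resid_m <- matrix(0, k, k, dimnames = dimnames(response))
  resid_m[lower.tri(resid_m)] <- obs$res
  resid_m <- resid_m + t(resid_m)
  structure(list(coefficients = setNames(as.numeric(obs$beta), colnames(X)),
                 r_squared = obs$r2, f = obs$f, p_overall = p_overall,
                 p_predictors = p_pred,
                 residual_matrix = dist_matrix(resid_m, check = FALSE),
                 n_perm = n_perm, seed = seed),
            class = "mrdm_fit")
}

#' @export
print.mrdm_fit <- function(x, ...) {
  cat(sprintf("MRDM fit: R^2 = %.3f, F = %.2f, p = %.4g (%d permutations)\n",
              x$r_squared, x$f, x$p_overall, x$n_perm))
  co <- data.frame(coef = x$coefficients[-1], p_perm = x$p_predictors)
  print(round(co, 4))
  invisible(x)
}

#' Screen landscape predictors for collinearity
#'
#' Drops any predictor whose lower-triangle R^2 with geographic distance,
#' or with an already retained predictor, exceeds `r2_max` (predictors are
#' considered in input order).
#'
#' @param predictors named list of [dist_matrix()]s.
#' @param geo geographic-distance [dist_matrix()].
#' @param r2_max maximum tolerated R^2 (default 0.70).
#' @return Character vector of retained predictor names.
#' @export
collinearity_screen <- function(predictors, geo, r2_max = 0.70) {
  if (!length(predictors)) return(character(0))
  aligned <- align_dists(c(list(geo), predictors))
  geo_v <- lower_vec(aligned[[1]])
  vecs <- lapply(aligned[-1], lower_vec)
  retained <- character(0)
  for (nm in names(predictors)) {
    v <- vecs[[nm]]
    r2s <- c(cor(v, geo_v)^2,
             vapply(retained, function(r) cor(v, vecs[[r]])^2, numeric(1)))
    if (all(r2s <= r2_max)) retained <- c(retained, nm)
  }
  retained
}

#' Stepwise residual MRDM: geography first, landscape second
#'
#' Stage 1 regresses genetic distance on geographic distance; the stage-1
#' residuals are reassembled into a symmetric zero-diagonal matrix which
#' becomes the response for stage 2, where every non-empty subset of the
#' (collinearity-screened) landscape predictors is fitted. The best model
#' is the one with the highest R^2 among models whose predictors are all
#' permutation-significant at `alpha`; when none qualifies the result
#' records no significant model.
#'
#' @param response genetic-distance [dist_matrix()].
#' @param geo geographic-distance [dist_matrix()].
#' @param landscape named list of landscape [dist_matrix()]s.
#' @param n_perm,seed permutation settings for every fit.
#' @param alpha per-predictor significance threshold for model selection.
#' @param max_subset largest subset size fitted (caps the model space).
#' @return List of class `stepwise_mrdm`: `stage1` (mrdm_fit), `fits`
#'   (named list of stage-2 mrdm_fits), `retained` (post-screen predictor
#'   names), `best` (name of the best model or `NA`), `best_fit`.
#' @export
stepwise_residual <- function(response, geo, landscape, n_perm = 10000L,
                              seed = 1L, alpha = 0.05, max_subset = 3L) {
  stage1 <- mrdm_fit(response, list(geo = geo), n_perm, seed)
  resid <- stage1$residual_matrix
  retained <- collinearity_screen(landscape, geo)
  fits <- list()
  if (length(retained)) {
    subsets <- unlist(lapply(seq_len(min(max_subset, length(retained))),
                             function(s) combn(retained, s, simplify = FALSE)),
                      recursive = FALSE)
    for (ss in subsets) {
      nm <- paste(ss, collapse = "+")
      fits[[nm]] <- mrdm_fit(resid, landscape[ss], n_perm, seed + 1L)
    }
  }
  ok <- vapply(fits, function(f) all(f$p_predictors < alpha), logical(1))
  best <- NA_character_
  if (any(ok)) {
    r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
    r2[!ok] <- -Inf
    best <- names(fits)[which.max(r2)]
  }
  structure(list(stage1 = stage1, fits = fits, retained = retained,
                 best = best,
                 best_fit = if (!is.na(best)) fits[[best]] else NULL),
            class = "stepwise_mrdm")
}

#' @export
print.stepwise_mrdm <- function(x, ...) {
  cat(sprintf("Stage 1 (geography): R^2 = %.3f, p = %.4g\n",
              x$stage1$r_squared, x$stage1$p_overall))
  if (is.na(x$best)) cat("Stage 2: no significant landscape model\n")
  else cat(sprintf("Stage 2 best model: %s (R^2 = %.3f)\n", x$best,
                   x$best_fit$r_squared))
  invisible(x)
}

#' Isolation-by-environment test
#'
#' Single-predictor MRDM of adaptive-locus genetic differentiation on the
#' absolute pairwise difference of each environmental variable.
#'
#' @param fst_adaptive [dist_matrix()] of F_ST at climate-adaptive loci.
#' @param env named list of per-population environmental value vectors
#'   (names become predictor names; each is turned into an
#'   absolute-difference matrix), or a named list of ready
#'   [dist_matrix()]s.
#' @param n_perm,seed permutation settings.
#' @return Named list of `mrdm_fit`s, one per environmental variable.
#' @export
ibe_test <- function(fst_adaptive, env, n_perm = 10000L, seed = 1L) {
  labs <- rownames(fst_adaptive)
  fits <- list()
  for (nm in names(env)) {
    e <- env[[nm]]
    d <- if (inherits(e, "dist_matrix") || is.matrix(e)) dist_matrix(as.matrix(e))
         else {
           if (is.null(names(e))) names(e) <- labs
           dist_matrix(abs(outer(e[labs], e[labs], `-`)), labels = labs)
         }
    fits[[nm]] <- mrdm_fit(fst_adaptive, setNames(list(d), nm), n_perm,
                           seed + match(nm, names(env)))
  }
  fits
}
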