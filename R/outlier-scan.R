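# simulate per-locus (theta, He) under Balding-Nichols at divergence f:
# one ancestral frequency per locus, per-population beta draws, binomial
# genotypes at the given sample sizes
sim_neutral_theta <- function(n_loci, sample_sizes, f) {
  r <- length(sample_sizes)
  p_anc <- runif(n_loci, 0.05, 0.95)
  P <- N <- H <- matrix(0, r, n_loci)
  for (i in seq_len(r)) {
    pf <- pmin(pmax(rbn(n_loci, p_anc, f), 1e-4), 1 - 1e-4)
    n <- sample_sizes[i]
    g <- matrix(rbinom(n * n_loci, 2L, rep(pf, each = n)), n, n_loci)
    N[i, ] <- n
    P[i, ] <- colMeans(g) / 2
    H[i, ] <- colMeans(g == 1L)
  }
  cmp <- wc_components(P, N, H)
  list(theta = cmp$a / (cmp$a + cmp$b + cmp$c),
       he = 2 * cmp$pbar * (1 - cmp$pbar),
       mean_theta = sum(cmp$a, na.rm = TRUE) /
         sum(cmp$a + cmp$b + cmp$c, na.rm = TRUE))
}

#' Simulate a neutral F_ST--heterozygosity envelope
#'
#' FDist-style neutral null: loci are simulated under the Balding--Nichols
#' island model with the divergence parameter calibrated by bisection so the
#' simulated multi-locus Weir--Cockerham theta matches `mean_fst_target`
#' within `tol`. The stored per-locus (He, theta) cloud supports conditional
#' upper-tail quantiles at any alpha.
#'
#' @param n_pops number of populations.
#' @param sample_sizes individuals per population (scalar or vector).
#' @param mean_fst_target target multi-locus theta in (0,1).
#' @param n_sim_loci simulated loci in the final envelope (default 10,000).
#' @param seed integer seed.
#' @param tol calibration tolerance on the mean theta.
#' @return Object of class `neutral_envelope`: `theta`, `he`, and `meta`
#'   (calibrated F, achieved mean theta, inputs).
#' @export
simulate_envelope <- function(n_pops, sample_sizes, mean_fst_target,
                              n_sim_loci = 10000L, seed = 1L, tol = 0.005) {
  if (!(mean_fst_target > 0 && mean_fst_target < 1))
    stopf("mean_fst_target must be in (0,1)")
  if (length(sample_sizes) == 1L) sample_sizes <- rep(sample_sizes, n_pops)
  stopifnot(length(sample_sizes) == n_pops)
  n_calib <- min(n_sim_loci, 2000L)
  eval_f <- function(f) {
    set.seed(seed)
    sim_neutral_theta(n_calib, sample_sizes, f)$mean_theta
  }
  lo <- 1e-4; hi <- 0.95
  f <- mean_fst_target  # theta tracks F closely; start the bracket there
  for (step in seq_len(50L)) {
    m <- eval_f(f)
    if (abs(m - mean_fst_target) <= tol) break
    if (m < mean_fst_target) lo <- f else hi <- f
    f <- (lo + hi) / 2
    if (step == 50L) stopf("envelope calibration failed in 50 bisection steps")
  }
  set.seed(seed + 1L)
  sim <- sim_neutral_theta(n_sim_loci, sample_sizes, f)
  ok <- is.finite(sim$theta) & is.finite(sim$he)
  structure(list(theta = sim$theta[ok], he = sim$he[ok],
                 meta = list(n_pops = n_pops, sample_sizes = sample_sizes,
                             target = mean_fst_target, f_calibrated = f,
                             mean_theta = sim$mean_theta,
                             n_sim_loci = n_sim_loci, seed = seed)),
            class = "neutral_envelope")
}

#' @export
print.neutral_envelope <- function(x, ...) {
  cat(sprintf(
    "neutral_envelope: %d simulated loci, %d pops, mean theta %.4f (target %.4f, F = %.4f)\n",
    length(x$theta), x$meta$n_pops, x$meta$mean_theta, x$meta$target,
    x$meta$f_calibrated))
  invisible(x)
}

# conditional quantile of neutral theta in a sliding He window (width 0.05,
# widened until it holds min_pts points); also returns the window sample
envelope_window <- function(env, he, min_pts = 200L) {
  half <- 0.025
  he <- min(max(he, min(env$he)), max(env$he))   # nearest-bin rule off-support
  repeat {
    sel <- abs(env$he - he) <= half
    if (sum(sel) >= min(min_pts, length(env$he)) || half > 0.5) break
    half <- half * 1.5
  }
  env$theta[sel]
}

#' Scan loci against a neutral envelope
#'
#' Flags a locus as a candidate for directional selection when its observed
#' multi-population Weir--Cockerham theta exceeds the conditional
#' (1 - alpha) quantile of the simulated neutral theta given its pooled
#' expected heterozygosity.
#'
#' @param gm a [genotype_matrix()].
#' @param envelope a [simulate_envelope()] result.
#' @param alpha upper-tail significance level (alpha >= 1 flags everything).
#' @param pops_use populations to compute theta across (default: all with
#'   >= 2 individuals).
#' @return data.frame of class `outlier_result`: `id`, `theta`, `he`,
#'   `quantile` (empirical position in the conditional null), `threshold`,
#'   `outlier` (upper-tail flag), `off_support` (He outside envelope range).
#' @export
scan_outliers <- function(gm, envelope, alpha = 0.01, pops_use = NULL) {
  stopifnot(inherits(envelope, "neutral_envelope"))
  tab <- table(gm$pop)
  pops_use <- pops_use %||% names(tab)[tab >= 2]
  obs <- per_locus_theta(gm, pops_use)
  rng <- range(envelope$he)
  res <- obs
  res$quantile <- NA_real_
  res$threshold <- NA_real_
  res$off_support <- !is.na(obs$he) & (obs$he < rng[1] | obs$he > rng[2])
  for (k in seq_len(nrow(obs))) {
    if (!is.finite(obs$theta[k]) || !is.finite(obs$he[k])) next
    win <- envelope_window(envelope, obs$he[k])
    res$quantile[k] <- mean(win <= obs$theta[k])
    res$threshold[k] <- if (alpha >= 1) -Inf else
      as.numeric(quantile(win, 1 - alpha, names = FALSE))
  }
  res$outlier <- !is.na(res$threshold) & res$theta > res$threshold
  class(res) <- c("outlier_result", "data.frame")
  res
}

#' Logistic regression of allele dosage on an environmental covariate
#'
#' Binomial GLM of per-individual A2 dosage (successes out of 2) on the
#' standardized covariate; the Wald p-value is reported, falling back to a
#' likelihood-ratio test when the fit shows (quasi-)separation.
#'
#' @param dosage integer vector of 0/1/2 allele counts (`NA` allowed).
#' @param env numeric covariate, one value per individual (its population's
#'   environmental value).
#' @return List: `slope` (per covariate s.d.), `p`, `separated` flag, `n`.
#' @export
logistic_env_regression <- function(dosage, env) {
  ok <- !is.na(dosage) & !is.na(env)
  dosage <- dosage[ok]; env <- env[ok]
  if (length(unique(env)) < 2L) stopf("constant covariate")
  if (length(unique(dosage)) < 2L) stopf("no genotype variation at locus")
  z <- as.numeric(scale(env))
  fit <- suppressWarnings(glm(cbind(dosage, 2L - dosage) ~ z, family = binomial()))
  sm <- summary(fit)$coefficients
  slope <- sm["z", "Estimate"]
  se <- sm["z", "Std. Error"]
  separated <- abs(slope) > 15 || se > 100
  p <- if (separated) {
    null <- glm(cbind(dosage, 2L - dosage) ~ 1, family = binomial())
    as.numeric(pchisq(null$deviance - fit$deviance, 1, lower.tail = FALSE))
  } else sm["z", "Pr(>|z|)"]
  list(slope = slope, p = p, separated = separated, n = length(dosage))
}
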