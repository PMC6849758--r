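# mean-imputed, column-centered dosage matrix
imputed_centered <- function(gm) {
  G <- gm$geno
  storage.mode(G) <- "double"
  mu <- colMeans(G, na.rm = TRUE)
  idx <- which(is.na(G), arr.ind = TRUE)
  if (nrow(idx)) G[idx] <- mu[idx[, 2]]
  sweep(G, 2, colMeans(G))
}

#' Estimate latent factors of population structure
#'
#' Top-K left singular vectors of the mean-imputed, centered genotype
#' matrix -- the standard PCA surrogate for discrete population structure
#' used to condition genotype--environment regressions.
#'
#' @param gm a [genotype_matrix()].
#' @param K number of factors (1 <= K < number of individuals).
#' @return Numeric matrix (individuals x K).
#' @export
estimate_latent_factors <- function(gm, K) {
  n <- nrow(gm$geno)
  if (K < 1L) stopf("K must be >= 1")
  if (K >= n) stopf("K must be smaller than the number of individuals")
  X <- imputed_centered(gm)
  sv <- svd(X, nu = min(n, K + 1L), nv = 0)
  if (K >= sum(sv$d > sv$d[1] * 1e-8))
    stopf("K is not smaller than the rank of the genotype matrix")
  U <- sv$u[, seq_len(K), drop = FALSE]
  rownames(U) <- gm$sample_id
  U
}

#' Suggest K from the singular-value scree
#'
#' Returns the position of the largest relative gap in the leading singular
#' values. Advisory only -- the scan functions never apply it automatically;
#' K is a configuration input (e.g. the number of clusters found by an
#' external assignment analysis).
#'
#' @param gm a [genotype_matrix()].
#' @param k_max largest K considered.
#' @return Integer suggestion for K.
#' @export
scree_gap_k <- function(gm, k_max = 8L) {
  X <- imputed_centered(gm)
  d <- svd(X, nu = 0, nv = 0)$d
  d <- d[seq_len(min(k_max + 1L, length(d)))]
  which.max(d[-length(d)] / d[-1])
}

# genome-wide intraclass drift-variance ratio phi (population random-effect
# variance over residual variance), by one-way ANOVA moments on dosages
estimate_phi <- function(Y, grp) {
  N <- nrow(Y); G <- nlevels(grp)
  m_g <- tabulate(grp, G)
  pm <- rowsum(Y, grp) / m_g
  gmn <- colMeans(Y)
  ssb <- colSums(m_g * sweep(pm, 2, gmn)^2)
  ssw <- colSums(Y^2) - colSums(m_g * pm^2)
  msb <- ssb / (G - 1)
  msw <- ssw / (N - G)
  n0 <- (N - sum(m_g^2) / N) / (G - 1)
  ratio <- (msb - msw) / (n0 * msw)
  max(0, mean(ratio[is.finite(ratio)], na.rm = TRUE))
}

# compound-symmetry whitening within populations: subtract theta_g times the
# population mean, theta_g = 1 - 1/sqrt(1 + m_g * phi)
whiten <- function(M, grp, phi) {
  m_g <- tabulate(grp, nlevels(grp))
  theta <- 1 - 1 / sqrt(1 + m_g * phi)
  pm <- rowsum(M, grp) / m_g
  M - (theta * pm)[grp, , drop = FALSE]
}

# one deterministic latent-factor association run on whitened data:
# z-score per locus for dosage ~ covariate + factors
gea_run <- function(Yw, Xw) {
  n <- nrow(Yw)
  p <- ncol(Xw)
  qrX <- qr(Xw)
  B <- qr.coef(qrX, Yw)                     # p x L
  rss <- colSums((Yw - Xw %*% B)^2)
  sigma2 <- rss / (n - p)
  xtx_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  zs <- B[2, ] / se
  zs[!is.finite(zs)] <- 0
  zs
}

#' Latent-factor mixed-model genotype--environment association scan
#'
#' Regresses each locus's (mean-imputed) dosage on the standardized
#' covariate plus K latent factors. Two structure corrections act
#' together, as in latent-factor mixed models: a genome-wide intraclass
#' (population random-effect) variance ratio is estimated by one-way ANOVA
#' moments and used to whiten the within-population correlation that a
#' population-level covariate induces; and the latent factors are the top-K
#' singular vectors of the whitened, covariate-residualized genotype matrix
#' (estimating the factors on residuals emulates the joint factor/effect
#' estimation of the mixed model -- plain genotype PCs would absorb the
#' environmental signal itself). The scan is repeated `n_runs` times --
#' run 1 uses the factors as estimated; later runs apply a seeded random
#' rotation plus a small jitter to the factor matrix, emulating the run-to-
#' run variability of stochastic latent-factor solvers. Z-scores are
#' combined across runs by the median, divided by the genomic inflation
#' factor lambda = median(z^2)/0.456, converted to p-values against
#' chi-squared(1), and Benjamini--Hochberg adjusted; loci with q <= `fdr`
#' are flagged.
#'
#' @param gm a [genotype_matrix()].
#' @param env covariate value per individual (typically the individual's
#'   population-level environmental value). Must vary.
#' @param K number of latent factors.
#' @param n_runs number of repetition runs (>= 1).
#' @param seed integer seed driving the run perturbations.
#' @param fdr expected false discovery rate for the significance flag.
#' @param covariate label stored in the output.
#' @return data.frame of class `gea_result`: `id`, `covariate`, `z`
#'   (median z), `lambda`, `p`, `q`, `flag`.
#' @export
lfmm_scan <- function(gm, env, K, n_runs = 5L, seed = 1L, fdr = 0.05,
                      covariate = "env") {
  if (n_runs < 1L) stopf("n_runs must be >= 1")
  if (length(env) != nrow(gm$geno)) stopf("env must have one value per individual")
  if (length(unique(env)) < 2L) stopf("constant covariate")
  if (K < 1L) stopf("K must be >= 1")
  if (K >= nrow(gm$geno)) stopf("K must be smaller than the number of individuals")
  z_env <- as.numeric(scale(env))
  Y <- imputed_centered(gm)
  grp <- factor(gm$pop)
  phi <- estimate_phi(Y, grp)
  Yw <- whiten(Y, grp, phi)
  Xw <- whiten(cbind(1, z_env), grp, phi)
  # factors from the whitened matrix with the covariate regressed out
  bz <- qr.coef(qr(Xw), Yw)
  U <- svd(Yw - Xw %*% bz, nu = K, nv = 0)$u
  zmat <- matrix(NA_real_, n_runs, ncol(Y))
  zmat[1, ] <- gea_run(Yw, cbind(Xw, U))
  if (n_runs > 1L) {
    set.seed(seed)
    for (r in 2:n_runs) {
      Q <- qr.Q(qr(matrix(rnorm(K * K), K, K)))
      Up <- U %*% Q + matrix(rnorm(length(U), sd = 0.05 * sd(U)), nrow(U), K)
      zmat[r, ] <- gea_run(Yw, cbind(Xw, Up))
    }
  }
  z_med <- apply(zmat, 2, median)
  lambda <- max(median(z_med^2) / 0.456, 1e-8)
  p <- pchisq(z_med^2 / lambda, 1, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  res <- data.frame(id = gm$loci$id, covariate = covariate, z = z_med,
                    lambda = lambda, p = p, q = q, flag = q <= fdr,
                    stringsAsFactors = FALSE)
  class(res) <- c("gea_result", "data.frame")
  res
}

#' Run the GEA scan at two spatial scales
#'
#' Performs independent scans on the full data set and on the main-region
#' subset (the within-refugium scale, which guards against false positives
#' from neutral allele-frequency clines formed during range expansion).
#' The subset re-applies the minor-allele-frequency check before scanning.
#'
#' @param gm a QC'd [genotype_matrix()].
#' @param pops a `population_table` (needs `pop`, `region`, `tmax_now`,
#'   `rain_now`).
#' @param K_full,K_region latent-factor counts for the two scales.
#' @param region_main label of the main region (default "main").
#' @param n_runs,seed,fdr passed to [lfmm_scan()].
#' @param maf minor-allele-frequency threshold re-applied to the subset.
#' @return List with elements `full` and `region`, each a named list of
#'   `gea_result`s for covariates `temperature` and `rainfall`.
#' @export
run_two_scales <- function(gm, pops, K_full = 3L, K_region = 2L,
                           region_main = "main", n_runs = 5L, seed = 1L,
                           fdr = 0.05, maf = 0.03) {
  env_of <- function(g, col) {
    v <- pops[[col]][match(g$pop, pops$pop)]
    if (anyNA(v)) stopf("population missing from the population table")
    v
  }
  scan_both <- function(g, K, sd_seed) list(
    temperature = lfmm_scan(g, env_of(g, "tmax_now"), K, n_runs, sd_seed,
                            fdr, "temperature"),
    rainfall = lfmm_scan(g, env_of(g, "rain_now"), K, n_runs, sd_seed + 1L,
                         fdr, "rainfall"))

  full <- scan_both(gm, K_full, seed)

  main_pops <- pops$pop[pops$region == region_main]
  keep <- which(gm$pop %in% main_pops)
  if (length(unique(gm$pop[keep])) < 2L)
    stopf("main-region subset has fewer than 2 populations")
  sub <- gm_subset(gm, ind = keep)
  p <- allele_freq(sub)
  sub <- gm_subset(sub, loc = which(!is.na(p) & pmin(p, 1 - p) >= maf))
  region <- scan_both(sub, K_region, seed + 100L)

  list(full = full, region = region)
}
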