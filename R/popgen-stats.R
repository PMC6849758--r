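# Weir-Cockerham (1984) variance components for biallelic loci.
# P, N, H: populations x loci matrices of A2 frequency, sample size
# (individuals with data) and observed heterozygote proportion.
# Returns per-locus components a (among-population), b, c; loci where any
# population lacks data (or nbar <= 1) are NA.
wc_components <- function(P, N, H) {
  r <- nrow(P)
  if (r < 2L) stopf("Weir-Cockerham needs >= 2 populations")
  ok <- colSums(N >= 1) == r & colSums(N) > r   # nbar > 1
  nbar <- colMeans(N)
  rn <- r * nbar
  nc <- (rn - colSums(N^2) / rn) / (r - 1)
  pbar <- colSums(N * P) / rn
  s2 <- colSums(N * sweep(P, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(N * H) / rn
  inner <- pbar * (1 - pbar) - (r - 1) / r * s2
  a <- nbar / nc * (s2 - (inner - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!ok] <- b[!ok] <- cc[!ok] <- NA_real_
  # degenerate nc (all data in one population) -> uninformative
  bad <- ok & (!is.finite(nc) | nc <= 0)
  a[bad] <- b[bad] <- cc[bad] <- NA_real_
  list(a = a, b = b, c = cc, pbar = pbar)
}

# per-population frequency / sample size / het-proportion matrices for a
# set of populations (rows follow `pops_use` order)
pop_locus_stats <- function(gm, pops_use = sort(unique(gm$pop)), loci = NULL) {
  loc <- loci %||% seq_len(ncol(gm$geno))
  if (is.character(loc)) loc <- match(loc, gm$loci$id)
  P <- N <- H <- matrix(NA_real_, length(pops_use), length(loc))
  for (k in seq_along(pops_use)) {
    sub <- gm$geno[gm$pop == pops_use[k], loc, drop = FALSE]
    n <- colSums(!is.na(sub))
    N[k, ] <- n
    P[k, ] <- ifelse(n > 0, colSums(sub, na.rm = TRUE) / (2 * n), NA)
    H[k, ] <- ifelse(n > 0, colSums(sub == 1L, na.rm = TRUE) / n, NA)
  }
  list(P = P, N = N, H = H, pops = pops_use, loci = loc)
}

#' Multi-locus Weir--Cockerham F_ST between two populations
#'
#' Ratio-of-sums estimator: theta = sum(a) / sum(a + b + c) over informative
#' loci, where a, b, c are the among-population, among-individual and
#' within-individual variance components of Weir & Cockerham (1984).
#'
#' @param gm a [genotype_matrix()].
#' @param pop_a,pop_b population ids.
#' @param loci optional locus ids or indices to restrict to.
#' @return The multi-locus theta (may be slightly negative near zero
#'   differentiation).
#' @export
wc_fst <- function(gm, pop_a, pop_b, loci = NULL) {
  st <- pop_locus_stats(gm, c(pop_a, pop_b), loci)
  if (any(rowSums(st$N >= 1, na.rm = TRUE) == 0))
    stopf("population without genotyped individuals")
  cmp <- wc_components(st$P, st$N, st$H)
  denom <- sum(cmp$a + cmp$b + cmp$c, na.rm = TRUE)
  if (!is.finite(denom) || denom == 0) stopf("no informative loci for %s vs %s",
                                             pop_a, pop_b)
  sum(cmp$a, na.rm = TRUE) / denom
}

#' Pairwise multi-locus F_ST matrix
#'
#' @param gm a [genotype_matrix()].
#' @param pops_use populations to include (default: all with >= 2
#'   genotyped individuals).
#' @param loci optional locus subset (ids or indices).
#' @return A [dist_matrix()] of pairwise theta.
#' @export
fst_matrix <- function(gm, pops_use = NULL, loci = NULL) {
  tab <- table(gm$pop)
  pops_use <- pops_use %||% names(tab)[tab >= 2]
  pops_use <- sort(pops_use)
  k <- length(pops_use)
  m <- matrix(0, k, k, dimnames = list(pops_use, pops_use))
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    m[i, j] <- m[j, i] <- wc_fst(gm, pops_use[i], pops_use[j], loci)
  dist_matrix(m)
}

# per-locus theta and pooled expected heterozygosity across all populations
# (the F_ST-He pairs the outlier scan works on)
per_locus_theta <- function(gm, pops_use = sort(unique(gm$pop)), loci = NULL) {
  st <- pop_locus_stats(gm, pops_use, loci)
  cmp <- wc_components(st$P, st$N, st$H)
  theta <- cmp$a / (cmp$a + cmp$b + cmp$c)
  he <- 2 * cmp$pbar * (1 - cmp$pbar)
  data.frame(id = gm$loci$id[st$loci], theta = theta, he = he)
}

#' Individual inbreeding coefficients and population heterozygosity
#'
#' For each individual, F = (Obs_Hom - Exp_Hom) / (Total - Exp_Hom), where
#' Obs_Hom and Total count homozygous and non-missing loci, and Exp_Hom sums
#' 1 - 2p(1-p) n/(n-1) over its non-missing loci (p = whole-dataset A2
#' frequency, n = non-missing allele count at the locus). Population
#' heterozygosity is 1 - mean(F) over its individuals.
#'
#' @param gm a [genotype_matrix()] (outlier loci should already be excluded
#'   by the caller when neutral diversity is wanted).
#' @return List with `individuals` (sample, pop, obs_hom, exp_hom, total, f)
#'   and `populations` (pop, n, mean_f, heterozygosity, capped flag).
#' @export
heterozygosity <- function(gm) {
  G <- gm$geno
  nonmiss <- !is.na(G)
  if (any(rowSums(nonmiss) == 0))
    stopf("individual with no genotyped loci; F undefined")
  p <- allele_freq(gm)
  n_all <- 2 * colSums(nonmiss)
  exp_hom_l <- 1 - 2 * p * (1 - p) * n_all / pmax(n_all - 1, 1)
  obs_hom <- rowSums(G == 0L | G == 2L, na.rm = TRUE)
  total <- rowSums(nonmiss)
  exp_hom <- nonmiss %*% exp_hom_l
  f <- as.numeric((obs_hom - exp_hom) / (total - exp_hom))
  ind <- data.frame(sample = gm$sample_id, pop = gm$pop,
                    obs_hom = obs_hom, exp_hom = as.numeric(exp_hom),
                    total = total, f = f, stringsAsFactors = FALSE)
  agg <- aggregate(f ~ pop, ind, mean)
  pops <- data.frame(pop = agg$pop,
                     n = as.integer(table(gm$pop)[agg$pop]),
                     mean_f = agg$f,
                     heterozygosity = 1 - agg$f,
                     capped = 1 - agg$f > 1,
                     stringsAsFactors = FALSE)
  list(individuals = ind, populations = pops)
}

#' Two-level analysis of molecular variance
#'
#' Decomposes squared pairwise allele-count distances between individuals
#' (mean-imputed dosages) into among-group and within-group components,
#' reports Phi_ST, the R-squared-style effect size SS_among / SS_total, and
#' a permutation p-value obtained by shuffling individuals among groups.
#'
#' @param gm a [genotype_matrix()].
#' @param grouping character vector (one value per individual), e.g.
#'   populations or regions; defaults to `gm$pop`.
#' @param n_perm number of permutations (>= 99 recommended).
#' @param seed integer seed for the permutation draw.
#' @return List of class `amova`: sums of squares, variance components,
#'   `phi_st`, `r_squared`, `p_value`, `n_perm`.
#' @export
amova <- function(gm, grouping = gm$pop, n_perm = 999L, seed = 1L) {
  grouping <- as.character(grouping)
  if (length(unique(grouping)) < 2L) stopf("AMOVA needs >= 2 groups")
  G <- gm$geno
  # mean-impute per locus so every pair is comparable
  mu <- colMeans(G, na.rm = TRUE)
  idx <- which(is.na(G), arr.ind = TRUE)
  if (nrow(idx)) G[idx] <- mu[idx[, 2]]
  d2 <- as.matrix(dist(G))^2
  N <- nrow(G)

  ss_of <- function(groups) {
    ss_w <- 0
    for (g in unique(groups)) {
      rows <- which(groups == g)
      if (length(rows) > 1L)
        ss_w <- ss_w + sum(d2[rows, rows][upper.tri(d2[rows, rows])]) / length(rows)
    }
    ss_w
  }
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- ss_of(grouping)
  ss_among <- ss_total - ss_within
  k <- length(unique(grouping))
  df_among <- k - 1L
  df_within <- N - k
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n_g <- table(grouping)
  n0 <- (N - sum(n_g^2) / N) / df_among
  sigma_w <- ms_within
  sigma_a <- (ms_among - ms_within) / n0
  phi <- sigma_a / (sigma_a + sigma_w)

  set.seed(seed)
  stat_perm <- replicate(n_perm, {
    gp <- sample(grouping)
    ss_w <- ss_of(gp)
    (ss_total - ss_w) / df_among / (ss_w / df_within)   # pseudo-F ordering
  })
  f_obs <- ms_among / ms_within
  p <- (sum(stat_perm >= f_obs) + 1) / (n_perm + 1)
  structure(list(ss_among = ss_among, ss_within = ss_within,
                 ss_total = ss_total, sigma_among = sigma_a,
                 sigma_within = sigma_w, phi_st = phi,
                 r_squared = ss_among / ss_total, f = f_obs,
                 p_value = p, n_perm = n_perm),
            class = "amova")
}

#' @export
print.amova <- function(x, ...) {
  cat("AMOVA (two-level)\n")
  cat(sprintf("  Phi_ST = %.4f, R^2 = %.3f, F = %.2f, p = %.4g (%d permutations)\n",
              x$phi_st, x$r_squared, x$f, x$p_value, x$n_perm))
  cat(sprintf("  variance components: among %.4g, within %.4g\n",
              x$sigma_among, x$sigma_within))
  invisible(x)
}
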