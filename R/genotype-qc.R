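# pooled A2 allele frequency per locus (ignoring missing calls)
allele_freq <- function(gm) {
  colSums(gm$geno, na.rm = TRUE) / (2 * colSums(!is.na(gm$geno)))
}

# per-population A2 frequency matrix (populations x loci)
pop_allele_freq <- function(gm) {
  pops <- sort(unique(gm$pop))
  out <- matrix(NA_real_, length(pops), ncol(gm$geno),
                dimnames = list(pops, gm$loci$id))
  for (p in pops) {
    rows <- gm$pop == p
    out[p, ] <- colSums(gm$geno[rows, , drop = FALSE], na.rm = TRUE) /
      (2 * colSums(!is.na(gm$geno[rows, , drop = FALSE])))
  }
  out
}

#' Exact test of Hardy--Weinberg equilibrium
#'
#' Two-sided exact test for one biallelic locus in one population, summing
#' the probabilities of all heterozygote counts (conditional on the observed
#' allele counts) that are no more probable than the observed one.
#' A monomorphic locus returns p = 1 by convention.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (A1 homozygote, heterozygote,
#'   A2 homozygote).
#' @return The exact p-value.
#' @export
hwe_exact <- function(n_hom1, n_het, n_hom2) {
  if (any(c(n_hom1, n_het, n_hom2) < 0)) stopf("genotype counts must be >= 0")
  n <- n_hom1 + n_het + n_hom2
  n_a <- 2 * n_hom1 + n_het           # copies of allele 1
  n_b <- 2 * n_hom2 + n_het
  rare <- min(n_a, n_b)
  if (n == 0 || rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  # P(het = h | n, allele counts): multinomial genotype probability
  # conditional on the allele margin
  logp <- lfactorial(n) - lfactorial((rare - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (rare + hets) / 2) + hets * log(2) +
    lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- which(hets == n_het)
  if (!length(obs)) stopf("heterozygote count inconsistent with allele counts")
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

# hwe_exact across all loci of one population's genotype submatrix
hwe_pvals <- function(geno) {
  vapply(seq_len(ncol(geno)), function(j) {
    g <- geno[, j]
    hwe_exact(sum(g == 0L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
              sum(g == 2L, na.rm = TRUE))
  }, numeric(1))
}

#' Method-of-moments relatedness (PI_HAT) for one pair
#'
#' Plink-style identity-by-descent estimate from identity-by-state counts
#' over the pair's co-genotyped loci, using whole-dataset allele
#' frequencies: PI_HAT = P(IBD=1)/2 + P(IBD=2), with the three IBD
#' probabilities clipped to \[0,1\] and renormalized.
#'
#' @param gm a [genotype_matrix()].
#' @param i,j individual indices or sample ids.
#' @return PI_HAT in \[0,1\].
#' @export
pi_hat <- function(gm, i, j) {
  if (is.character(i)) i <- match(i, gm$sample_id)
  if (is.character(j)) j <- match(j, gm$sample_id)
  gi <- gm$geno[i, ]; gj <- gm$geno[j, ]
  ok <- !is.na(gi) & !is.na(gj)
  if (!any(ok)) stopf("no co-genotyped loci for this pair; PI_HAT undefined")
  p <- allele_freq(gm)[ok]
  gi <- gi[ok]; gj <- gj[ok]
  q <- 1 - p
  ibs <- 2L - abs(gi - gj)
  n0 <- sum(ibs == 0L); n1 <- sum(ibs == 1L); n2 <- sum(ibs == 2L)
  e0_ibd0 <- sum(2 * p^2 * q^2)
  e1_ibd0 <- sum(4 * p^3 * q + 4 * p * q^3)
  e2_ibd0 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e1_ibd1 <- sum(2 * p^2 * q + 2 * p * q^2)
  e2_ibd1 <- sum(p^3 + q^3 + p^2 * q + p * q^2)
  n_loci <- sum(ok)
  p0 <- if (e0_ibd0 > 0) n0 / e0_ibd0 else 0
  p1 <- if (e1_ibd1 > 0) (n1 - p0 * e1_ibd0) / e1_ibd1 else 0
  p2 <- (n2 - p0 * e2_ibd0 - p1 * e2_ibd1) / n_loci
  pr <- pmin(pmax(c(p0, p1, p2), 0), 1)
  pr <- pr / sum(pr)
  min(max(pr[2] / 2 + pr[3], 0), 1)
}

# all-pairs PI_HAT (same estimator, matrix algebra over shared loci)
pi_hat_matrix <- function(gm) {
  G <- gm$geno
  N <- nrow(G)
  M <- !is.na(G); storage.mode(M) <- "double"
  A0 <- (G == 0L) & M; A1 <- (G == 1L) & M; A2 <- (G == 2L) & M
  A0[is.na(A0)] <- FALSE; A1[is.na(A1)] <- FALSE; A2[is.na(A2)] <- FALSE
  storage.mode(A0) <- storage.mode(A1) <- storage.mode(A2) <- "double"
  n2 <- A0 %*% t(A0) + A1 %*% t(A1) + A2 %*% t(A2)
  n0 <- A0 %*% t(A2) + A2 %*% t(A0)
  C <- M %*% t(M)
  n1 <- C - n0 - n2
  p <- allele_freq(gm); q <- 1 - p
  wsum <- function(w) M %*% (w * t(M))      # per-pair sum over co-typed loci
  e0_0 <- wsum(2 * p^2 * q^2)
  e1_0 <- wsum(4 * p^3 * q + 4 * p * q^3)
  e2_0 <- wsum(p^4 + q^4 + 4 * p^2 * q^2)
  e1_1 <- wsum(2 * p^2 * q + 2 * p * q^2)
  e2_1 <- wsum(p^3 + q^3 + p^2 * q + p * q^2)
  p0 <- ifelse(e0_0 > 0, n0 / e0_0, 0)
  p1 <- ifelse(e1_1 > 0, (n1 - p0 * e1_0) / e1_1, 0)
  p2 <- (n2 - p0 * e2_0 - p1 * e2_1) / pmax(C, 1)
  p0 <- pmin(pmax(p0, 0), 1); p1 <- pmin(pmax(p1, 0), 1); p2 <- pmin(pmax(p2, 0), 1)
  tot <- p0 + p1 + p2
  ph <- (p1 / 2 + p2) / ifelse(tot > 0, tot, 1)
  ph <- pmin(pmax(ph, 0), 1)
  diag(ph) <- 1
  dimnames(ph) <- list(gm$sample_id, gm$sample_id)
  ph
}

#' Apply the genotype quality-control filter chain
#'
#' Filters are applied in a fixed canonical order: (1) individuals with more
#' than `ind_miss` missing calls removed; (2) loci with more than
#' `locus_miss` missingness removed; (3) loci with minor allele frequency
#' below `maf` (pooled over retained individuals) removed; (4) one member of
#' each close-relative pair (PI_HAT > `pi_hat_max`) removed -- the member
#' with more missing data, ties broken by sample-id sort order; (5) loci out
#' of Hardy--Weinberg equilibrium (exact test p < `hwe_p`) in more than two
#' populations removed. Populations retaining at least `min_pop_n`
#' individuals are flagged as usable for population-level statistics.
#'
#' @param gm a [genotype_matrix()].
#' @param ind_miss,locus_miss missingness thresholds (proportions).
#' @param maf minor-allele-frequency threshold.
#' @param pi_hat_max relatedness threshold.
#' @param hwe_p per-population HWE p-value threshold.
#' @param hwe_pops locus removed if out of HWE in more than this many
#'   populations (strictly greater).
#' @param min_pop_n minimum retained individuals for population-level use.
#' @return List with `gm` (filtered matrix) and `report` (class
#'   `qc_report`): per-stage removal counts, final genotyping rate, and
#'   `pops_ok`, the populations meeting `min_pop_n`.
#' @export
apply_qc <- function(gm, ind_miss = 0.5, locus_miss = 0.3, maf = 0.03,
                     pi_hat_max = 0.5, hwe_p = 0.01, hwe_pops = 2L,
                     min_pop_n = 7L) {
  if (length(unique(gm$pop)) < 2L) stopf("QC needs at least 2 populations")
  dims_in <- dim(gm$geno)
  chk <- function(g, stage) {
    if (nrow(g$geno) == 0L || ncol(g$geno) == 0L)
      stopf("all individuals or loci filtered out at stage '%s'", stage)
    g
  }

  # 1. individual missingness
  im <- rowMeans(is.na(gm$geno))
  keep_i <- im <= ind_miss
  n_ind_miss <- sum(!keep_i)
  gm <- chk(gm_subset(gm, ind = which(keep_i)), "individual missingness")

  # 2. locus missingness
  lm_ <- colMeans(is.na(gm$geno))
  keep_l <- lm_ <= locus_miss
  n_loc_miss <- sum(!keep_l)
  gm <- chk(gm_subset(gm, loc = which(keep_l)), "locus missingness")

  # 3. MAF (pooled across all retained individuals)
  p <- allele_freq(gm)
  keep_l <- !is.na(p) & pmin(p, 1 - p) >= maf
  n_loc_maf <- sum(!keep_l)
  gm <- chk(gm_subset(gm, loc = which(keep_l)), "MAF")

  # 4. close relatives
  ph <- pi_hat_matrix(gm)
  drop <- character(0)
  repeat {
    ph_w <- ph
    ph_w[upper.tri(ph_w, diag = TRUE)] <- 0
    if (length(drop)) ph_w[drop, ] <- ph_w[, drop] <- 0
    idx <- which(ph_w > pi_hat_max, arr.ind = TRUE)
    if (!nrow(idx)) break
    pair <- gm$sample_id[idx[1, ]]
    miss <- rowMeans(is.na(gm$geno[pair, , drop = FALSE]))
    worse <- if (miss[1] != miss[2]) pair[which.max(miss)] else sort(pair)[2]
    drop <- c(drop, worse)
  }
  n_ind_rel <- length(drop)
  gm <- chk(gm_subset(gm, ind = which(!gm$sample_id %in% drop)), "relatedness")

  # 5. HWE per population
  pops_u <- unique(gm$pop)
  n_bad <- integer(ncol(gm$geno))
  for (p_ in pops_u) {
    sub <- gm$geno[gm$pop == p_, , drop = FALSE]
    if (nrow(sub) < 2L) next
    n_bad <- n_bad + (hwe_pvals(sub) < hwe_p)
  }
  keep_l <- n_bad <= hwe_pops
  n_loc_hwe <- sum(!keep_l)
  gm <- chk(gm_subset(gm, loc = which(keep_l)), "HWE")

  tab <- table(gm$pop)
  report <- structure(list(
    dims_in = dims_in, dims_out = dim(gm$geno),
    removed = c(ind_missingness = n_ind_miss, loci_missingness = n_loc_miss,
                loci_maf = n_loc_maf, ind_relatedness = n_ind_rel,
                loci_hwe = n_loc_hwe),
    removed_relatives = drop,
    genotyping_rate = mean(!is.na(gm$geno)),
    pops_ok = names(tab)[tab >= min_pop_n]), class = "qc_report")
  list(gm = gm, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC report\n")
  cat(sprintf("  input : %d individuals x %d loci\n", x$dims_in[1], x$dims_in[2]))
  r <- x$removed
  cat(sprintf("  removed: %d individuals (missingness), %d loci (missingness),\n",
              r["ind_missingness"], r["loci_missingness"]))
  cat(sprintf("           %d loci (MAF), %d individuals (relatedness), %d loci (HWE)\n",
              r["loci_maf"], r["ind_relatedness"], r["loci_hwe"]))
  cat(sprintf("  output: %d individuals x %d loci; genotyping rate %.3f\n",
              x$dims_out[1], x$dims_out[2], x$genotyping_rate))
  cat(sprintf("  populations usable for population-level statistics: %s\n",
              paste(x$pops_ok, collapse = ", ")))
  invisible(x)
}
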