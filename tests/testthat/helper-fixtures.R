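# shared fixture builders; all randomness is seeded by the caller

# quick genotype_matrix from a plain matrix
make_gm <- function(geno, pop, ids = NULL) {
  n <- nrow(geno); L <- ncol(geno)
  genotype_matrix(geno,
                  ids %||% sprintf("s%03d", seq_len(n)),
                  pop,
                  data.frame(id = sprintf("L%04d", seq_len(L)),
                             a1 = "A", a2 = "G", stringsAsFactors = FALSE))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# flat (single-region) Balding-Nichols simulation, coded independently of
# the package generator: serves as the neutral oracle for estimator tests
sim_flat_bn <- function(n_pops, n_ind, n_loci, fst, seed,
                        adaptive = 0L, slope = 0, env = NULL) {
  set.seed(seed)
  p_anc <- runif(n_loci, 0.05, 0.95)
  a <- p_anc * (1 - fst) / fst
  b <- (1 - p_anc) * (1 - fst) / fst
  pf <- matrix(0, n_pops, n_loci)
  for (i in seq_len(n_pops)) pf[i, ] <- rbeta(n_loci, a, b)
  if (adaptive > 0L) {
    if (is.null(env)) env <- as.numeric(scale(seq_len(n_pops)))
    for (j in seq_len(adaptive))
      pf[, j] <- plogis(qlogis(p_anc[j]) + slope * env)
  }
  pf <- pmin(pmax(pf, 1e-4), 1 - 1e-4)
  pop_of <- rep(seq_len(n_pops), each = n_ind)
  G <- matrix(rbinom(n_pops * n_ind * n_loci, 2L, pf[pop_of, ]),
              n_pops * n_ind, n_loci)
  list(gm = make_gm(G, sprintf("P%02d", pop_of)),
       pfreq = pf, env = env, adaptive = seq_len(adaptive))
}

# scalar Weir-Cockerham (1984) variance components for one biallelic locus,
# written step by step from the published estimator as an independent oracle
wc_oracle_locus <- function(geno_list) {
  r <- length(geno_list)
  n_i <- vapply(geno_list, function(g) sum(!is.na(g)), numeric(1))
  p_i <- vapply(geno_list, function(g) mean(g, na.rm = TRUE) / 2, numeric(1))
  h_i <- vapply(geno_list, function(g) mean(g == 1, na.rm = TRUE), numeric(1))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# exact HWE null distribution by Wigginton-style recurrence (independent of
# the package's direct log-factorial evaluation)
hwe_oracle <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  n_a <- 2 * n_hom1 + n_het
  rare <- min(n_a, 2 * n - n_a)
  if (n == 0 || rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  mid <- which.max(hets)                 # start from the largest het count
  probs[mid] <- 1
  if (mid > 1) for (k in mid:2) {
    h <- hets[k]
    # P(h-2) = P(h) * h (h-1) / ((nAA+1)(nBB+1) 4)
    naa <- (rare - h) / 2; nbb <- n - naa - h
    probs[k - 1] <- probs[k] * h * (h - 1) / (4 * (naa + 1) * (nbb + 1))
  }
  probs <- probs / sum(probs)
  obs <- which(hets == n_het)
  sum(probs[probs <= probs[obs] * (1 + 1e-12)])
}
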