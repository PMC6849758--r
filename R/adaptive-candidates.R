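#' Per-locus logistic environmental regressions
#'
#' Runs [logistic_env_regression()] for each requested locus against each
#' climate covariate, using each individual's population-level value.
#'
#' @param gm a [genotype_matrix()].
#' @param pops a `population_table` (columns `pop`, `tmax_now`, `rain_now`).
#' @param loci locus ids to test (typically the outlier set).
#' @param pops_use optional population subset (e.g. the main region) whose
#'   individuals enter the regressions.
#' @return data.frame: `id`, `covariate`, `slope`, `p`, `separated`.
#' @export
logistic_screen <- function(gm, pops, loci, pops_use = NULL) {
  if (!is.null(pops_use)) gm <- gm_subset(gm, ind = which(gm$pop %in% pops_use))
  cov_cols <- c(temperature = "tmax_now", rainfall = "rain_now")
  out <- expand.grid(id = loci, covariate = names(cov_cols),
                     stringsAsFactors = FALSE)
  out$slope <- out$p <- NA_real_
  out$separated <- NA
  for (k in seq_len(nrow(out))) {
    j <- match(out$id[k], gm$loci$id)
    if (is.na(j)) stopf("locus %s not present in genotype matrix", out$id[k])
    env <- pops[[cov_cols[out$covariate[k]]]][match(gm$pop, pops$pop)]
    fit <- tryCatch(logistic_env_regression(gm$geno[, j], env),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      out$slope[k] <- fit$slope
      out$p[k] <- fit$p
      out$separated[k] <- fit$separated
    }
  }
  out
}

#' Orient the climate-adaptive allele at a locus
#'
#' Sign convention: the warm-adaptive allele is the one whose frequency
#' increases with maximum temperature (positive logistic slope on the A2
#' dosage means A2); the dry-adaptive allele is the one whose frequency
#' decreases with summer rainfall (negative slope means A2).
#'
#' @param covariate "temperature" or "rainfall".
#' @param slope logistic slope of A2 dosage on the covariate.
#' @return "A1" or "A2"; `NA` (ambiguous) when the slope is exactly zero.
#' @export
orient_adaptive_allele <- function(covariate, slope) {
  if (is.na(slope) || slope == 0) return(NA_character_)
  if (covariate == "temperature") {
    if (slope > 0) "A2" else "A1"
  } else if (covariate == "rainfall") {
    if (slope < 0) "A2" else "A1"
  } else stopf("unknown covariate '%s'", covariate)
}

#' Nominate climate-adaptive candidate SNPs by strict intersection
#'
#' A locus becomes a candidate only when all three evidence types agree:
#' excess differentiation (envelope outlier), a genotype--environment
#' association flag for either covariate (the within-region scale by
#' default), and a significant per-locus logistic regression. Provenance is
#' recorded per locus, the adaptive allele is oriented from the logistic
#' slope, and per-population adaptive-allele frequencies are attached.
#'
#' @param gm a QC'd [genotype_matrix()].
#' @param pops a `population_table`.
#' @param outliers an `outlier_result` from [scan_outliers()].
#' @param gea output of [run_two_scales()].
#' @param logit output of [logistic_screen()] (run on the outlier loci).
#' @param gea_scale which GEA scale gates candidacy: "region" (default) or
#'   "full".
#' @param alpha_logit significance level for the logistic evidence.
#' @return List of class `candidate_set`: `loci` (per-candidate provenance
#'   and orientation) and `freq` (populations x candidates matrix of
#'   adaptive-allele frequencies).
#' @export
intersect_candidates <- function(gm, pops, outliers, gea, logit,
                                 gea_scale = c("region", "full"),
                                 alpha_logit = 0.05) {
  gea_scale <- match.arg(gea_scale)
  gsets <- gea[[gea_scale]]
  out_ids <- outliers$id[outliers$outlier]
  gea_flagged <- lapply(gsets, function(r) r$id[r$flag])
  gea_ids <- unique(unlist(gea_flagged))
  sig <- logit[!is.na(logit$p) & logit$p < alpha_logit, , drop = FALSE]
  logit_ids <- unique(sig$id)
  ids <- intersect(intersect(out_ids, gea_ids), logit_ids)

  loci <- data.frame(id = character(0), covariate = character(0),
                     adaptive_allele = character(0), slope = numeric(0),
                     theta = numeric(0), gea_q = numeric(0),
                     logit_p = numeric(0), stringsAsFactors = FALSE)
  for (id in ids) {
    # covariate: the GEA-flagged covariate; if both, the smaller q
    qs <- vapply(gsets, function(r) {
      row <- r[r$id == id, ]
      if (nrow(row) && row$flag) row$q else NA_real_
    }, numeric(1))
    covn <- names(which.min(qs))
    lg <- sig[sig$id == id & sig$covariate == covn, ]
    if (!nrow(lg)) lg <- sig[sig$id == id, ][1, ]
    loci <- rbind(loci, data.frame(
      id = id, covariate = covn,
      adaptive_allele = orient_adaptive_allele(lg$covariate, lg$slope),
      slope = lg$slope, theta = outliers$theta[outliers$id == id],
      gea_q = qs[covn], logit_p = lg$p, stringsAsFactors = FALSE))
  }
  rownames(loci) <- NULL
  freq <- NULL
  if (nrow(loci)) {
    pf <- pop_allele_freq(gm)[, loci$id, drop = FALSE]
    flip <- !is.na(loci$adaptive_allele) & loci$adaptive_allele == "A1"
    pf[, flip] <- 1 - pf[, flip]
    freq <- pf
  }
  structure(list(loci = loci, freq = freq), class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d climate-adaptive candidate loci\n",
              nrow(x$loci)))
  if (nrow(x$loci)) print(x$loci, row.names = FALSE)
  invisible(x)
}

#' Per-population adaptive-allele frequency summary
#'
#' @param candidates a [intersect_candidates()] result (must be non-empty).
#' @param low_freq threshold below which an adaptive allele counts as rare.
#' @return data.frame: `pop`, `mean_freq` (mean adaptive-allele frequency
#'   across candidate loci), `n_below` and `frac_below` (count and fraction
#'   of candidate loci with frequency < `low_freq`).
#' @export
population_summary <- function(candidates, low_freq = 0.25) {
  stopifnot(inherits(candidates, "candidate_set"))
  if (is.null(candidates$freq) || !nrow(candidates$loci))
    stopf("empty candidate set: no per-population summary")
  f <- candidates$freq
  data.frame(pop = rownames(f),
             mean_freq = rowMeans(f, na.rm = TRUE),
             n_below = rowSums(f < low_freq, na.rm = TRUE),
             frac_below = rowMeans(f < low_freq, na.rm = TRUE),
             stringsAsFactors = FALSE, row.names = NULL)
}
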