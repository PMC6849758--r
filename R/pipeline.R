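#' Default end-to-end pipeline configuration
#'
#' Returns the full parameter list consumed by [run_pipeline()], with every
#' stage's knobs in one place: simulation settings, QC thresholds, outlier
#' alpha, GEA latent-factor counts and run count, FDR, sea cost, the
#' range-shift ratio threshold tau, permutation counts and the master seed.
#'
#' @param seed master seed; each stage derives its own seed from it.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       sim = list(seed = as.integer(seed)),
       qc = list(ind_miss = 0.5, locus_miss = 0.3, maf = 0.03,
                 pi_hat_max = 0.5, hwe_p = 0.01, hwe_pops = 2L, min_pop_n = 7L),
       scan = list(alpha = 0.01, n_sim_loci = 10000L),
       gea = list(K_full = 3L, K_region = 2L, n_runs = 5L, fdr = 0.05),
       candidates = list(gea_scale = "region", alpha_logit = 0.05),
       connect = list(sea_cost = 200, buffer_radius = 2L, tau = 0.5),
       mrdm = list(n_perm = 1000L),
       stages = c("simulate", "qc", "stats", "scan", "gea", "candidates",
                  "connect", "mrdm", "assess"))
}

write_stage_csv <- function(x, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".csv"))
  write.csv(x, path, row.names = FALSE)
  path
}

#' Run the vulnerability-assessment pipeline end to end
#'
#' Executes the stages in dependency order on a synthetic study system:
#' simulate genotypes/landscape, genotype QC, population-genetic statistics,
#' the neutral-envelope outlier scan, the two-scale GEA, candidate
#' intersection and adaptive-allele summaries, circuit-theory connectivity
#' for present and future conditions, stepwise MRDM and the
#' isolation-by-environment test, and the final exposure/sensitivity/risk
#' assessment. Every stage writes CSV (and raster) artifacts under
#' `out_dir` and the run ends with a manifest recording parameters, seeds
#' and artifact checksums.
#'
#' @param config a [default_config()]-shaped list.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results: `sim`, `qc`,
#'   `het`, `fst_neutral`, `fst_adaptive`, `outliers`, `gea`, `candidates`,
#'   `connectivity`, `mrdm`, `ibe`, `risk`, `manifest_path`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("climvuln_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  artifacts <- character(0)
  say <- function(fmt, ...) message(sprintf(paste0("[climvuln] ", fmt), ...))
  run_stage <- function(name, expr) {
    say("stage %s", name)
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # -- simulate ------------------------------------------------------------
  sim <- run_stage("simulate", {
    cfg <- do.call(sim_config, config$sim)
    s <- simulate_study(cfg)
    write_ped_map(s$gm, file.path(out_dir, "genotypes.ped"),
                  file.path(out_dir, "genotypes.map"))
    artifacts <- c(artifacts, write_stage_csv(s$pops, out_dir, "populations"),
                    write_stage_csv(s$truth, out_dir, "truth"))
    for (nm in names(s$landscape))
      write_ascii_grid(s$landscape[[nm]], file.path(out_dir, paste0(nm, ".asc")))
    s
  })
  pops <- sim$pops

  # -- qc ------------------------------------------------------------------
  qc <- run_stage("qc", do.call(apply_qc, c(list(sim$gm), config$qc)))
  gm <- qc$gm
  pops_ok <- qc$report$pops_ok
  artifacts <- c(artifacts, write_stage_csv(
    data.frame(stage = names(qc$report$removed), removed = qc$report$removed),
    out_dir, "qc_report"))

  # -- scan (outliers; envelope calibrated to the observed mean theta) -----
  scan <- run_stage("scan", {
    st <- pop_locus_stats(gm, pops_ok)
    cmp <- wc_components(st$P, st$N, st$H)
    mean_theta <- sum(cmp$a, na.rm = TRUE) /
      sum(cmp$a + cmp$b + cmp$c, na.rm = TRUE)
    target <- min(max(mean_theta, 0.005), 0.5)
    env <- simulate_envelope(length(pops_ok),
                             as.integer(table(gm$pop)[pops_ok]),
                             target, config$scan$n_sim_loci, seed + 10L)
    res <- scan_outliers(gm, env, config$scan$alpha, pops_ok)
    artifacts <- c(artifacts, write_stage_csv(res, out_dir, "outliers"))
    list(envelope = env, result = res)
  })
  outlier_ids <- scan$result$id[scan$result$outlier]

  # -- stats (heterozygosity on non-outlier loci; F_ST matrices) -----------
  stats_res <- run_stage("stats", {
    neutral_loci <- setdiff(gm$loci$id, outlier_ids)
    het <- heterozygosity(gm_subset(gm, loc = match(neutral_loci, gm$loci$id)))
    fst_n <- fst_matrix(gm, pops_ok, neutral_loci)
    artifacts <- c(artifacts,
                    write_stage_csv(het$populations, out_dir, "heterozygosity"),
                    write_stage_csv(as.data.frame(as.matrix(fst_n)), out_dir,
                                    "fst_neutral"))
    list(het = het, fst_neutral = fst_n)
  })

  # -- gea -----------------------------------------------------------------
  gea <- run_stage("gea", run_two_scales(
    gm, pops, config$gea$K_full, config$gea$K_region,
    n_runs = config$gea$n_runs, seed = seed + 20L, fdr = config$gea$fdr))

  # -- candidates ----------------------------------------------------------
  cand <- run_stage("candidates", {
    logit <- logistic_screen(gm, pops, outlier_ids,
                             pops_use = pops$pop[pops$region == "main"])
    cs <- intersect_candidates(gm, pops, scan$result, gea, logit,
                               config$candidates$gea_scale,
                               config$candidates$alpha_logit)
    artifacts <- c(artifacts, write_stage_csv(cs$loci, out_dir, "candidates"))
    cs
  })
  fst_adaptive <- if (nrow(cand$loci) >= 1L)
    tryCatch(fst_matrix(gm, pops_ok, cand$loci$id), error = function(e) NULL)
  else NULL

  # -- connect -------------------------------------------------------------
  connect <- run_stage("connect", {
    sea <- sim$landscape$sea_mask
    surf_now <- build_cost_surface(sim$landscape$suitability_now, NULL, sea,
                                   config$connect$sea_cost)
    surf_fut <- build_cost_surface(sim$landscape$suitability_future, NULL, sea,
                                   config$connect$sea_cost)
    rd_now <- resistance_distance(surf_now, pops)
    rd_fut <- resistance_distance(surf_fut, pops)
    cm_now <- cumulative_current(surf_now, pops)
    cm_fut <- cumulative_current(surf_fut, pops)
    write_ascii_grid(cm_now$map, file.path(out_dir, "current_now.asc"))
    write_ascii_grid(cm_fut$map, file.path(out_dir, "current_future.asc"))
    flags <- connectivity_change(cm_now, cm_fut, pops,
                                 config$connect$buffer_radius,
                                 config$connect$tau)
    artifacts <- c(artifacts, write_stage_csv(flags, out_dir, "range_shift"))
    list(resistance_now = rd_now, resistance_future = rd_fut,
         current_now = cm_now, current_future = cm_fut, flags = flags)
  })

  # -- mrdm ----------------------------------------------------------------
  mrdm_res <- run_stage("mrdm", {
    geo <- euclidean_matrix(pops[pops$pop %in% pops_ok, ])
    rn <- connect$resistance_now[pops_ok, pops_ok]
    landscape <- list(suitability_resistance = dist_matrix(rn, check = FALSE))
    sw <- stepwise_residual(stats_res$fst_neutral, geo, landscape,
                            config$mrdm$n_perm, seed + 30L)
    ibe <- if (!is.null(fst_adaptive)) {
      pop_sub <- pops[match(pops_ok, pops$pop), ]
      ibe_test(fst_adaptive,
               list(temperature = setNames(pop_sub$tmax_now, pops_ok),
                    rainfall = setNames(pop_sub$rain_now, pops_ok)),
               config$mrdm$n_perm, seed + 40L)
    } else NULL
    list(stepwise = sw, ibe = ibe)
  })

  # -- assess --------------------------------------------------------------
  risk <- run_stage("assess", {
    land_cells <- which(sim$landscape$sea_mask$m == 0)
    thr_now <- max_sss_threshold(pops$suit_now,
                                 sim$landscape$suitability_now$m[land_cells])
    rec <- cbind(climate_dissimilarity(pops),
                 data.frame(suitable_now = pops$suit_now >= thr_now,
                            suitable_future = pops$suit_future >= thr_now))
    expo <- exposure_level(rec)
    sens_pops <- intersect(pops_ok, pops$pop)
    if (nrow(cand$loci) >= 1L) {
      smry <- population_summary(cand)
      smry <- smry[smry$pop %in% sens_pops, ]
      adaptive <- adaptive_sensitivity(smry$mean_freq, smry$frac_below)
      names(adaptive) <- smry$pop
    } else {
      adaptive <- setNames(rep("0", length(sens_pops)), sens_pops)
    }
    hp <- stats_res$het$populations
    hp <- hp[hp$pop %in% sens_pops, ]
    neutral <- neutral_sensitivity(pmin(pmax(hp$heterozygosity, 0), 1))
    sens <- data.frame(pop = hp$pop, adaptive = adaptive[hp$pop],
                       neutral = neutral, stringsAsFactors = FALSE)
    expo_s <- expo[expo$pop %in% sens$pop, c("pop", "level")]
    flags <- connect$flags[connect$flags$pop %in% sens$pop, c("pop", "flag")]
    rt <- assess_risk(expo_s, sens, flags)
    artifacts <- c(artifacts, write_stage_csv(as.data.frame(rt), out_dir, "risk"))
    rt
  })

  # -- manifest ------------------------------------------------------------
  manifest <- file.path(out_dir, "manifest.txt")
  md5 <- tools::md5sum(artifacts)
  writeLines(c(sprintf("climvuln %s", as.character(utils::packageVersion("climvuln"))),
               sprintf("seed: %d", seed),
               sprintf("stages: %s", paste(config$stages, collapse = " > ")),
               "artifacts:",
               sprintf("  %s  %s", md5, basename(names(md5)))),
             manifest)
  say("done; artifacts in %s", out_dir)
  invisible(list(sim = sim, qc = qc, het = stats_res$het,
                 fst_neutral = stats_res$fst_neutral,
                 fst_adaptive = fst_adaptive, outliers = scan$result,
                 gea = gea, candidates = cand, connectivity = connect,
                 mrdm = mrdm_res, risk = risk, out_dir = out_dir,
                 manifest_path = manifest))
}
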