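test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_pops = 0), "positive")
  expect_error(sim_config(target_fst = 0), "target_fst")
  expect_error(sim_config(target_fst = 1), "target_fst")
  expect_error(sim_config(missing_rate = 0.5), "missing_rate")
  expect_error(sim_config(grid_shape = c(1, 10)), "degenerate grid")
  expect_error(generate_landscape(sim_config(grid_shape = c(6, 6))), "8 x 8")
})

test_that("future deltas act exactly as configured on the rasters", {
  base <- list(n_pops = 4L, n_ind_per_pop = 5L, n_neutral = 50L,
               n_adaptive = 0L, seed = 3L, grid_shape = c(12L, 12L))
  # zero delta: future layers identical to current
  cfg0 <- do.call(sim_config, c(base, list(
    future_delta = list(tmax = list(add = 0), rain = list(mult = 1)))))
  l0 <- generate_landscape(cfg0)
  expect_identical(l0$tmax_future$m, l0$tmax_now$m)
  expect_identical(l0$rain_future$m, l0$rain_now$m)
  expect_identical(l0$suitability_future$m, l0$suitability_now$m)

  # the largest printed warming, +9.1 degC uniform: every cell differs by 9.1
  cfg9 <- do.call(sim_config, c(base, list(
    future_delta = list(tmax = list(add = 9.1), rain = list(mult = 1)))))
  l9 <- generate_landscape(cfg9)
  expect_equal(unique(as.numeric(round(l9$tmax_future$m - l9$tmax_now$m, 10))), 9.1)
})

test_that("the generator is deterministic given config and seed", {
  cfg <- sim_config(n_pops = 5, n_ind_per_pop = 6, n_neutral = 80,
                    n_adaptive = 4, seed = 17, grid_shape = c(14, 14))
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
})

test_that("populations land on distinct non-sea cells with raster-read env values", {
  cfg <- sim_config(n_pops = 10, seed = 23, grid_shape = c(20, 20),
                    n_neutral = 10, n_adaptive = 0)
  l <- generate_landscape(cfg)
  p <- generate_populations(cfg, l)
  expect_equal(nrow(p), 10)
  expect_equal(anyDuplicated(p[, c("row", "col")]), 0L)
  expect_true(all(l$sea_mask$m[cbind(p$row, p$col)] == 0))
  expect_equal(p$tmax_now, l$tmax_now$m[cbind(p$row, p$col)])
  expect_equal(p$rain_future, l$rain_future$m[cbind(p$row, p$col)])

  cfg1 <- sim_config(n_pops = 1, seed = 23, grid_shape = c(20, 20),
                     n_neutral = 10, n_adaptive = 0)
  p1 <- generate_populations(cfg1, generate_landscape(cfg1))
  expect_equal(nrow(p1), 1)
  expect_equal(p1$suit_now, l <- generate_landscape(cfg1)$suitability_now$m[
    cbind(p1$row, p1$col)])
})

test_that("more populations than land cells is rejected", {
  cfg <- sim_config(n_pops = 10, grid_shape = c(8, 8), n_neutral = 5,
                    n_adaptive = 0, seed = 1)
  l <- generate_landscape(cfg)
  cfg_big <- cfg
  cfg_big$n_pops <- sum(l$sea_mask$m == 0) + 1L
  expect_error(generate_populations(cfg_big, l), "more populations")
})

test_that("genotype calls are valid and missingness honours the config", {
  cfg <- sim_config(n_pops = 4, n_ind_per_pop = 6, n_neutral = 120,
                    n_adaptive = 5, missing_rate = 0, seed = 29,
                    grid_shape = c(12, 12))
  s <- simulate_study(cfg)
  expect_false(anyNA(s$gm$geno))
  expect_true(all(s$gm$geno %in% 0:2))
  expect_equal(sum(s$truth$is_adaptive), 5)
  # every adaptive locus carries one covariate, one allele and one slope
  ad <- s$truth[s$truth$is_adaptive, ]
  expect_false(anyNA(ad$adaptive_covariate))
  expect_false(anyNA(ad$adaptive_allele))
  expect_false(anyNA(ad$slope))

  cfg_m <- sim_config(n_pops = 4, n_ind_per_pop = 6, n_neutral = 400,
                      n_adaptive = 0, missing_rate = 0.2, seed = 29,
                      grid_shape = c(12, 12))
  s_m <- simulate_study(cfg_m)
  expect_equal(mean(is.na(s_m$gm$geno)), 0.2, tolerance = 0.02)
})

test_that("neutral differentiation within the main region hits the target", {
  cfg <- sim_config(n_pops = 10, n_ind_per_pop = 10, n_neutral = 2000,
                    n_adaptive = 0, target_fst = 0.056, missing_rate = 0,
                    seed = 37, grid_shape = c(25, 25))
  s <- simulate_study(cfg)
  main <- s$pops$pop[s$pops$region == "main"]
  st <- climvuln:::pop_locus_stats(s$gm, main)
  cmp <- climvuln:::wc_components(st$P, st$N, st$H)
  theta <- sum(cmp$a, na.rm = TRUE) / sum(cmp$a + cmp$b + cmp$c, na.rm = TRUE)
  expect_lt(abs(theta - 0.056), 0.015)
})

test_that("planted adaptive loci track their covariate across populations", {
  # pooled over 10 seeded replicates; the floor (0.5 at rho > 0.8, mean rho
  # 0.7) comes from a 100-replicate pilot of this generator, where the
  # climate shift rides on top of per-locus drift
  rho <- unlist(lapply(1:10, function(rep) {
    cfg <- sim_config(n_pops = 10, n_ind_per_pop = 10, n_neutral = 50,
                      n_adaptive = 10, env_effect = 2, missing_rate = 0,
                      seed = 43 + rep, grid_shape = c(25, 25))
    s <- simulate_study(cfg)
    pf <- climvuln:::pop_allele_freq(s$gm)[s$pops$pop, ]
    ad <- s$truth[s$truth$is_adaptive, ]
    vapply(seq_len(nrow(ad)), function(k) {
      env <- if (ad$adaptive_covariate[k] == "temperature") s$pops$tmax_now
             else s$pops$rain_now
      r <- abs(suppressWarnings(cor(pf[, ad$id[k]], env, method = "spearman")))
      if (is.na(r)) 0 else r
    }, numeric(1))
  }))
  expect_gte(mean(rho > 0.8), 0.5)
  expect_gte(mean(rho), 0.7)

  # null reduction: with env_effect = 0 the planted loci are plain neutral
  rej <- vapply(1:10, function(s_) {
    cfg0 <- sim_config(n_pops = 8, n_ind_per_pop = 8, n_neutral = 300,
                       n_adaptive = 12, env_effect = 0, missing_rate = 0,
                       seed = 500 + s_, grid_shape = c(20, 20))
    s0 <- simulate_study(cfg0)
    th <- climvuln:::per_locus_theta(s0$gm)
    ad0 <- s0$truth$is_adaptive
    suppressWarnings(
      wilcox.test(th$theta[ad0], th$theta[!ad0])$p.value) < 0.05
  }, logical(1))
  # allowed rejection rate: alpha + 3 binomial s.e. at 10 replicates
  expect_lte(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 10))
})

test_that("a planted close-relative pair exceeds the PI_HAT threshold", {
  cfg <- sim_config(n_pops = 5, n_ind_per_pop = 8, n_neutral = 600,
                    n_adaptive = 0, missing_rate = 0.05, seed = 47,
                    grid_shape = c(15, 15))
  s <- simulate_study(cfg)
  expect_gt(pi_hat(s$gm, 1, 2), 0.9)
})
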