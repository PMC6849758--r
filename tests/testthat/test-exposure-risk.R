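test_that("climate dissimilarity arithmetic matches hand values and conventions", {
  x <- data.frame(pop = c("A", "B"),
                  tmax_now = c(25.3, 31.6), tmax_future = c(28.6, 40.4),
                  rain_now = c(36, 61), rain_future = c(28, 27),
                  suit_now = c(100, 34), suit_future = c(80, 17))
  d <- climate_dissimilarity(x)
  expect_equal(d$delta_tmax, c(3.3, 8.8))
  expect_equal(d$delta_rain, c(-8, -34))
  expect_equal(d$pct_change_rain, c(-22.2, -55.7))
  expect_equal(d$pct_change_suit, c(-20.0, -50.0))

  # future identical to present: every change is zero
  same <- data.frame(tmax_now = 20, tmax_future = 20, rain_now = 80,
                     rain_future = 80, suit_now = 50, suit_future = 50)
  expect_true(all(climate_dissimilarity(same) == 0))

  # zero baseline: percent change undefined, flagged
  zero <- data.frame(tmax_now = 20, tmax_future = 21, rain_now = 0,
                     rain_future = 5, suit_now = 50, suit_future = 40)
  expect_warning(dz <- climate_dissimilarity(zero), "zero baseline")
  expect_true(is.na(dz$pct_change_rain))

  # half-away-from-zero rounding at one decimal
  expect_equal(climvuln:::round_half_up(c(0.25, -0.25, 2.345), 1),
               c(0.3, -0.3, 2.3))
  expect_equal(climvuln:::round_half_up(c(0.05, -0.05), 1), c(0.1, -0.1))
})

test_that("the max-SSS threshold matches exhaustive search and conventions", {
  # fully separable: the smallest candidate with sens+spec = 2
  t1 <- max_sss_threshold(rep(0.9, 4), rep(0.1, 5))
  expect_equal(as.numeric(t1), 0.9)
  expect_equal(attr(t1, "sss"), 2)

  # interleaved toy vectors against a brute-force oracle
  pres <- c(0.9, 0.6, 0.4); bg <- c(0.5, 0.3, 0.2)
  cand <- sort(unique(c(pres, bg)))
  sss <- vapply(cand, function(t) mean(pres >= t) + mean(bg < t), numeric(1))
  oracle <- cand[which.max(sss)]
  expect_equal(as.numeric(max_sss_threshold(pres, bg)), oracle)
  expect_equal(oracle, 0.4)

  # swapping the labels cannot do better than the true orientation
  t_sw <- max_sss_threshold(bg, pres)
  expect_lte(attr(t_sw, "sss"), attr(max_sss_threshold(pres, bg), "sss"))

  expect_warning(t_d <- max_sss_threshold(c(0.5, 0.5), 0.5), "degenerate")
  expect_true(attr(t_d, "degenerate"))
  expect_error(max_sss_threshold(numeric(0), 1), "at least one")
})

test_that("exposure ranks reproduce the printed population assignments", {
  clim <- iberia_climate()
  rec <- cbind(climate_dissimilarity(clim),
               clim[, c("suitable_now", "suitable_future")])
  ex <- exposure_level(rec)
  lvl <- setNames(ex$level, ex$pop)
  expect_equal(unname(lvl["Valencia"]), 4L)     # unsuitable + >50% rain loss
  expect_equal(unname(lvl["Albacete"]), 4L)
  expect_equal(unname(lvl["Girona"]), 3L)       # unsuitable, medium dissimilarity
  expect_equal(unname(lvl["Valladolid"]), 3L)   # +9.1 degC alone
  expect_equal(unname(lvl["Granada"]), 2L)      # suitable, big ENM loss, medium temp
  expect_equal(unname(lvl["Lisboa"]), 1L)
  # Bizkaia satisfies no printed formula: flagged, assigned the floor level
  expect_equal(unname(lvl["Bizkaia"]), 1L)
  expect_true(ex$mismatch[ex$pop == "Bizkaia"])
  expect_false(any(ex$mismatch[ex$pop %in% c("Valencia", "Granada", "Lisboa")]))
})

test_that("sensitivity codes follow the frequency and heterozygosity bins", {
  expect_equal(adaptive_sensitivity(0.4, 0.5), "++")
  expect_equal(adaptive_sensitivity(0.4, 0.2), "+")
  expect_equal(adaptive_sensitivity(0.6, 1 / 3), "0")
  expect_equal(adaptive_sensitivity(0.6, 0), "-")
  expect_equal(adaptive_sensitivity(0.5, 0), "-")   # boundary convention
  expect_equal(adaptive_sensitivity(0.5, 0.1), "0")
  expect_error(adaptive_sensitivity(1.2, 0), "mean_freq")

  expect_equal(neutral_sensitivity(0.95), "-")
  expect_equal(neutral_sensitivity(0.844), "0")
  expect_equal(neutral_sensitivity(0.664), "+")
  expect_equal(neutral_sensitivity(c(0.9, 0.75)), c("0", "0"))
})

test_that("sensitivity combination reproduces every printed overall code", {
  inputs <- iberia_risk_inputs()
  expect_equal(combine_sensitivity(inputs$adaptive, inputs$neutral),
               inputs$overall)
  # spot checks of the additive sign rule
  expect_equal(combine_sensitivity("++", "-"), "+")
  expect_equal(combine_sensitivity("+", "-"), "0")
  expect_equal(combine_sensitivity("-", "0"), "-")
})

test_that("the risk engine reproduces the printed classifications", {
  inputs <- iberia_risk_inputs()
  rl <- risk_level(inputs$exposure, inputs$overall, inputs$range_shift)
  expect_equal(rl$risk, inputs$risk)
  expect_equal(risk_level(4, "+", "-")$risk, "High")
  expect_equal(risk_level(4, "-", "-")$risk, "Medium-high")
  expect_equal(risk_level(1, "+", "+")$risk, "Low")
  # unreachable combination: loud, never silent
  un <- risk_level(4, "-", "+")
  expect_equal(un$risk, "Unclassified")
  expect_match(un$rule, "no rule covers")
})

test_that("risk is monotone over the classified input lattice", {
  levels_risk <- c(Low = 1, Medium = 2, `Medium-high` = 3, High = 4)
  sens_rank <- c(`-` = 1, `0` = 2, `+` = 3)
  range_rank <- c(`+` = 1, `-` = 2)   # losing connectivity raises risk
  lattice <- expand.grid(e = 1:4, s = c("-", "0", "+"), r = c("+", "-"),
                         stringsAsFactors = FALSE)
  lattice$risk <- risk_level(lattice$e, lattice$s, lattice$r)$risk
  cls <- lattice[lattice$risk != "Unclassified", ]
  for (i in seq_len(nrow(cls))) for (j in seq_len(nrow(cls))) {
    if (cls$e[i] >= cls$e[j] &&
        sens_rank[cls$s[i]] >= sens_rank[cls$s[j]] &&
        range_rank[cls$r[i]] >= range_rank[cls$r[j]]) {
      expect_gte(levels_risk[cls$risk[i]], levels_risk[cls$risk[j]])
    }
  }
  # the seven printed combinations are always classified
  inputs <- iberia_risk_inputs()
  expect_false(any(risk_level(inputs$exposure, inputs$overall,
                              inputs$range_shift)$risk == "Unclassified"))
})

test_that("assess_risk joins components by population and is deterministic", {
  out <- reproduce_risk_table()
  expect_s3_class(out$risk, "risk_table")
  expect_equal(nrow(out$risk), 7)
  out2 <- reproduce_risk_table()
  expect_identical(as.data.frame(out$risk), as.data.frame(out2$risk))

  bad <- data.frame(pop = c("X", "Y"), level = c(1, 2))
  sens <- data.frame(pop = c("X", "Z"), adaptive = "+", neutral = "0")
  rng <- data.frame(pop = c("X", "Y"), flag = "+")
  expect_error(assess_risk(bad, sens, rng), "do not match")
})
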