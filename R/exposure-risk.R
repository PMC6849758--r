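#' Climate and suitability dissimilarity between periods
#'
#' Computes, per population, the change in maximum temperature and summer
#' rainfall and the percent changes in rainfall and climatic suitability,
#' reported to one decimal with half-away-from-zero rounding (the printed-
#' table convention).
#'
#' @param x data.frame with columns `tmax_now`, `tmax_future`, `rain_now`,
#'   `rain_future`, `suit_now`, `suit_future` (and optionally `pop`).
#' @return data.frame: `pop` (if present), `delta_tmax` (degC),
#'   `delta_rain` (mm), `pct_change_rain`, `pct_change_suit` (%); a percent
#'   change with a zero baseline is `NA` with a warning.
#' @export
climate_dissimilarity <- function(x) {
  need <- c("tmax_now", "tmax_future", "rain_now", "rain_future",
            "suit_now", "suit_future")
  if (!all(need %in% names(x)))
    stopf("missing columns: %s", paste(setdiff(need, names(x)), collapse = ", "))
  pct <- function(now, fut) {
    out <- ifelse(now == 0, NA_real_, 100 * (fut - now) / now)
    if (anyNA(out)) warning("percent change undefined for zero baseline")
    out
  }
  res <- data.frame(
    delta_tmax = round_half_up(x$tmax_future - x$tmax_now, 1),
    delta_rain = round_half_up(x$rain_future - x$rain_now, 1),
    pct_change_rain = round_half_up(pct(x$rain_now, x$rain_future), 1),
    pct_change_suit = round_half_up(pct(x$suit_now, x$suit_future), 1))
  if (!is.null(x$pop)) res <- cbind(pop = x$pop, res)
  res
}

#' Threshold maximizing sensitivity plus specificity
#'
#' Converts continuous suitability into a binary suitable/unsuitable map by
#' the cut-off that maximizes sensitivity + specificity over the candidate
#' set of observed values (predicted suitable means value >= threshold);
#' ties go to the lowest threshold.
#'
#' @param presence suitability values at presence cells.
#' @param background suitability values at background cells.
#' @return The threshold, with attributes `sss` (achieved sum) and
#'   `degenerate` (all input values identical).
#' @export
max_sss_threshold <- function(presence, background) {
  if (!length(presence) || !length(background))
    stopf("need at least one presence and one background value")
  cand <- sort(unique(c(presence, background)))
  if (length(cand) == 1L) {
    warning("all suitability values identical; threshold degenerate")
    return(structure(cand, sss = 1, degenerate = TRUE))
  }
  sss <- vapply(cand, function(t)
    mean(presence >= t) + mean(background < t), numeric(1))
  best <- cand[which.max(sss)]   # which.max takes the first (lowest) on ties
  structure(best, sss = max(sss), degenerate = FALSE)
}

# dissimilarity bins used by the exposure rules
exposure_bins <- function(rec) {
  dec_rain <- -rec$pct_change_rain       # positive when rainfall decreases
  dec_suit <- -rec$pct_change_suit
  list(temp_high = rec$delta_tmax > 8,
       temp_med = rec$delta_tmax >= 6 & rec$delta_tmax <= 8,
       temp_low = rec$delta_tmax < 6,
       rain_high = dec_rain > 50,
       rain_med = dec_rain >= 25 & dec_rain <= 50,
       rain_low = dec_rain < 25,
       enm_small = dec_suit < 25,        # occurrence-probability change <25%
       enm_big = dec_suit >= 25,
       s2u = rec$suitable_now & !rec$suitable_future,
       remains = rec$suitable_now & rec$suitable_future)
}

#' Exposure rank (1--4) from climate and suitability change
#'
#' Rule engine over the dissimilarity bins (temperature increase: low <6,
#' medium 6--8, high >8 degC; rainfall decrease: low <25, medium 25--50,
#' high >50%; suitability: percent occurrence-probability change and the
#' binary suitable/unsuitable transition). Levels are evaluated from 4 down
#' to 1 and the highest satisfied level wins:
#' 4 = became unsuitable AND (temperature or rainfall high);
#' 3 = became unsuitable OR temperature high OR rainfall high;
#' 2 = remains suitable with >=25% suitability loss AND (temperature or
#' rainfall medium); 1 = remains suitable, <25% suitability change,
#' temperature and rainfall low. A record matching no rule is assigned
#' level 1 with `mismatch = TRUE` and the assignment path says so.
#'
#' @param rec data.frame with columns `delta_tmax`, `pct_change_rain`,
#'   `pct_change_suit`, `suitable_now`, `suitable_future` (and optionally
#'   `pop`).
#' @return data.frame: `pop` (if present), `level` (1--4), `rule`
#'   (assignment path), `mismatch`.
#' @export
exposure_level <- function(rec) {
  b <- exposure_bins(rec)
  n <- length(b$s2u)
  level <- integer(n); rule <- character(n); mismatch <- logical(n)
  for (k in seq_len(n)) {
    if (b$s2u[k] && (b$temp_high[k] || b$rain_high[k])) {
      level[k] <- 4L; rule[k] <- "became unsuitable + high climate dissimilarity"
    } else if (b$s2u[k] || b$temp_high[k] || b$rain_high[k]) {
      level[k] <- 3L; rule[k] <- "became unsuitable or one high dissimilarity"
    } else if (b$remains[k] && b$enm_big[k] && (b$temp_med[k] || b$rain_med[k])) {
      level[k] <- 2L; rule[k] <- "suitable, >25% suitability loss + medium dissimilarity"
    } else if (b$remains[k] && b$enm_small[k] && b$temp_low[k] && b$rain_low[k]) {
      level[k] <- 1L; rule[k] <- "suitable, low change in all variables"
    } else {
      level[k] <- 1L
      rule[k] <- "rule mismatch: no exposure formula satisfied (assigned 1)"
      mismatch[k] <- TRUE
    }
  }
  res <- data.frame(level = level, rule = rule, mismatch = mismatch,
                    stringsAsFactors = FALSE)
  if (!is.null(rec$pop)) res <- cbind(pop = rec$pop, res)
  res
}

#' Adaptive sensitivity code from adaptive-allele frequencies
#'
#' Codes: `++` (very high) mean frequency < 0.5 and more than a third of
#' adaptive alleles rare (< 0.25); `+` (high) mean < 0.5, a third or fewer
#' rare; `0` (medium) mean >= 0.5 with at least one rare allele; `-` (low)
#' mean > 0.5 and none rare. The boundary mean = 0.5 with no rare allele is
#' assigned `-`.
#'
#' @param mean_freq mean adaptive-allele frequency across candidate loci.
#' @param frac_below fraction of candidate loci with frequency < 0.25.
#' @return "++", "+", "0" or "-" (vectorized).
#' @export
adaptive_sensitivity <- function(mean_freq, frac_below) {
  stopifnot(all(mean_freq >= 0 & mean_freq <= 1),
            all(frac_below >= 0 & frac_below <= 1))
  ifelse(mean_freq < 0.5,
         ifelse(frac_below > 1 / 3, "++", "+"),
         ifelse(frac_below > 0, "0", "-"))
}

#' Neutral sensitivity code from heterozygosity
#'
#' Heterozygosity > 0.9 gives `-` (low sensitivity: high diversity),
#' 0.75--0.9 gives `0`, below 0.75 gives `+` (high sensitivity).
#'
#' @param het population heterozygosity in \[0, 1\].
#' @return "-", "0" or "+" (vectorized).
#' @export
neutral_sensitivity <- function(het) {
  stopifnot(all(het >= 0 & het <= 1))
  ifelse(het > 0.9, "-", ifelse(het >= 0.75, "0", "+"))
}

sens_score <- c("++" = 2, "+" = 1, "0" = 0, "-" = -1)

#' Combine adaptive and neutral sensitivity
#'
#' Additive sign rule: scores ++ = 2, + = 1, 0 = 0, - = -1 are summed and
#' the overall code is `+` for a positive sum, `0` for zero, `-` for a
#' negative sum.
#'
#' @param adaptive adaptive code ("++", "+", "0", "-").
#' @param neutral neutral code ("+", "0", "-").
#' @return "+", "0" or "-" (vectorized).
#' @export
combine_sensitivity <- function(adaptive, neutral) {
  s <- sens_score[adaptive] + sens_score[neutral]
  unname(ifelse(s >= 1, "+", ifelse(s <= -1, "-", "0")))
}

#' Overall risk level from exposure, sensitivity and range-shift potential
#'
#' Rules evaluated from High down, first match wins: High when exposure
#' 3--4, sensitivity high (+) and range shift low (-); Medium-high when
#' exposure 3--4 and (sensitivity high or range shift low); Medium when
#' exposure 2 and (sensitivity 0/+ or range shift low), or exposure 3 with
#' sensitivity -/0 and range shift +; Low when exposure 1 and (sensitivity
#' - or range shift +), or exposure 2 with sensitivity - and range shift +.
#' Combinations reached by no rule return "Unclassified" with a diagnostic,
#' never silently.
#'
#' @param exposure integer 1--4.
#' @param sensitivity overall code "+", "0" or "-".
#' @param range_shift "+" (high future connectivity) or "-" (low).
#' @return data.frame: `risk` in {"Low", "Medium", "Medium-high", "High",
#'   "Unclassified"} and `rule` (vectorized over the inputs).
#' @export
risk_level <- function(exposure, sensitivity, range_shift) {
  stopifnot(all(exposure %in% 1:4), all(sensitivity %in% c("+", "0", "-")),
            all(range_shift %in% c("+", "-")))
  n <- length(exposure)
  risk <- character(n); rule <- character(n)
  for (k in seq_len(n)) {
    e <- exposure[k]; s <- sensitivity[k]; r <- range_shift[k]
    if (e >= 3 && s == "+" && r == "-") {
      risk[k] <- "High"; rule[k] <- "exposure 3-4 + high sensitivity + low range shift"
    } else if (e >= 3 && (s == "+" || r == "-")) {
      risk[k] <- "Medium-high"; rule[k] <- "exposure 3-4 + (high sensitivity or low range shift)"
    } else if ((e == 2 && (s %in% c("0", "+") || r == "-")) ||
               (e == 3 && s %in% c("-", "0") && r == "+")) {
      risk[k] <- "Medium"; rule[k] <- "exposure 2 with sensitivity/range support, or exposure 3 buffered"
    } else if ((e == 1 && (s == "-" || r == "+")) ||
               (e == 2 && s == "-" && r == "+")) {
      risk[k] <- "Low"; rule[k] <- "low exposure with low sensitivity or high range shift"
    } else {
      risk[k] <- "Unclassified"
      rule[k] <- sprintf("no rule covers (exposure %d, sensitivity %s, range %s)",
                         e, s, r)
    }
  }
  data.frame(risk = risk, rule = rule, stringsAsFactors = FALSE)
}

#' Assemble the per-population risk table
#'
#' Joins exposure levels, overall sensitivity and range-shift flags by
#' population id and applies [risk_level()].
#'
#' @param exposures data.frame with `pop`, `level` (from
#'   [exposure_level()]).
#' @param sensitivities data.frame with `pop`, `adaptive`, `neutral`
#'   (codes) or a ready `overall` column.
#' @param range_flags data.frame with `pop`, `flag` ("+"/"-").
#' @return data.frame of class `risk_table`: per-population components and
#'   final `risk`, with class counts as attribute `counts`.
#' @export
assess_risk <- function(exposures, sensitivities, range_flags) {
  ids <- exposures$pop
  if (!setequal(ids, sensitivities$pop) || !setequal(ids, range_flags$pop))
    stopf("population ids do not match across the three components")
  sens <- sensitivities[match(ids, sensitivities$pop), , drop = FALSE]
  rng <- range_flags[match(ids, range_flags$pop), , drop = FALSE]
  overall <- sens$overall %||% combine_sensitivity(sens$adaptive, sens$neutral)
  rl <- risk_level(exposures$level, overall, rng$flag)
  out <- data.frame(pop = ids, exposure = exposures$level,
                    adaptive = sens$adaptive %||% NA_character_,
                    neutral = sens$neutral %||% NA_character_,
                    sensitivity = overall, range_shift = rng$flag,
                    risk = rl$risk, rule = rl$rule, stringsAsFactors = FALSE)
  attr(out, "counts") <- table(factor(out$risk, levels = c(
    "Low", "Medium", "Medium-high", "High", "Unclassified")))
  class(out) <- c("risk_table", "data.frame")
  out
}

#' @export
print.risk_table <- function(x, ...) {
  print.data.frame(x[, setdiff(names(x), "rule")], row.names = FALSE)
  cat("\nrisk class counts:\n")
  print(attr(x, "counts"))
  invisible(x)
}

#' Printed climate-change fixture for the Iberian/English populations
#'
#' Loads the shipped per-population current/future climate and suitability
#' table (with the binary suitable/unsuitable statements) used by the
#' worked example and the regression tests of the rule engines.
#'
#' @return data.frame, one row per population.
#' @export
iberia_climate <- function() {
  read.csv(system.file("extdata", "iberia_climate.csv", package = "climvuln"),
           stringsAsFactors = FALSE)
}

#' Printed risk-component fixture for the Iberian populations
#'
#' Per-population exposure rank, adaptive and neutral sensitivity codes,
#' overall sensitivity, range-shift flag and final risk class, as shipped
#' for regression-testing the risk engine.
#'
#' @return data.frame, one row per population.
#' @export
iberia_risk_inputs <- function() {
  read.csv(system.file("extdata", "iberia_risk_inputs.csv", package = "climvuln"),
           stringsAsFactors = FALSE, check.names = FALSE)
}

#' Reproduce the per-population risk table from the shipped fixtures
#'
#' Runs [climate_dissimilarity()] and [exposure_level()] on the climate
#' fixture, combines the shipped sensitivity codes and range-shift flags,
#' and applies the risk engine -- the package's end-to-end worked example.
#'
#' @return List: `dissimilarity`, `exposure`, and `risk` (a `risk_table`).
#' @export
reproduce_risk_table <- function() {
  clim <- iberia_climate()
  dis <- climate_dissimilarity(clim)
  rec <- cbind(dis, clim[, c("suitable_now", "suitable_future")])
  expo <- exposure_level(rec)
  inputs <- iberia_risk_inputs()
  expo_i <- expo[expo$pop %in% inputs$pop, ]
  risk <- assess_risk(expo_i[, c("pop", "level")],
                      inputs[, c("pop", "adaptive", "neutral")],
                      data.frame(pop = inputs$pop, flag = inputs$range_shift))
  list(dissimilarity = dis, exposure = expo, risk = risk)
}
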