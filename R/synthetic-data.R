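#' Simulation configuration
#'
#' Bundles every knob of the synthetic study system. Defaults emulate the
#' scale of the motivating study design: 10 populations of 7--10 sampled
#' individuals split over two regions (a large "main" region holding most
#' populations and a small northern one), roughly 6,000 biallelic SNPs of
#' which a handful are climate-adaptive, neutral differentiation within the
#' main region around F_ST = 0.056, ~8% missing calls, and paired
#' current/future rasters of maximum temperature and summer rainfall with a
#' mean warming of +6.9 degC and a ~40% rainfall reduction.
#'
#' @param n_pops number of populations.
#' @param n_ind_per_pop individuals sampled per population (scalar or vector
#'   of length `n_pops`).
#' @param n_neutral,n_adaptive numbers of neutral and climate-adaptive loci.
#' @param target_fst Balding--Nichols F for populations within a region
#'   (the neutral differentiation level the generator aims at).
#' @param region_fst Balding--Nichols F for the region split (hierarchical
#'   structure above `target_fst`).
#' @param env_effect log-odds slope of adaptive-allele frequency per
#'   standard deviation of the environmental covariate.
#' @param missing_rate probability that a genotype call is missing.
#' @param seed integer seed; all generator randomness derives from it.
#' @param grid_shape integer `c(rows, cols)` of the raster grid (each >= 8).
#' @param future_delta per-raster change specification: a list with elements
#'   `tmax = list(add = )` (additive, degC) and `rain = list(mult = )`
#'   (multiplicative).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 10L, n_ind_per_pop = 9L, n_neutral = 6000L,
                       n_adaptive = 8L, target_fst = 0.056,
                       region_fst = 0.15, env_effect = 2.0,
                       missing_rate = 0.08, seed = 1L,
                       grid_shape = c(40L, 40L),
                       future_delta = list(tmax = list(add = 6.9),
                                           rain = list(mult = 0.6))) {
  if (n_pops < 1L || n_neutral < 1L || n_adaptive < 0L)
    stopf("counts must be positive")
  if (any(n_ind_per_pop < 1L)) stopf("n_ind_per_pop must be positive")
  if (!(target_fst > 0 && target_fst < 1)) stopf("target_fst must be in (0,1)")
  if (missing_rate < 0 || missing_rate >= 0.5)
    stopf("missing_rate must be in [0, 0.5)")
  if (length(grid_shape) != 2L || any(grid_shape < 2L))
    stopf("degenerate grid: both dimensions of grid_shape must be >= 2")
  n_ind <- if (length(n_ind_per_pop) == 1L) rep(as.integer(n_ind_per_pop), n_pops)
           else as.integer(n_ind_per_pop)
  if (length(n_ind) != n_pops) stopf("n_ind_per_pop must have length 1 or n_pops")
  structure(list(n_pops = as.integer(n_pops), n_ind_per_pop = n_ind,
                 n_neutral = as.integer(n_neutral),
                 n_adaptive = as.integer(n_adaptive),
                 target_fst = target_fst, region_fst = region_fst,
                 env_effect = env_effect, missing_rate = missing_rate,
                 seed = as.integer(seed), grid_shape = as.integer(grid_shape),
                 future_delta = future_delta),
            class = "sim_config")
}

# smooth random field: iid normal noise blurred by repeated 3x3 box filters
smooth_field <- function(nr, nc, sd = 1, passes = 6L) {
  m <- matrix(rnorm(nr * nc, sd = sd), nr, nc)
  for (k in seq_len(passes)) {
    p <- rbind(m[1, ], m, m[nr, ])
    p <- cbind(p[, 1], p, p[, nc])
    m <- (p[1:nr, 1:nc] + p[1:nr, 2:(nc + 1)] + p[1:nr, 3:(nc + 2)] +
          p[2:(nr + 1), 1:nc] + p[2:(nr + 1), 2:(nc + 1)] + p[2:(nr + 1), 3:(nc + 2)] +
          p[3:(nr + 2), 1:nc] + p[3:(nr + 2), 2:(nc + 1)] + p[3:(nr + 2), 3:(nc + 2)]) / 9
  }
  m
}

# Gaussian climatic niche shared by present and future suitability layers,
# so suitable -> unsuitable transitions arise mechanistically from climate
suitability_fun <- function(tmax, rain, t_opt = 26, t_sd = 4.5,
                            r_opt = 130, r_sd = 90) {
  exp(-((tmax - t_opt)^2 / (2 * t_sd^2) + (rain - r_opt)^2 / (2 * r_sd^2)))
}

apply_delta <- function(m, spec) {
  if (is.null(spec)) return(m)
  if (!is.null(spec$add)) m <- m + spec$add
  if (!is.null(spec$mult)) m <- m * spec$mult
  m
}

#' Generate a synthetic landscape raster stack
#'
#' Builds smooth environmental surfaces (low-order spatial trends plus
#' smoothed noise): current and future maximum temperature and summer
#' rainfall, a habitat-suitability layer for each period derived from the
#' same climatic niche function, land cover, slope, altitude, and a boolean
#' sea mask along the western edge. Future climate layers apply
#' `cfg$future_delta`; future suitability is recomputed from future climate.
#'
#' @param cfg a [sim_config()].
#' @return Named list of [ascii_grid()] layers: `tmax_now`, `rain_now`,
#'   `tmax_future`, `rain_future`, `suitability_now`, `suitability_future`,
#'   `landcover`, `slope`, `altitude`, `sea_mask` (0/1).
#' @export
generate_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(cfg$grid_shape < 8L)) stopf("grid_shape must be at least 8 x 8")
  nr <- cfg$grid_shape[1]; nc <- cfg$grid_shape[2]
  set.seed(cfg$seed)

  row_f <- matrix((seq_len(nr) - 1) / (nr - 1), nr, nc)          # 0 north -> 1 south
  col_f <- matrix(rep((seq_len(nc) - 1) / (nc - 1), each = nr), nr, nc)

  altitude <- pmax(800 * smooth_field(nr, nc, sd = 1.5, passes = 8L) +
                     1600 * row_f * (1 - row_f) - 200, 0)
  # slope: finite-difference gradient magnitude of altitude
  gx <- cbind(altitude[, 2] - altitude[, 1],
              (altitude[, -(1:2), drop = FALSE] - altitude[, 1:(nc - 2), drop = FALSE]) / 2,
              altitude[, nc] - altitude[, nc - 1])
  gy <- rbind(altitude[2, ] - altitude[1, ],
              (altitude[-(1:2), , drop = FALSE] - altitude[1:(nr - 2), , drop = FALSE]) / 2,
              altitude[nr, ] - altitude[nr - 1, ])
  slope <- sqrt(gx^2 + gy^2)

  tmax_now <- 20 + 10 * row_f + 2 * col_f - altitude / 400 +
    smooth_field(nr, nc, sd = 2, passes = 5L)
  rain_now <- pmax(220 - 170 * row_f + altitude / 20 +
                     20 * smooth_field(nr, nc, sd = 1, passes = 5L), 5)

  tmax_future <- apply_delta(tmax_now, cfg$future_delta$tmax)
  rain_future <- apply_delta(rain_now, cfg$future_delta$rain)

  lc_field <- smooth_field(nr, nc, sd = 1, passes = 4L) + 0.5 * row_f
  landcover <- matrix(cut(lc_field, breaks = quantile(lc_field, c(0, .3, .6, .85, 1)),
                          labels = FALSE, include.lowest = TRUE), nr, nc)

  # sea: a wavy band along the western edge (deterministic in grid shape)
  width <- pmax(2L, round(nc * 0.08))
  coast <- width + round(1.5 * sin(seq_len(nr) / nr * 2 * pi))
  sea <- matrix(0, nr, nc)
  for (i in seq_len(nr)) sea[i, seq_len(max(1L, coast[i]))] <- 1

  suit_now <- suitability_fun(tmax_now, rain_now)
  suit_fut <- suitability_fun(tmax_future, rain_future)
  suit_now[sea == 1] <- 0
  suit_fut[sea == 1] <- 0

  lapply(list(tmax_now = tmax_now, rain_now = rain_now,
              tmax_future = tmax_future, rain_future = rain_future,
              suitability_now = suit_now, suitability_future = suit_fut,
              landcover = landcover, slope = slope, altitude = altitude,
              sea_mask = sea),
         ascii_grid)
}

#' Place populations on the synthetic landscape
#'
#' Samples `cfg$n_pops` distinct non-sea cells, spread out by a greedy
#' minimum-distance rule, and reads each population's environmental values
#' from the raster stack at its cell. Populations falling in the northern
#' fifth of the grid are labelled region "north" (the small marginal region);
#' at least one population is forced there when `n_pops >= 5` so both scales
#' of the analysis are exercised.
#'
#' @param cfg a [sim_config()].
#' @param landscape output of [generate_landscape()].
#' @return A data.frame (class `population_table`): `pop`, `row`, `col`,
#'   `x`, `y`, `region`, `n_ind`, and per-period environmental columns.
#' @export
generate_populations <- function(cfg, landscape) {
  sea <- landscape$sea_mask$m
  nr <- nrow(sea); nc <- ncol(sea)
  land <- which(sea == 0)
  if (length(land) < cfg$n_pops) stopf("more populations than land cells")
  set.seed(cfg$seed + 1L)

  north_band <- floor(nr / 5)
  n_north <- if (cfg$n_pops >= 5L) max(1L, round(cfg$n_pops / 5)) else 0L
  rows_of <- (land - 1L) %% nr + 1L
  north_cells <- land[rows_of <= north_band]
  south_cells <- land[rows_of > north_band]
  min_d <- sqrt(nr * nc / cfg$n_pops) / 2

  pick_spread <- function(cells, k, chosen_rc) {
    for (cell in sample(cells)) {
      if (k == 0L) break
      rc <- c((cell - 1L) %% nr + 1L, (cell - 1L) %/% nr + 1L)
      if (!nrow(chosen_rc) ||
          min(sqrt(colSums((t(chosen_rc) - rc)^2))) >= min_d) {
        chosen_rc <- rbind(chosen_rc, rc)
        k <- k - 1L
      }
    }
    chosen_rc
  }
  chosen <- matrix(numeric(0), 0, 2)
  chosen <- pick_spread(north_cells, n_north, chosen)
  chosen <- pick_spread(south_cells, cfg$n_pops - nrow(chosen), chosen)
  if (nrow(chosen) < cfg$n_pops) {  # relax the spacing rule if needed
    left <- setdiff(land, (chosen[, 2] - 1L) * nr + chosen[, 1])
    extra <- sample(left, cfg$n_pops - nrow(chosen))
    chosen <- rbind(chosen, cbind((extra - 1L) %% nr + 1L, (extra - 1L) %/% nr + 1L))
  }
  ord <- order(chosen[, 1], chosen[, 2])
  chosen <- chosen[ord, , drop = FALSE]

  at <- function(layer) layer$m[chosen]
  pops <- data.frame(
    pop = sprintf("P%02d", seq_len(cfg$n_pops)),
    row = chosen[, 1], col = chosen[, 2],
    x = chosen[, 2] - 0.5, y = nr - chosen[, 1] + 0.5,
    region = ifelse(chosen[, 1] <= north_band, "north", "main"),
    n_ind = cfg$n_ind_per_pop,
    tmax_now = at(landscape$tmax_now), rain_now = at(landscape$rain_now),
    tmax_future = at(landscape$tmax_future), rain_future = at(landscape$rain_future),
    suit_now = at(landscape$suitability_now),
    suit_future = at(landscape$suitability_future),
    stringsAsFactors = FALSE)
  class(pops) <- c("population_table", "data.frame")
  pops
}

# Balding-Nichols draw: population frequency around ancestral p at divergence F
rbn <- function(n, p, f) {
  a <- p * (1 - f) / f
  b <- (1 - p) * (1 - f) / f
  rbeta(n, a, b)
}

#' Generate genotypes with planted climate-adaptive loci
#'
#' Neutral loci follow a hierarchical Balding--Nichols model: ancestral
#' frequencies are Uniform(0.05, 0.95); each region draws its frequency at
#' divergence `cfg$region_fst`, and each population draws around its region
#' at `cfg$target_fst`. Adaptive loci instead get population frequencies
#' logistic in the standardized covariate (alternating maximum temperature
#' and summer rainfall) with log-odds slope `cfg$env_effect`. Diploid
#' genotypes are binomial draws; missing calls are injected uniformly at
#' random; one pair of close relatives is planted by copying an individual
#' and re-sampling 5% of its genotypes.
#'
#' @param cfg a [sim_config()].
#' @param pops output of [generate_populations()].
#' @return A list with elements `gm` (a [genotype_matrix()]) and `truth`
#'   (data.frame: `id`, `is_adaptive`, `adaptive_covariate`,
#'   `adaptive_allele` in {"A1","A2"}, `slope`).
#' @export
generate_genotypes <- function(cfg, pops) {
  n_loci <- cfg$n_neutral + cfg$n_adaptive
  if (cfg$n_adaptive > n_loci) stopf("n_adaptive exceeds total loci")
  set.seed(cfg$seed + 2L)
  n_pops <- nrow(pops)
  n_ind <- pops$n_ind
  N <- sum(n_ind)
  pop_of <- rep(seq_len(n_pops), n_ind)

  p_anc <- runif(n_loci, 0.05, 0.95)
  is_adaptive <- rep(FALSE, n_loci)
  if (cfg$n_adaptive > 0L)
    is_adaptive[sample(n_loci, cfg$n_adaptive)] <- TRUE

  regions <- unique(pops$region)
  # population frequency matrix (n_pops x n_loci)
  pfreq <- matrix(NA_real_, n_pops, n_loci)
  for (rg in regions) {
    idx <- which(pops$region == rg)
    p_rg <- if (length(regions) > 1L) rbn(n_loci, p_anc, cfg$region_fst) else p_anc
    p_rg <- pmin(pmax(p_rg, 1e-4), 1 - 1e-4)
    for (i in idx) pfreq[i, ] <- rbn(n_loci, p_rg, cfg$target_fst)
  }
  pfreq <- pmin(pmax(pfreq, 1e-4), 1 - 1e-4)

  cov_names <- c("temperature", "rainfall")
  truth <- data.frame(id = sprintf("L%05d", seq_len(n_loci)),
                      is_adaptive = is_adaptive,
                      adaptive_covariate = NA_character_,
                      adaptive_allele = NA_character_,
                      slope = NA_real_, stringsAsFactors = FALSE)
  ad <- which(is_adaptive)
  if (length(ad)) {
    z_t <- as.numeric(scale(pops$tmax_now))
    z_r <- as.numeric(scale(pops$rain_now))
    for (k in seq_along(ad)) {
      j <- ad[k]
      covn <- cov_names[(k - 1L) %% 2L + 1L]
      z <- if (covn == "temperature") z_t else z_r
      # warm-adaptive alleles rise with temperature; dry-adaptive fall with
      # rain; the climate shift acts on top of the locus's neutral drift so
      # env_effect = 0 reduces exactly to the neutral model
      slope <- if (covn == "temperature") cfg$env_effect else -cfg$env_effect
      pfreq[, j] <- stats::plogis(stats::qlogis(pfreq[, j]) + slope * z)
      truth$adaptive_covariate[j] <- covn
      truth$adaptive_allele[j] <- "A2"
      truth$slope[j] <- slope
    }
  }

  geno <- matrix(rbinom(N * n_loci, 2L, pfreq[pop_of, ]), N, n_loci)

  # planted close-relative pair: individual 2 becomes a noisy copy of 1
  if (N >= 2L && n_ind[1] >= 2L) {
    geno[2L, ] <- geno[1L, ]
    flip <- which(runif(n_loci) < 0.05)
    if (length(flip))
      geno[2L, flip] <- rbinom(length(flip), 2L, pfreq[1L, flip])
  }

  if (cfg$missing_rate > 0)
    geno[matrix(runif(N * n_loci) < cfg$missing_rate, N, n_loci)] <- NA_integer_

  pairs <- cbind(c("A", "C", "G", "T")[sample.int(4L, n_loci, replace = TRUE)], "")
  other <- c(A = "G", C = "T", G = "A", T = "C")
  pairs[, 2] <- other[pairs[, 1]]
  loci <- data.frame(id = truth$id, a1 = pairs[, 1], a2 = pairs[, 2],
                     chrom = 1L, pos = seq_len(n_loci), stringsAsFactors = FALSE)
  ids <- sprintf("%s_i%02d", pops$pop[pop_of], sequence(n_ind))
  gm <- genotype_matrix(geno, ids, pops$pop[pop_of], loci)
  list(gm = gm, truth = truth)
}

#' Generate a complete synthetic study system
#'
#' Convenience wrapper running [generate_landscape()],
#' [generate_populations()] and [generate_genotypes()] in sequence.
#'
#' @param cfg a [sim_config()].
#' @return List with `landscape`, `pops`, `gm`, `truth`, and the `cfg` used.
#' @export
simulate_study <- function(cfg = sim_config()) {
  landscape <- generate_landscape(cfg)
  pops <- generate_populations(cfg, landscape)
  g <- generate_genotypes(cfg, pops)
  list(landscape = landscape, pops = pops, gm = g$gm, truth = g$truth,
       cfg = cfg)
}
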