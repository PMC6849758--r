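# random symmetric distance matrix with zero diagonal
rand_dist <- function(k, labels = sprintf("P%02d", seq_len(k))) {
  m <- matrix(0, k, k)
  m[lower.tri(m)] <- runif(k * (k - 1) / 2)
  dist_matrix(m + t(m), labels = labels)
}

test_that("a perfect affine fit reaches R^2 = 1 and the minimal p-value", {
  set.seed(73)
  x <- rand_dist(8)
  y <- dist_matrix(3 + 2 * unclass(x) - 3 * diag(8) * 0, labels = rownames(x),
                   check = FALSE)
  diag(y) <- 0
  fit <- mrdm_fit(y, list(x = x), n_perm = 999, seed = 1)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$p_overall, 1 / 1000)
  expect_equal(unname(fit$coefficients["x"]), 2, tolerance = 1e-10)
})

test_that("OLS coefficients match the normal-equations oracle", {
  set.seed(79)
  k <- 9
  preds <- list(a = rand_dist(k), b = rand_dist(k))
  y <- rand_dist(k)
  fit <- mrdm_fit(y, preds, n_perm = 9, seed = 1)
  X <- cbind(1, vapply(preds, function(m) m[lower.tri(m)], numeric(36)))
  beta <- solve(t(X) %*% X, t(X) %*% y[lower.tri(y)])
  expect_equal(unname(fit$coefficients), as.numeric(beta), tolerance = 1e-10)
})

test_that("degenerate MRDM inputs are rejected", {
  set.seed(83)
  y <- rand_dist(6)
  expect_error(mrdm_fit(y, list(x = rand_dist(6)), n_perm = 0), "n_perm")
  const <- dist_matrix(matrix(1, 6, 6) - diag(6), labels = rownames(y))
  expect_error(mrdm_fit(y, list(x = const), n_perm = 9), "constant predictor")
  other <- rand_dist(6, labels = sprintf("Q%02d", 1:6))
  expect_error(mrdm_fit(y, list(x = other), n_perm = 9), "mismatched")
  expect_error(mrdm_fit(rand_dist(3), list(x = rand_dist(3)), n_perm = 9),
               ">= 4 populations")
})

test_that("null MRDM p-values are roughly uniform (quick check)", {
  set.seed(89)
  pv <- vapply(1:30, function(s) {
    mrdm_fit(rand_dist(9), list(x = rand_dist(9)), n_perm = 199,
             seed = s)$p_overall
  }, numeric(1))
  expect_lte(mean(pv < 0.05), 0.2)
  expect_gt(suppressWarnings(ks.test(pv, "punif")$p.value), 0.001)
})

test_that("permutation p is stable under population relabeling", {
  set.seed(97)
  k <- 8
  geo <- rand_dist(k)
  y <- dist_matrix(0.6 * unclass(geo) + unclass(rand_dist(k)) * 0.4,
                   labels = rownames(geo), check = FALSE)
  diag(y) <- 0
  p1 <- mrdm_fit(y, list(g = geo), n_perm = 4999, seed = 5)$p_overall
  perm <- sample(k)
  relab <- function(m) dist_matrix(unclass(m)[perm, perm],
                                   labels = rownames(m)[perm], check = FALSE)
  p2 <- mrdm_fit(relab(y), list(g = relab(geo)), n_perm = 4999, seed = 11)$p_overall
  expect_lt(abs(p1 - p2), 0.03)
})

test_that("collinearity screening drops duplicates and keeps near-threshold predictors", {
  set.seed(101)
  k <- 9
  geo <- rand_dist(k)
  # predictor correlated with geo at R^2 just below / above the cut
  scale_vec <- function(m) as.numeric(scale(m[lower.tri(m)]))
  noise <- rand_dist(k)
  mix <- function(w) {
    m <- w * scale_vec(geo) + (1 - w) * scale_vec(noise)
    out <- matrix(0, k, k, dimnames = dimnames(geo))
    out[lower.tri(out)] <- m
    dist_matrix(out + t(out), check = FALSE)
  }
  # calibrate weights so the realized lower-triangle R^2 brackets 0.70
  w_hi <- uniroot(function(w) cor(mix(w)[lower.tri(geo)],
                                  geo[lower.tri(geo)])^2 - 0.75,
                  c(0.3, 0.99))$root
  w_lo <- uniroot(function(w) cor(mix(w)[lower.tri(geo)],
                                  geo[lower.tri(geo)])^2 - 0.69,
                  c(0.05, 0.99))$root
  preds <- list(nearmiss = mix(w_lo), dup = geo, over = mix(w_hi),
                clean = rand_dist(k))
  kept <- collinearity_screen(preds, geo)
  expect_true("nearmiss" %in% kept)     # R^2 = 0.69 < 0.70 retained
  expect_false("dup" %in% kept)
  expect_false("over" %in% kept)
  expect_true("clean" %in% kept)

  orth <- list(a = rand_dist(k), b = rand_dist(k))
  expect_equal(collinearity_screen(orth, geo), c("a", "b"))
})

test_that("stepwise residual regression recovers a planted landscape driver", {
  set.seed(103)
  k <- 9
  hits <- vapply(1:5, function(s) {
    set.seed(200 + s)
    geo <- rand_dist(k)
    land <- rand_dist(k)
    y <- dist_matrix(unclass(geo) + 0.9 * unclass(land) +
                       0.15 * unclass(rand_dist(k)),
                     labels = rownames(geo), check = FALSE)
    sw <- stepwise_residual(y, geo, list(land = land, noise = rand_dist(k)),
                            n_perm = 499, seed = s)
    !is.na(sw$best) && grepl("land", sw$best)
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  # zero landscape effect: mostly no significant model
  empty <- vapply(1:5, function(s) {
    set.seed(300 + s)
    geo <- rand_dist(k)
    y <- dist_matrix(unclass(geo) + 0.3 * unclass(rand_dist(k)),
                     labels = rownames(geo), check = FALSE)
    sw <- stepwise_residual(y, geo, list(land = rand_dist(k)),
                            n_perm = 199, seed = s)
    is.na(sw$best)
  }, logical(1))
  expect_gte(mean(empty), 0.6)
})

test_that("a geo-collinear landscape predictor is screened, not credited", {
  set.seed(107)
  k <- 9
  geo <- rand_dist(k)
  clone <- dist_matrix(unclass(geo) * 1.0001 + 1e-6, labels = rownames(geo),
                       check = FALSE)
  diag(clone) <- 0
  y <- dist_matrix(unclass(geo) + 0.2 * unclass(rand_dist(k)),
                   labels = rownames(geo), check = FALSE)
  sw <- stepwise_residual(y, geo, list(clone = clone), n_perm = 199, seed = 1)
  expect_false("clone" %in% sw$retained)
  expect_true(is.na(sw$best))
})

test_that("isolation-by-environment detects a rainfall-built signal", {
  set.seed(109)
  k <- 8
  rain <- runif(k, 20, 220)
  labs <- sprintf("P%02d", seq_len(k))
  d_rain <- abs(outer(rain, rain, `-`))
  fst <- dist_matrix(0.002 * d_rain + 0.02 * unclass(rand_dist(k, labs)),
                     labels = labs, check = FALSE)
  fits <- ibe_test(fst, list(rainfall = setNames(rain, labs),
                             temperature = setNames(runif(k, 20, 30), labs)),
                   n_perm = 999, seed = 3)
  expect_lt(fits$rainfall$p_overall, 0.05)
  # shuffled control: break the link and the signal disappears (usually)
  perm <- sample(k)
  fst_sh <- dist_matrix(unclass(fst)[perm, perm], labels = labs, check = FALSE)
  fits_sh <- ibe_test(fst_sh, list(rainfall = setNames(rain, labs)),
                      n_perm = 999, seed = 4)
  expect_gt(fits_sh$rainfall$p_overall, 0.01)
  expect_error(ibe_test(fst, list(rain = setNames(rep(1, k), labs)),
                        n_perm = 99, seed = 1), "constant predictor")
})

test_that("single-predictor MRDM agrees with vegan's Mantel statistic", {
  skip_if_not_installed("vegan")
  set.seed(113)
  k <- 9
  x <- rand_dist(k)
  y <- dist_matrix(0.5 * unclass(x) + 0.5 * unclass(rand_dist(k)),
                   labels = rownames(x), check = FALSE)
  fit <- mrdm_fit(y, list(x = x), n_perm = 999, seed = 1)
  mt <- vegan::mantel(as.dist(x), as.dist(y), permutations = 999)
  expect_equal(fit$r_squared, mt$statistic^2, tolerance = 1e-10)
  expect_lt(abs(fit$p_overall - mt$signif), 0.05)
})
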