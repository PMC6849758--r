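grid_of <- function(m) ascii_grid(as.matrix(m))

cost_surface_of <- function(cost) {
  structure(list(cost = as.matrix(cost),
                 sea = matrix(FALSE, nrow(as.matrix(cost)), ncol(as.matrix(cost))),
                 xllcorner = 0, yllcorner = 0, cellsize = 1),
            class = "cost_surface")
}

test_that("cost surfaces follow the suitability rule and sea override", {
  suit <- grid_of(matrix(c(1, 0.5, 0, 1), 2, 2))
  sea <- grid_of(matrix(c(0, 0, 0, 1), 2, 2))
  cs <- build_cost_surface(suit, sea_mask = sea, sea_cost = 200)
  expect_equal(cs$cost[1, 1], 1)            # s = 1 -> cost 1
  expect_equal(cs$cost[2, 1], 1 + 99 * 0.5) # s = 0.5 -> 50.5
  expect_equal(cs$cost[1, 2], 100)          # s = 0 -> cost 100
  expect_equal(cs$cost[2, 2], 200)          # sea override

  cs120 <- build_cost_surface(suit, sea_mask = sea, sea_cost = 120)
  changed <- cs$cost != cs120$cost
  expect_true(all(changed == (sea$m == 1)))

  lc <- grid_of(matrix(c(1, 2, 3, 9), 2, 2))
  expect_error(build_cost_surface(lc, cost_rule = c("1" = 1, "2" = 10, "3" = 50)),
               "unmapped raster categories: 9")
  cs_cat <- build_cost_surface(grid_of(matrix(c(1, 2, 3, 1), 2, 2)),
                               cost_rule = c("1" = 1, "2" = 10, "3" = 50))
  expect_equal(cs_cat$cost[2, 1], 10)
})

test_that("effective resistance matches series and parallel closed forms", {
  # 1x3 chain of unit-cost cells: two unit resistors in series -> R = 2
  s <- cost_surface_of(matrix(1, 1, 3))
  focal <- data.frame(pop = c("a", "b"), row = c(1, 1), col = c(1, 3))
  R <- resistance_distance(s, focal, neighbors = 4)
  expect_equal(R["a", "b"], 2, tolerance = 1e-9)

  # 2x2, 4-neighbour, diagonal nodes: two 2-resistor paths in parallel -> R = 1
  s2 <- cost_surface_of(matrix(1, 2, 2))
  focal2 <- data.frame(pop = c("a", "b"), row = c(1, 2), col = c(1, 2))
  R2 <- resistance_distance(s2, focal2, neighbors = 4)
  expect_equal(R2["a", "b"], 1, tolerance = 1e-9)

  # doubling every cost doubles every pairwise resistance
  set.seed(61)
  cost <- matrix(runif(63, 1, 50), 7, 9)
  sA <- cost_surface_of(cost); sB <- cost_surface_of(2 * cost)
  f <- data.frame(pop = c("a", "b", "c"), row = c(1, 7, 4), col = c(1, 9, 5))
  expect_equal(unclass(resistance_distance(sB, f)),
               2 * unclass(resistance_distance(sA, f)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("effective resistance agrees with a dense pseudo-inverse oracle", {
  set.seed(67)
  for (rep in 1:3) {
    nr <- sample(8:14, 1); nc <- sample(8:14, 1)   # up to ~200-400 nodes
    cost <- matrix(runif(nr * nc, 1, 100), nr, nc)
    s <- cost_surface_of(cost)
    f <- data.frame(pop = c("a", "b", "c", "d"),
                    row = sample(nr, 4), col = sample(nc, 4))
    R <- resistance_distance(s, f)

    g <- climvuln:::lattice_graph(s, 8L, "mean")
    n <- length(g$cells)
    L <- matrix(0, n, n)
    for (e in seq_along(g$cond)) {
      i <- g$edges_i[e]; j <- g$edges_j[e]; w <- g$cond[e]
      L[i, j] <- L[i, j] - w; L[j, i] <- L[j, i] - w
      L[i, i] <- L[i, i] + w; L[j, j] <- L[j, j] + w
    }
    Lp <- MASS::ginv(L)
    ids <- g$node_id[(f$col - 1) * nr + f$row]
    for (a in 1:3) for (b in (a + 1):4) {
      e <- numeric(n); e[ids[a]] <- 1; e[ids[b]] <- -1
      expect_equal(R[a, b], drop(t(e) %*% Lp %*% e), tolerance = 1e-9)
    }
    # metric properties on the oracle-checked matrix
    expect_equal(unclass(R), t(unclass(R)), ignore_attr = TRUE)
    for (a in 1:4) for (b in 1:4) for (cc in 1:4)
      expect_lte(R[a, b], R[a, cc] + R[cc, b] + 1e-9)
  }
})

test_that("resistance weakly decreases when a cell gets cheaper", {
  set.seed(71)
  cost <- matrix(runif(36, 5, 50), 6, 6)
  f <- data.frame(pop = c("a", "b"), row = c(1, 6), col = c(1, 6))
  R0 <- resistance_distance(cost_surface_of(cost), f)["a", "b"]
  cost2 <- cost; cost2[3, 3] <- 1
  R1 <- resistance_distance(cost_surface_of(cost2), f)["a", "b"]
  expect_lte(R1, R0 + 1e-12)
})

test_that("disconnected focal pairs yield infinite resistance", {
  cost <- matrix(1, 4, 5)
  cost[, 3] <- NA                       # impassable band
  f <- data.frame(pop = c("a", "b"), row = c(2, 2), col = c(1, 5))
  R <- resistance_distance(cost_surface_of(cost), f)
  expect_true(is.infinite(R["a", "b"]))
})

test_that("cumulative current conserves and splits across equal paths", {
  # 1x3 chain: all current passes through the middle cell
  s <- cost_surface_of(matrix(1, 1, 3))
  f <- data.frame(pop = c("a", "b"), row = c(1, 1), col = c(1, 3))
  cm <- cumulative_current(s, f, neighbors = 4)
  expect_equal(cm$map$m[1, 2], 1, tolerance = 1e-9)
  expect_lt(cm$max_net_residual, 1e-9)

  # two parallel equal 2-step paths: each intermediate cell carries 0.5
  s2 <- cost_surface_of(matrix(1, 2, 2))
  f2 <- data.frame(pop = c("a", "b"), row = c(1, 2), col = c(1, 2))
  cm2 <- cumulative_current(s2, f2, neighbors = 4)
  expect_equal(cm2$map$m[2, 1], 0.5, tolerance = 1e-9)
  expect_equal(cm2$map$m[1, 2], 0.5, tolerance = 1e-9)
  expect_lt(cm2$max_net_residual, 1e-9)
})

test_that("euclidean distances are exact and permutation-equivariant", {
  pops <- data.frame(pop = c("a", "b", "c"), x = c(0, 3, 1), y = c(0, 4, 1))
  m <- euclidean_matrix(pops)
  expect_equal(m["a", "b"], 5)
  perm <- c(3, 1, 2)
  m2 <- euclidean_matrix(pops[perm, ])
  expect_equal(m2[pops$pop, pops$pop], m[pops$pop, pops$pop])
  expect_error(euclidean_matrix(data.frame(pop = "a")), "coordinates")
})

test_that("range-shift flags react to future isolation", {
  base <- matrix(1, 11, 11)
  pops <- data.frame(pop = c("P1", "P2", "P3"),
                     row = c(2, 6, 10), col = c(6, 6, 6),
                     suitable_future = c(TRUE, TRUE, TRUE))
  f <- pops[, c("pop", "row", "col")]
  s_now <- cost_surface_of(base)
  cm_now <- cumulative_current(s_now, f)

  # identical future -> every population keeps "+"
  flags0 <- connectivity_change(cm_now, cm_now, pops)
  expect_true(all(flags0$flag == "+"))

  # future: P2 ringed by near-barrier cost -> its local current collapses
  fut <- base
  ring <- rbind(cbind(4, 3:9), cbind(8, 3:9), cbind(4:8, 3), cbind(4:8, 9))
  fut[ring] <- 100
  cm_fut <- cumulative_current(cost_surface_of(fut), f)
  flags1 <- connectivity_change(cm_now, cm_fut, pops, buffer_radius = 1)
  expect_equal(flags1$flag[flags1$pop == "P2"], "-")
  expect_equal(flags1$flag[flags1$pop == "P1"], "+")

  # corridor rule: connected only to future-unsuitable populations -> "-"
  pops2 <- pops
  pops2$suitable_future <- c(FALSE, TRUE, FALSE)
  flags2 <- connectivity_change(cm_now, cm_now, pops2)
  expect_true(all(flags2$flag[pops2$pop %in% c("P1", "P3")] == "+"))
  expect_equal(flags2$flag[flags2$pop == "P2"], "-")
})
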