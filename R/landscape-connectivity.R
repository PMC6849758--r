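#' Build a resistance cost surface from a raster
#'
#' Maps raster values into movement resistance costs in \[1, 100\], then
#' overrides sea cells with `sea_cost`. Three rule forms are supported:
#' `NULL` (default suitability rule, cost = 1 + 99 (1 - s) for s in \[0,1\]),
#' a `list(breaks=, costs=)` piecewise-linear interpolation for continuous
#' rasters, or a named numeric vector as a category dictionary.
#'
#' @param raster an [ascii_grid()].
#' @param cost_rule `NULL`, `list(breaks, costs)`, or a named numeric
#'   vector mapping category values to costs.
#' @param sea_mask optional [ascii_grid()] of 0/1 sea indicators.
#' @param sea_cost resistance assigned to sea cells (study convention:
#'   200, with 120 as the relaxed alternative).
#' @return Object of class `cost_surface`: `cost` matrix (NA = no-data),
#'   `sea` logical matrix, plus the raster georeferencing.
#' @export
build_cost_surface <- function(raster, cost_rule = NULL, sea_mask = NULL,
                               sea_cost = 200) {
  stopifnot(inherits(raster, "ascii_grid"))
  v <- raster$m
  if (is.null(cost_rule)) {
    s <- pmin(pmax(v, 0), 1)
    cost <- 1 + 99 * (1 - s)
  } else if (is.list(cost_rule)) {
    cost <- matrix(approx(cost_rule$breaks, cost_rule$costs, v, rule = 2)$y,
                   nrow(v), ncol(v))
  } else {
    key <- as.character(v)
    unmapped <- setdiff(unique(key[!is.na(v)]), names(cost_rule))
    if (length(unmapped))
      stopf("unmapped raster categories: %s", paste(unmapped, collapse = ", "))
    cost <- matrix(cost_rule[key], nrow(v), ncol(v))
  }
  cost[is.na(v)] <- NA
  land_vals <- cost[!is.na(cost)]
  if (length(land_vals) && (any(land_vals < 1 - 1e-9) || any(land_vals > 100 + 1e-9)))
    stopf("cost rule produced land costs outside [1, 100]")
  sea <- if (is.null(sea_mask)) matrix(FALSE, nrow(v), ncol(v)) else
    sea_mask$m == 1
  cost[sea & !is.na(cost)] <- sea_cost
  structure(list(cost = cost, sea = sea, xllcorner = raster$xllcorner,
                 yllcorner = raster$yllcorner, cellsize = raster$cellsize),
            class = "cost_surface")
}

# lattice graph over non-NA cells: nodes (cell linear indices), undirected
# edge list with conductances. Conductance between adjacent cells is
# 1/mean(cost_i, cost_j) ("average resistance" convention; "harmonic"
# alternative uses mean conductance), diagonal edges scaled by 1/sqrt(2).
lattice_graph <- function(surface, neighbors = 8L,
                          conductance = c("mean", "harmonic")) {
  conductance <- match.arg(conductance)
  cost <- surface$cost
  nr <- nrow(cost); nc <- ncol(cost)
  node_id <- matrix(NA_integer_, nr, nc)
  cells <- which(!is.na(cost))
  node_id[cells] <- seq_along(cells)

  offs <- list(c(0L, 1L), c(1L, 0L))
  if (neighbors == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  ei <- ej <- integer(0); ew <- numeric(0)
  ri <- (cells - 1L) %% nr + 1L
  ci <- (cells - 1L) %/% nr + 1L
  for (o in offs) {
    r2 <- ri + o[1]; c2 <- ci + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    tgt <- (c2[ok] - 1L) * nr + r2[ok]
    src <- cells[ok]
    keep <- !is.na(node_id[tgt])
    src <- src[keep]; tgt <- tgt[keep]
    cond <- if (conductance == "mean") 1 / ((cost[src] + cost[tgt]) / 2) else
      (1 / cost[src] + 1 / cost[tgt]) / 2
    if (any(o != 0L) && sum(abs(o)) == 2L) cond <- cond / sqrt(2)
    ei <- c(ei, node_id[src]); ej <- c(ej, node_id[tgt]); ew <- c(ew, cond)
  }
  list(cells = cells, node_id = node_id, edges_i = ei, edges_j = ej,
       cond = ew, nr = nr, nc = nc)
}

# connected component label per node (BFS on the edge list)
graph_components <- function(g) {
  n <- length(g$cells)
  adj <- split(c(g$edges_j, g$edges_i), c(g$edges_i, g$edges_j))
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nb <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

# sparse graph Laplacian
graph_laplacian <- function(g) {
  n <- length(g$cells)
  A <- sparseMatrix(i = c(g$edges_i, g$edges_j), j = c(g$edges_j, g$edges_i),
                    x = c(g$cond, g$cond), dims = c(n, n))
  Diagonal(x = Matrix::rowSums(A)) - A
}

# map focal points (data.frame with row/col, or a population_table) to node ids
focal_nodes_of <- function(surface, focal, g) {
  if (!all(c("row", "col") %in% names(focal)))
    stopf("focal nodes need 'row' and 'col' columns")
  cell <- (focal$col - 1L) * g$nr + focal$row
  id <- g$node_id[cell]
  if (anyNA(id)) stopf("focal node on a no-data cell: %s",
                       paste(which(is.na(id)), collapse = ", "))
  if (any(surface$sea[cell])) stopf("focal node on a sea cell")
  id
}

# grounded solves: potentials for unit injection at each focal node
# (ground = first node of the component holding the most focal nodes)
circuit_solves <- function(L, focal_ids, comp) {
  main <- as.integer(names(which.max(table(comp[focal_ids]))))
  in_main <- which(comp == main)
  ground <- in_main[1]
  keep <- setdiff(in_main, ground)
  Lg <- L[keep, keep, drop = FALSE]
  pos <- match(seq_len(nrow(L)), keep)       # node -> grounded index
  n_f <- length(focal_ids)
  V <- matrix(0, nrow(L), n_f)               # full potential vectors, ground 0
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Lg), LDL = FALSE, perm = TRUE)
  for (k in seq_len(n_f)) {
    f <- focal_ids[k]
    if (comp[f] != main) { V[, k] <- NA; next }
    rhs <- numeric(length(keep))
    if (!is.na(pos[f])) rhs[pos[f]] <- 1     # injection at ground -> all zero
    x <- as.numeric(Matrix::solve(ch, rhs))
    V[keep, k] <- x
  }
  list(V = V, main = main)
}

#' Effective resistance distances between focal populations
#'
#' Treats the cost surface as a resistor lattice (conductance between
#' adjacent cells from their mean cost, diagonals scaled by 1/sqrt(2)) and
#' computes pairwise effective resistances via sparse grounded-Laplacian
#' solves. Pairs in disconnected components get `Inf`.
#'
#' @param surface a [build_cost_surface()] result.
#' @param focal data.frame with `row`, `col` (and optionally `pop` labels).
#' @param neighbors 8 (default) or 4-neighbour lattice.
#' @param conductance "mean" (average resistance, default) or "harmonic".
#' @return A [dist_matrix()] of effective resistances.
#' @export
resistance_distance <- function(surface, focal, neighbors = 8L,
                                conductance = "mean") {
  g <- lattice_graph(surface, neighbors, conductance)
  ids <- focal_nodes_of(surface, focal, g)
  comp <- graph_components(g)
  L <- graph_laplacian(g)
  sol <- circuit_solves(L, ids, comp)
  k <- length(ids)
  labs <- focal$pop %||% sprintf("F%02d", seq_len(k))
  m <- matrix(0, k, k, dimnames = list(labs, labs))
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    if (comp[ids[a]] != comp[ids[b]] || comp[ids[a]] != sol$main) {
      m[a, b] <- m[b, a] <- Inf
    } else {
      va <- sol$V[, a]; vb <- sol$V[, b]
      m[a, b] <- m[b, a] <- (va[ids[a]] - va[ids[b]]) - (vb[ids[a]] - vb[ids[b]])
    }
  }
  dist_matrix(m, check = FALSE)
}

#' Cumulative current map over all focal pairs
#'
#' For every focal pair a unit current is injected at one node and
#' extracted at the other; each cell's current is half the sum of absolute
#' branch currents incident to it, and the map sums these over all pairs
#' (the circuit-theory movement-density surface).
#'
#' @inheritParams resistance_distance
#' @return List of class `current_map`: `map` (an [ascii_grid()]; no-data
#'   cells are 0), `max_net_residual` (largest absolute net current at any
#'   non-focal node, a conservation diagnostic), and `n_pairs`.
#' @export
cumulative_current <- function(surface, focal, neighbors = 8L,
                               conductance = "mean") {
  g <- lattice_graph(surface, neighbors, conductance)
  ids <- focal_nodes_of(surface, focal, g)
  comp <- graph_components(g)
  L <- graph_laplacian(g)
  sol <- circuit_solves(L, ids, comp)
  n <- length(g$cells)
  acc <- numeric(n)
  k <- length(ids)
  max_resid <- 0
  n_pairs <- 0L
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    if (comp[ids[a]] != sol$main || comp[ids[b]] != sol$main) next
    v <- sol$V[, a] - sol$V[, b]
    dvi <- abs(v[g$edges_i] - v[g$edges_j]) * g$cond
    node_cur <- numeric(n)
    tab <- rowsum(c(dvi, dvi), c(g$edges_i, g$edges_j))
    node_cur[as.integer(rownames(tab))] <- tab[, 1]
    acc <- acc + node_cur / 2
    # conservation check on signed currents
    sgn <- (v[g$edges_i] - v[g$edges_j]) * g$cond
    net <- numeric(n)
    tab2 <- rowsum(c(-sgn, sgn), c(g$edges_i, g$edges_j))
    net[as.integer(rownames(tab2))] <- tab2[, 1]
    max_resid <- max(max_resid, max(abs(net[-c(ids[a], ids[b])])))
    n_pairs <- n_pairs + 1L
  }
  m <- matrix(0, g$nr, g$nc)
  m[g$cells] <- acc
  structure(list(map = ascii_grid(m, surface$xllcorner, surface$yllcorner,
                                  surface$cellsize),
                 max_net_residual = max_resid, n_pairs = n_pairs),
            class = "current_map")
}

#' Euclidean distance matrix between populations
#'
#' @param pops a `population_table` (or any data.frame with `pop` and
#'   coordinates `x`, `y` -- planar -- or `lon`, `lat` -- great-circle).
#' @param method "planar" (default) or "greatcircle" (haversine, km).
#' @return A [dist_matrix()].
#' @export
euclidean_matrix <- function(pops, method = c("planar", "greatcircle")) {
  method <- match.arg(method)
  if (method == "planar") {
    if (!all(c("x", "y") %in% names(pops))) stopf("missing x/y coordinates")
    m <- as.matrix(dist(cbind(pops$x, pops$y)))
  } else {
    if (!all(c("lon", "lat") %in% names(pops))) stopf("missing lon/lat coordinates")
    rad <- pi / 180
    lat <- pops$lat * rad; lon <- pops$lon * rad
    n <- length(lat)
    m <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      h <- sin((lat[j] - lat[i]) / 2)^2 +
        cos(lat[i]) * cos(lat[j]) * sin((lon[j] - lon[i]) / 2)^2
      m[i, j] <- 2 * 6371 * asin(pmin(1, sqrt(h)))
    }
    if (any(abs(m[upper.tri(m)] - pi * 6371) < 1e-6))
      warning("antipodal population pair: great-circle bearing undefined")
  }
  dist_matrix(m, labels = pops$pop)
}

#' Range-shift potential from present vs future current maps
#'
#' Scores each population by the mean cumulative current within
#' `buffer_radius` cells of its location, on the present and future maps.
#' A population is flagged "-" (low range-shift potential) when its
#' future/present score ratio falls below `tau`, or when every population
#' it stays connected to through above-threshold future corridors is
#' climatically unsuitable in the future; otherwise "+".
#'
#' @param current_now,current_future `current_map`s on aligned grids.
#' @param pops a `population_table` (needs `row`, `col`, `pop`; the
#'   corridor rule also uses `suit_future` and `suitable_future` if present).
#' @param buffer_radius buffer radius in cells (clipped at grid edges).
#' @param tau minimum acceptable future/present connectivity ratio.
#' @param corridor_quantile quantile of positive future currents defining
#'   an "above-threshold" corridor cell.
#' @return data.frame: `pop`, `score_now`, `score_future`, `ratio`,
#'   `reachable_suitable`, `flag` in {"+", "-"}.
#' @export
connectivity_change <- function(current_now, current_future, pops,
                                buffer_radius = 2L, tau = 0.5,
                                corridor_quantile = 0.5) {
  m_now <- current_now$map$m; m_fut <- current_future$map$m
  if (!all(dim(m_now) == dim(m_fut))) stopf("current maps on different grids")
  nr <- nrow(m_now); nc <- ncol(m_now)
  buf_mean <- function(m, r, c) {
    rs <- max(1L, r - buffer_radius):min(nr, r + buffer_radius)
    cs <- max(1L, c - buffer_radius):min(nc, c + buffer_radius)
    mean(m[rs, cs])
  }
  score_now <- mapply(function(r, c) buf_mean(m_now, r, c), pops$row, pops$col)
  score_fut <- mapply(function(r, c) buf_mean(m_fut, r, c), pops$row, pops$col)
  ratio <- ifelse(score_now > 0, score_fut / score_now,
                  ifelse(score_fut > 0, Inf, 1))

  # corridor rule: label future-corridor cells, find which populations stay
  # connected, and whether any of them remains suitable
  pos <- m_fut[m_fut > 0]
  thr <- if (length(pos)) quantile(pos, corridor_quantile, names = FALSE) else Inf
  corridor <- m_fut >= thr
  cell <- (pops$col - 1L) * nr + pops$row
  corridor[cell] <- TRUE                     # a population sits on its own cell
  lab <- label_components(corridor)
  suit_fut <- if ("suitable_future" %in% names(pops)) pops$suitable_future
              else pops$suit_future >= 0.5
  reach_ok <- vapply(seq_len(nrow(pops)), function(k) {
    same <- lab[cell] == lab[cell[k]] & seq_len(nrow(pops)) != k
    any(same & suit_fut)
  }, logical(1))
  flag <- ifelse(ratio < tau | !reach_ok, "-", "+")
  data.frame(pop = pops$pop, score_now = score_now, score_future = score_fut,
             ratio = ratio, reachable_suitable = reach_ok, flag = flag,
             stringsAsFactors = FALSE)
}

# 8-neighbour connected-component labels of a logical matrix
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    frontier <- start
    lab[start] <- cur
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      c <- (frontier - 1L) %/% nr + 1L
      nxt <- integer(0)
      for (dr in -1L:1L) for (dc in -1L:1L) {
        if (dr == 0L && dc == 0L) next
        r2 <- r + dr; c2 <- c + dc
        ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
        idx <- (c2[ok] - 1L) * nr + r2[ok]
        idx <- idx[mask[idx] & lab[idx] == 0L]
        lab[idx] <- cur
        nxt <- c(nxt, idx)
      }
      frontier <- unique(nxt)
    }
  }
  lab
}
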