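test_that("stationary points of convex and preset surfaces are exact", {
  # convex 2D bowl: one minimum, no saddle
  g <- landscape_to_grid(make_surface("harmonic", list(dim = 2, kappa = 2)), 0.1)
  sp <- find_stationary_points(g)
  expect_identical(nrow(sp$minima), 1L)
  expect_identical(nrow(sp$saddles), 0L)
  expect_lt(max(abs(c(sp$minima$x1, sp$minima$x2))), 0.1)  # within one bin of 0

  g2 <- landscape_to_grid(make_surface("double_well_2d"), 0.02)
  sp2 <- find_stationary_points(g2)
  expect_identical(nrow(sp2$minima), 2L)
  expect_identical(nrow(sp2$saddles), 1L)
  expect_equal(sp2$minima$x1, c(1.2, 2.2), tolerance = 0.021)
  expect_equal(sp2$saddles$x1, 1.7, tolerance = 0.021)
  expect_equal(sp2$saddles$energy, 5, tolerance = 0.05)

  g3 <- landscape_to_grid(make_surface("four_state_2d"), 0.02)
  sp3 <- find_stationary_points(g3)
  l3 <- make_surface("four_state_2d")
  expect_identical(nrow(sp3$minima), 3L)
  expect_identical(nrow(sp3$saddles), 2L)
  expect_equal(sort(sp3$minima$x1), l3$stationary$minima$x1, tolerance = 0.021)
  expect_equal(sort(sp3$saddles$x1), l3$stationary$saddles$x1, tolerance = 0.021)
})

test_that("a fully masked grid is rejected", {
  g <- grid_from_matrix(matrix(1, 3, 3), mask = matrix(TRUE, 3, 3))
  expect_error(find_stationary_points(g), "masked")
})

test_that("the prominence filter merges shallow ripple basins", {
  # deep wells at the ends, a 0.05-deep ripple in between
  v <- c(0, 3, 2.95, 3, 0.5)
  g <- grid_from_matrix(v)
  expect_identical(nrow(find_stationary_points(g)$minima), 3L)
  sp <- find_stationary_points(g, min_prominence = 0.2)
  expect_identical(nrow(sp$minima), 2L)
  expect_equal(sp$minima$energy, c(0, 0.5))
})

test_that("the 1D double-well path is the monotone sweep over the barrier", {
  l <- make_surface("double_well_1d")
  g <- landscape_to_grid(l, 0.02)
  sp <- find_stationary_points(g)
  p <- trace_mep(g, sp$minima$node[1], sp$minima$node[2])
  expect_identical(p$nodes, seq(min(sp$minima$node), max(sp$minima$node)))
  expect_equal(unname(p$coords[p$peak_index, 1]), 1.7, tolerance = 0.021)
  expect_equal(p$peak_energy, 5, tolerance = 0.05)
  expect_equal(extract_barrier(p), p$peak_energy - p$energy[1])
})

test_that("bottleneck peak equals exhaustive minimax on random grids", {
  set.seed(501)
  # the sweep oracle itself is first certified against genuine
  # all-simple-paths enumeration on tiny grids
  for (rep in 1:6) {
    m <- matrix(stats::runif(12, 0, 10), 3, 4)
    s <- 1L; t <- 12L
    expect_identical(minimax_oracle_sweep(m, s, t),
                     minimax_oracle_dfs(m, s, t))
  }
  for (rep in 1:25) {
    nr <- sample(4:12, 1); nc <- sample(4:12, 1)
    m <- matrix(stats::runif(nr * nc, 0, 10), nr, nc)
    s <- sample.int(nr * nc, 1)
    t <- sample.int(nr * nc, 1)
    if (s == t) t <- if (s == 1L) 2L else s - 1L
    g <- grid_from_matrix(m)
    p <- trace_mep(g, s, t)
    expect_identical(p$peak_energy, minimax_oracle_sweep(m, s, t))
    # consecutive path nodes are grid neighbours
    for (i in seq_len(length(p$nodes) - 1))
      expect_true(p$nodes[i + 1] %in% .or_neigh(p$nodes[i], nr, nc))
  }
})

test_that("path tracing respects masks, symmetry and monotonicity", {
  set.seed(77)
  m <- matrix(stats::runif(100, 0, 5), 10, 10)
  g <- grid_from_matrix(m)
  # symmetry: identical peak both ways
  p1 <- trace_mep(g, 1L, 100L)
  p2 <- trace_mep(g, 100L, 1L)
  expect_identical(p1$peak_energy, p2$peak_energy)
  # monotonicity: raising one node never lowers the bottleneck
  for (rep in 1:10) {
    v <- sample.int(100, 1)
    m2 <- m; m2[v] <- m2[v] + stats::runif(1, 0, 5)
    expect_gte(trace_mep(grid_from_matrix(m2), 1L, 100L)$peak_energy,
               p1$peak_energy)
  }
  # a masked wall separates the basins
  mask <- matrix(FALSE, 10, 10); mask[5, ] <- TRUE
  gw <- grid_from_matrix(m, mask = mask)
  expect_error(trace_mep(gw, 1L, 100L), class = "fel_no_path")
  expect_error(trace_mep(gw, 1L, 100L), "disconnected")
  # 4-connectivity cannot cut diagonal corners
  diagm <- matrix(c(0, 10, 10, 0), 2, 2)
  p4 <- trace_mep(grid_from_matrix(diagm), 1L, 4L, connectivity = 4)
  expect_identical(p4$peak_energy, 10)
  p8 <- trace_mep(grid_from_matrix(diagm), 1L, 4L, connectivity = 8)
  expect_identical(p8$peak_energy, 0)
})

test_that("barriers are extracted from peak minus reference", {
  g <- grid_from_matrix(c(0, 3, 5, 2))
  p <- trace_mep(g, 1L, 4L)
  expect_equal(extract_barrier(p, reference = 0), 5)
  expect_equal(extract_barrier(p), 5)          # default: start-node energy
  expect_equal(extract_barrier(p, reference = 2), 3)
  single <- trace_mep(g, 2L, 2L)
  expect_equal(extract_barrier(single), 0)
  # preset double well, reference = the deeper minimum
  l <- make_surface("double_well_1d")
  gd <- landscape_to_grid(l, 0.02)
  sp <- find_stationary_points(gd)
  deep <- sp$minima$node[which.min(sp$minima$energy)]
  other <- setdiff(sp$minima$node, deep)[1]
  pd <- trace_mep(gd, deep, other)
  expect_equal(extract_barrier(pd), 5, tolerance = 0.05)  # within a bin
})

test_that("saddles connect the basins their bottleneck paths cross", {
  g <- landscape_to_grid(make_surface("four_state_2d"), 0.02)
  sp <- find_stationary_points(g)
  expect_true(all(sp$saddles$energy >=
                    pmax(sp$minima$energy[sp$saddles$basin_from],
                         sp$minima$energy[sp$saddles$basin_to])))
  expect_false(anyDuplicated(sp$minima$basin) > 0)
})
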