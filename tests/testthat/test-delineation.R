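test_that("tree-top detection handles peaks, plateaus and constants", {
  v <- matrix(1, 5, 5); v[3, 3] <- 20
  chm <- raster_grid(v, resolution = 1)
  tops <- find_local_maxima(chm, delineation_params(window_diameter = 3,
                                                    min_tree_height = 2))
  expect_equal(nrow(tops), 1L)
  expect_equal(c(tops$row, tops$col), c(3L, 3L))
  expect_equal(tops$apex_height, 20)

  # a perfectly constant grid has no strict maximum
  const <- raster_grid(matrix(10, 6, 6), resolution = 1)
  expect_equal(nrow(find_local_maxima(const, delineation_params())), 0L)

  # a two-pixel plateau peak yields exactly one seed (lexicographic keeper)
  v2 <- matrix(1, 5, 5); v2[3, 3] <- v2[3, 4] <- 20
  tops2 <- find_local_maxima(raster_grid(v2, resolution = 1),
                             delineation_params(window_diameter = 3))
  expect_equal(nrow(tops2), 1L)
  expect_equal(c(tops2$row, tops2$col), c(3L, 3L))

  # a too-small window is a configuration error
  expect_error(find_local_maxima(chm, delineation_params(window_diameter = 0.5)),
               "window")
})

test_that("tree-top detection matches the all-pairs brute-force oracle", {
  params <- delineation_params(window_diameter = 3, min_tree_height = 2)
  for (seed in 1:50) {
    v <- round(random_bumpy_grid(12, 14, n_bumps = 3, seed = seed), 2)
    got <- find_local_maxima(raster_grid(v, resolution = 1), params)
    want <- oracle_local_maxima(v, 1, 3, 2)
    expect_equal(nrow(got), NROW(want), info = paste("seed", seed))
    if (NROW(want))
      expect_equal(unname(as.matrix(got[c("row", "col")])),
                   unname(want[order(want[, 1], want[, 2]), , drop = FALSE]),
                   info = paste("seed", seed))
  }
  # also at a wider window
  params5 <- delineation_params(window_diameter = 5)
  for (seed in 51:75) {
    v <- round(random_bumpy_grid(10, 10, n_bumps = 2, seed = seed), 2)
    got <- find_local_maxima(raster_grid(v, resolution = 1), params5)
    want <- oracle_local_maxima(v, 1, 5, 2)
    expect_equal(nrow(got), NROW(want), info = paste("seed", seed))
  }
})

test_that("region growth applies the relative and absolute drop rules", {
  # seed apex 20, frac 0.3 (-> drop < 6), abs 5: neighbour at 16 joins
  v <- matrix(1, 3, 3); v[2, 2] <- 20; v[2, 3] <- 16
  chm <- raster_grid(v, resolution = 1)
  seeds <- data.frame(row = 2L, col = 2L, x = 2.5, y = 0.5, apex_height = 20)
  p <- delineation_params(frac_threshold = 0.3, abs_threshold = 5)
  lab <- grow_crowns(chm, seeds, p)
  expect_equal(lab$values[2, 3], 1L)

  # neighbour at 14 is excluded: drop 6 >= abs threshold 5
  v[2, 3] <- 14
  lab2 <- grow_crowns(raster_grid(v, resolution = 1), seeds, p)
  expect_equal(lab2$values[2, 3], 0L)

  # a seed below the cut-off is skipped with a warning
  seeds_low <- rbind(seeds, data.frame(row = 1L, col = 1L, x = 0.5, y = 2.5,
                                       apex_height = 1))
  expect_warning(grow_crowns(raster_grid(v, resolution = 1), seeds_low, p),
                 "cut-off")
})

test_that("region growth matches a round-synchronous BFS oracle", {
  p <- delineation_params(frac_threshold = 0.4, abs_threshold = 5)
  for (seed in 1:60) {
    set.seed(seed)
    nr <- 12L; nc <- 12L
    v <- round(random_bumpy_grid(nr, nc, n_bumps = sample(1:3, 1),
                                 seed = seed + 500), 2)
    tops <- find_local_maxima(raster_grid(v, resolution = 1), p)
    if (nrow(tops) == 0L) next
    tops <- tops[seq_len(min(5L, nrow(tops))), ]
    got <- grow_crowns(raster_grid(v, resolution = 1), tops, p)
    want <- oracle_grow(v, tops, 0.4, 5)
    expect_identical(got$values, want, info = paste("seed", seed))
  }
})

test_that("regions are disjoint, 4-connected, seed-anchored and monotone in thresholds", {
  v <- round(random_bumpy_grid(30, 30, n_bumps = 5, seed = 77), 2)
  chm <- raster_grid(v, resolution = 1)
  p1 <- delineation_params(frac_threshold = 0.3, abs_threshold = 4)
  p2 <- delineation_params(frac_threshold = 0.5, abs_threshold = 7)
  tops <- find_local_maxima(chm, p1)
  l1 <- grow_crowns(chm, tops, p1)$values
  l2 <- grow_crowns(chm, tops, p2)$values
  for (s in seq_len(nrow(tops))) {
    expect_equal(l1[tops$row[s], tops$col[s]], s)
    # monotonicity: looser thresholds never shrink a region
    expect_true(all(which(l1 == s) %in% which(l2 == s)))
    # 4-connectivity: flood fill from the seed recovers the whole region
    reg <- l1 == s
    reach <- matrix(FALSE, nrow(v), ncol(v))
    reach[tops$row[s], tops$col[s]] <- TRUE
    repeat {
      grew <- FALSE
      idx <- which(reach, arr.ind = TRUE)
      for (k in seq_len(nrow(idx)))
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          r2 <- idx[k, 1] + d[1]; c2 <- idx[k, 2] + d[2]
          if (r2 >= 1 && r2 <= nrow(v) && c2 >= 1 && c2 <= ncol(v) &&
              reg[r2, c2] && !reach[r2, c2]) {
            reach[r2, c2] <- TRUE; grew <- TRUE
          }
        }
      if (!grew) break
    }
    expect_true(all(reach == reg))
  }
})

test_that("crown return extraction filters by return number, cut-off and pixel", {
  lab <- raster_grid(matrix(c(1L, 1L, 0L, 0L), 2, 2), origin_y = 2,
                     resolution = 1, nodata = 0)
  pc <- point_cloud(x = c(0.5, 0.5, 0.5, 1.5, 0.2, 0.8, 0.4, 0.6, 0.3, 0.7),
                    y = c(1.5, 0.5, 1.2, 0.5, 1.8, 1.1, 0.3, 1.9, 0.9, 1.4),
                    z = c(10, 9, 1, 12, 8, 7, 11, 6, 9, 5),
                    return_number = c(1, 1, 1, 1, 2, 1, 1, 1, 1, 1),
                    num_returns = 2)
  out <- extract_crown_returns(lab, pc, delineation_params(low_point_cutoff = 2))
  expect_named(out, "1")
  # in-column-1 first returns above 2 m only; the x=1.5 column is unlabelled
  expect_true(all(out[["1"]]$z > 2))
  expect_true(all(out[["1"]]$return_number == 1L))
  expect_true(all(out[["1"]]$x < 1))
  # second returns alone cannot form a crown
  pc2 <- point_cloud(rep(0.5, 4), c(0.3, 0.6, 1.2, 1.7), rep(10, 4),
                     return_number = 2L, num_returns = 2L)
  expect_warning(out2 <- extract_crown_returns(lab, pc2, delineation_params()),
                 "fewer than 3")
  expect_length(out2, 0L)
})

test_that("convex hulls give exact areas, the pinned percentile, and match the oracle", {
  sq <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1),
                   z = c(5, 6, 7, 8), return_number = 1L)
  out <- hull_crowns(list("1" = sq))
  expect_equal(out$table$crown_area_m2, 1)

  zz <- data.frame(x = runif(100), y = runif(100), z = 1:100)
  h <- hull_crowns(list("1" = zz))
  expect_equal(h$table$height_m, 99.01)

  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(5:40, 1)
    pts <- data.frame(x = runif(n, 0, 10), y = runif(n, 0, 10), z = runif(n, 2, 20))
    got <- hull_crowns(list("1" = pts))$table$crown_area_m2
    expect_equal(got, oracle_hull_area(pts$x, pts$y), tolerance = 1e-9,
                 info = paste("seed", seed))
  }

  # collinear points cannot be hulled
  col3 <- data.frame(x = c(1, 2, 3), y = c(1, 2, 3), z = c(5, 6, 7))
  expect_warning(h0 <- hull_crowns(list("1" = col3)), "collinear")
  expect_equal(length(h0), 0L)
})

test_that("full delineation resolves separable trees and rejects bare ground", {
  set.seed(11)
  mk_tree <- function(cx, cy, apex, r, n = 500) {
    ang <- runif(n, 0, 2 * pi); rad <- sqrt(runif(n)) * r
    x <- cx + rad * cos(ang); y <- cy + rad * sin(ang)
    z <- apex * (1 - 0.6 * (rad / r)^2) + rnorm(n, 0, 0.1)
    data.frame(x = x, y = y, z = z)
  }
  t1 <- mk_tree(5, 5, 15, 2.5)
  t2 <- mk_tree(15, 5, 12, 2.5)
  ground <- data.frame(x = runif(2000, 0, 20), y = runif(2000, 0, 10),
                       z = abs(rnorm(2000, 0, 0.05)))
  all_pts <- rbind(t1, t2, ground)
  cloud <- point_cloud(all_pts$x, all_pts$y, all_pts$z)
  itcs <- delineate(cloud)
  expect_equal(length(itcs), 2L)
  # each polygon contains its seed
  for (i in 1:2)
    expect_true(pt_in_ring(itcs$table$x[i], itcs$table$y[i], itcs$polygons[[i]]))

  # ground-only cloud: no crowns
  g <- point_cloud(ground$x, ground$y, ground$z)
  expect_equal(length(delineate(g)), 0L)
})

test_that("delineation is invariant to point-cloud record order", {
  sc <- forest_scenario("separable_stand", extent_m = 50, seed = 13)
  cloud <- simulate_point_cloud(simulate_forest(sc), sc)
  set.seed(1)
  perm <- sample(nrow(cloud))
  cloud2 <- point_cloud(cloud$x[perm], cloud$y[perm], cloud$z[perm],
                        cloud$return_number[perm], cloud$num_returns[perm],
                        cloud$is_ground[perm])
  a <- delineate(cloud); b <- delineate(cloud2)
  expect_equal(length(a), length(b))
  expect_equal(a$table$crown_area_m2[order(a$table$id)],
               b$table$crown_area_m2[order(b$table$id)])
  expect_equal(a$table$height_m, b$table$height_m)
})
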