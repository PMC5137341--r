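square_itc <- function(id, cx, cy, half, height) {
  ring <- cbind(cx + half * c(-1, 1, 1, -1), cy + half * c(-1, -1, 1, 1))
  list(tab = data.frame(id = id, x = cx, y = cy, height_m = height,
                        crown_area_m2 = (2 * half)^2),
       ring = ring)
}

test_that("the height contest picks the closest-in-height contained tree", {
  s <- square_itc(1L, 0, 0, 5, height = 26)
  itcs <- itc_set(s$tab, list(s$ring))
  trees <- data.frame(id = 1:2, x = c(-1, 1), y = c(0, 0),
                      height_m = c(20, 27), dbh_cm = c(30, 40))
  m <- match_itcs(itcs, trees)
  expect_equal(m$pairs$tree_id, 2L)
  expect_equal(m$unmatched_field_trees, 1L)

  # a lone contained tree is paired regardless of the height gap
  trees1 <- data.frame(id = 7L, x = 0, y = 0, height_m = 2, dbh_cm = 5)
  m1 <- match_itcs(itcs, trees1)
  expect_equal(m1$pairs$tree_id, 7L)
  expect_length(m1$unmatched_itcs, 0L)

  # boundary counts as inside
  trees_b <- data.frame(id = 3L, x = 5, y = 0, height_m = 25, dbh_cm = 30)
  expect_equal(nrow(match_itcs(itcs, trees_b)$pairs), 1L)

  # equal height gaps: the larger DBH wins
  trees_t <- data.frame(id = c(10L, 11L), x = c(-1, 1), y = 0,
                        height_m = c(25, 27), dbh_cm = c(30, 50))
  expect_equal(match_itcs(itcs, trees_t)$pairs$tree_id, 11L)
})

test_that("matching equals the exhaustive-enumeration oracle on random scenes", {
  for (seed in 1:40) {
    set.seed(seed)
    n_itc <- sample(1:6, 1); n_tree <- sample(1:12, 1)
    parts <- lapply(seq_len(n_itc), function(i)
      square_itc(i, runif(1, 0, 30), runif(1, 0, 30), runif(1, 2, 6),
                 runif(1, 5, 35)))
    itcs <- itc_set(do.call(rbind, lapply(parts, `[[`, "tab")),
                    lapply(parts, `[[`, "ring"))
    trees <- data.frame(id = seq_len(n_tree), x = runif(n_tree, 0, 30),
                        y = runif(n_tree, 0, 30),
                        height_m = runif(n_tree, 3, 35),
                        dbh_cm = runif(n_tree, 5, 80))
    got <- match_itcs(itcs, trees)$pairs
    want <- oracle_match(itcs, trees)
    expect_equal(nrow(got), NROW(want), info = paste("seed", seed))
    if (NROW(want))
      expect_equal(unname(as.matrix(got)), unname(want),
                   info = paste("seed", seed))
  }
})

test_that("delineation metrics implement the DET/OE/CE/AI identities", {
  # 10 trees, 6 matched, 8 ITCs of which 2 unmatched
  trees <- data.frame(id = 1:10, dbh_cm = seq(5, 95, 10),
                      x = 1:10, y = 1, height_m = 10)
  parts <- lapply(1:8, function(i) square_itc(i, i, 1, 0.4, 10))
  itcs <- itc_set(do.call(rbind, lapply(parts, `[[`, "tab")),
                  lapply(parts, `[[`, "ring"))
  itcs$table$dbh_cm <- seq(10, 80, 10)
  match <- list(pairs = data.frame(itc_id = 1:6, tree_id = 1:6),
                unmatched_field_trees = 7:10, unmatched_itcs = 7:8)
  class(match) <- "match_result"
  dm <- delineation_metrics(match, trees, itcs)
  expect_equal(dm$det_pct, 60)
  expect_equal(dm$oe_pct, 40)
  expect_equal(dm$ce_pct, 25)
  expect_equal(dm$ai_pct, 35)
  # identities
  expect_equal(dm$det_pct + dm$oe_pct, 100)
  expect_equal(dm$ai_pct, 100 - (dm$oe_pct + dm$ce_pct))
  # per-class counts add up to the totals
  expect_equal(sum(dm$by_class$n_matched), 6L)
  expect_equal(sum(dm$by_class$n_field), 10L)
  expect_equal(sum(dm$by_class$n_unmatched_itc), 2L)
  # class DET values bracket the overall rate
  cls_det <- dm$by_class$det_pct[!is.na(dm$by_class$det_pct)]
  expect_gte(dm$det_pct, min(cls_det))
  expect_lte(dm$det_pct, max(cls_det))

  # perfect delineation
  match_all <- list(pairs = data.frame(itc_id = 1:8, tree_id = 1:8),
                    unmatched_field_trees = integer(0),
                    unmatched_itcs = integer(0))
  dm2 <- delineation_metrics(match_all, trees[1:8, ], itcs)
  expect_equal(c(dm2$det_pct, dm2$oe_pct, dm2$ce_pct, dm2$ai_pct),
               c(100, 0, 0, 100))

  expect_error(delineation_metrics(match, trees[0, ], itcs), "undefined")
})

test_that("biomass detection by class reflects what the crowns captured", {
  trees <- data.frame(id = 1:6, dbh_cm = c(5, 15, 25, 45, 65, 95),
                      agb_kg = c(2, 20, 80, 400, 900, 2500),
                      x = 1:6, y = 1, height_m = 10)
  parts <- lapply(1:6, function(i) square_itc(i, i, 1, 0.4, 10))
  itcs <- itc_set(do.call(rbind, lapply(parts, `[[`, "tab")),
                  lapply(parts, `[[`, "ring"))
  itcs$table$dbh_cm <- trees$dbh_cm
  itcs$table$agb_kg <- trees$agb_kg
  all_m <- list(pairs = data.frame(itc_id = 1:6, tree_id = 1:6),
                unmatched_field_trees = integer(0), unmatched_itcs = integer(0))
  tb <- biomass_detection_by_class(all_m, trees, itcs)
  expect_true(all(tb$detected_pct[tb$field_agb_kg > 0] == 100))

  none <- list(pairs = data.frame(itc_id = integer(), tree_id = integer()),
               unmatched_field_trees = 1:6, unmatched_itcs = 1:6)
  tb0 <- biomass_detection_by_class(none, trees, itcs)
  expect_true(all(tb0$detected_pct[tb0$field_agb_kg > 0] == 0))
  expect_equal(sum(tb0$field_agb_kg), sum(trees$agb_kg))
})

test_that("suppressed small trees push biomass detection up the DBH classes", {
  sc <- forest_scenario("alpine_default", extent_m = 80, seed = 21)
  f <- simulate_forest(sc)
  # emulate delineation detecting exactly the overstorey
  detected <- f$overstorey
  match <- list(pairs = data.frame(itc_id = f$id[detected],
                                   tree_id = f$id[detected]),
                unmatched_field_trees = f$id[!detected],
                unmatched_itcs = integer(0))
  parts <- lapply(which(detected), function(i)
    square_itc(f$id[i], f$x[i], f$y[i], f$crown_radius_m[i], f$height_m[i]))
  itcs <- itc_set(do.call(rbind, lapply(parts, `[[`, "tab")),
                  lapply(parts, `[[`, "ring"))
  itcs$table$dbh_cm <- f$dbh_cm[detected]
  itcs$table$agb_kg <- f$agb_kg[detected]
  trees <- data.frame(id = f$id, x = f$x, y = f$y, dbh_cm = f$dbh_cm,
                      height_m = f$height_m, agb_kg = f$agb_kg)
  tb <- biomass_detection_by_class(match, trees, itcs,
                                   dbh_breaks = c(20, 40, 60))
  det <- tb$detected_pct[tb$field_agb_kg > 0]
  # non-decreasing detected-biomass share with size class
  expect_true(all(diff(det) >= -1e-9))
  expect_lt(det[1], 100)
  expect_equal(det[length(det)], 100)
})

test_that("height agreement reports RMSE, R2 and bias", {
  s <- lapply(1:2, function(i) square_itc(i, i * 10, 0, 2, c(12, 18)[i]))
  itcs <- itc_set(do.call(rbind, lapply(s, `[[`, "tab")),
                  lapply(s, `[[`, "ring"))
  trees <- data.frame(id = 1:2, x = c(10, 20), y = 0,
                      height_m = c(10, 20), dbh_cm = c(30, 40))
  m <- list(pairs = data.frame(itc_id = 1:2, tree_id = 1:2))
  ha <- height_agreement(m, trees, itcs)
  expect_equal(ha$rmse_m, 2)

  # identical heights: perfect agreement
  itcs2 <- itcs; itcs2$table$height_m <- trees$height_m
  ha2 <- height_agreement(m, trees, itcs2)
  expect_equal(ha2$rmse_m, 0)
  expect_equal(ha2$r_squared, 1)
  expect_equal(ha2$mean_bias_pct, 0)

  expect_error(height_agreement(list(pairs = m$pairs[1, ]), trees, itcs),
               "2 matched")
})

test_that("5% height noise yields RMSE near 5% of mean height", {
  set.seed(31)
  n <- 400
  true_h <- runif(n, 10, 40)
  est_h <- true_h * (1 + rnorm(n, 0, 0.05))
  parts <- lapply(seq_len(n), function(i)
    square_itc(i, i * 3, 0, 1, est_h[i]))
  itcs <- itc_set(do.call(rbind, lapply(parts, `[[`, "tab")),
                  lapply(parts, `[[`, "ring"))
  trees <- data.frame(id = seq_len(n), x = 3 * seq_len(n), y = 0,
                      height_m = true_h, dbh_cm = 30)
  ha <- height_agreement(list(pairs = data.frame(itc_id = seq_len(n),
                                                 tree_id = seq_len(n))),
                         trees, itcs)
  expected <- 0.05 * mean(true_h)
  expect_lt(abs(ha$rmse_m - expected) / expected, 0.25)
})
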