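cube_from_matrix <- function(m, nb) {
  # one pixel row: build a small cube where pixel (1, j) has spectrum m[j, ]
  a <- array(0, dim = c(1, nrow(m), nb))
  for (j in seq_len(nrow(m))) a[1, j, ] <- m[j, ]
  hyper_cube(a, origin_x = 0, origin_y = 1, resolution = 1)
}

test_that("pixel normalization divides by the band sum and is idempotent", {
  cube <- cube_from_matrix(rbind(c(1, 2, 3, 4)), 4)
  n1 <- normalize_pixels(cube)
  expect_equal(as.numeric(n1$values[1, 1, ]), c(0.1, 0.2, 0.3, 0.4))
  n2 <- normalize_pixels(n1)
  expect_equal(n2$values, n1$values)

  set.seed(8)
  big <- hyper_cube(array(runif(20 * 20 * 6, 0.01, 1), dim = c(20, 20, 6)),
                    resolution = 1)
  s <- apply(normalize_pixels(big)$values, c(1, 2), sum)
  expect_true(all(abs(s - 1) < 1e-9))

  zero <- cube_from_matrix(rbind(c(0, 0, 0, 0), c(1, 1, 1, 1)), 4)
  expect_warning(nz <- normalize_pixels(zero), "zero-sum")
  expect_true(all(is.na(nz$values[1, 1, ])))
})

test_that("sunlit extraction keeps the bright half of each crown", {
  # 4 pixels in a row with brightnesses 1, 2, 3, 4; median 2.5
  cube <- cube_from_matrix(rbind(c(1, 1), c(2, 2), c(3, 3), c(4, 4)), 2)
  ring <- cbind(c(-0.5, 4.5, 4.5, -0.5), c(-0.5, -0.5, 1.5, 1.5))
  itcs <- itc_set(data.frame(id = 1L, x = 2, y = 0.5, height_m = 10,
                             crown_area_m2 = 8), list(ring))
  out <- extract_sunlit_pixels(cube, itcs)
  expect_equal(sort(out$brightness), c(3, 4))

  # a single-pixel crown keeps its pixel
  small_ring <- cbind(c(0.1, 0.9, 0.9, 0.1), c(0.1, 0.1, 0.9, 0.9))
  itcs1 <- itc_set(data.frame(id = 1L, x = 0.5, y = 0.5, height_m = 10,
                              crown_area_m2 = 0.6), list(small_ring))
  expect_equal(nrow(extract_sunlit_pixels(cube, itcs1)), 1L)

  # on a shaded-edge synthetic scene the kept pixels are brighter on average
  sc <- forest_scenario("alpine_default", extent_m = 40, seed = 15)
  f <- simulate_forest(sc)
  hsi <- simulate_hypercube(f, sc)
  over <- f[f$overstorey & f$crown_radius_m > 1.5, ]
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  polys <- lapply(seq_len(nrow(over)), function(i)
    cbind(over$x[i] + over$crown_radius_m[i] * cos(ang),
          over$y[i] + over$crown_radius_m[i] * sin(ang)))
  itcs2 <- itc_set(data.frame(id = seq_len(nrow(over)), x = over$x, y = over$y,
                              height_m = over$height_m,
                              crown_area_m2 = over$crown_area_m2), polys)
  sun <- extract_sunlit_pixels(hsi$cube, itcs2)
  d <- dim(hsi$cube$values)
  flat <- matrix(hsi$cube$values, d[1] * d[2], d[3])
  all_b <- rowMeans(flat)
  grid_idx <- (sun$col - 1L) * d[1] + sun$row
  rejected <- setdiff(which(all_b > 0), grid_idx)
  expect_gt(mean(sun$brightness), mean(all_b[rejected]))
})

test_that("JM distance obeys its closed forms, symmetry and bounds", {
  set.seed(3)
  a <- matrix(rnorm(300), ncol = 3)
  expect_equal(jm_distance(a, a), 0, tolerance = 1e-9)

  # 1-D equal-variance closed form: B = 0.5, JM = 2(1 - exp(-0.5))
  n <- 30000
  x <- matrix(rnorm(n, 0, 1)); y <- matrix(rnorm(n, 2, 1))
  expect_equal(jm_distance(x, y), 2 * (1 - exp(-0.5)), tolerance = 0.05)

  # symmetry and bounds; strictly increasing in mean separation
  prev <- -1
  for (mu in c(0.5, 1, 2, 4, 8)) {
    y <- matrix(rnorm(5000, mu, 1))
    x <- matrix(rnorm(5000, 0, 1))
    jm <- jm_distance(x, y)
    expect_equal(jm, jm_distance(y, x), tolerance = 1e-12)
    expect_gt(jm, prev)
    expect_true(jm >= 0 && jm <= 2)
    prev <- jm
  }
})

test_that("SFFS finds the informative features and beats pure forward search", {
  gen_problem <- function(seed, n_per = 40, p = 6, informative = c(2, 5)) {
    set.seed(seed)
    labels <- rep(c("A", "B", "C"), each = n_per)
    x <- matrix(rnorm(3 * n_per * p), ncol = p)
    shift <- rbind(c(0, 0), c(2.5, 0), c(0, 2.5))
    for (k in 1:3)
      x[labels == c("A", "B", "C")[k], informative] <-
        x[labels == c("A", "B", "C")[k], informative] +
        matrix(shift[k, ], n_per, 2, byrow = TRUE)
    list(x = x, labels = labels)
  }
  # planted 2-feature problems: SFFS finds the exhaustive-search optimum
  for (seed in 1:5) {
    pr <- gen_problem(seed)
    sel <- sffs_select(pr$x, pr$labels, 2)
    combos <- utils::combn(6, 2)
    crits <- apply(combos, 2, function(f)
      mean(c(jm_distance(pr$x[pr$labels == "A", f], pr$x[pr$labels == "B", f]),
             jm_distance(pr$x[pr$labels == "A", f], pr$x[pr$labels == "C", f]),
             jm_distance(pr$x[pr$labels == "B", f], pr$x[pr$labels == "C", f]))))
    best <- combos[, which.max(crits)]
    expect_equal(sort(as.integer(sel)), sort(best), info = paste("seed", seed))
    expect_equal(sort(as.integer(sel)), c(2L, 5L), info = paste("seed", seed))
  }

  # selecting everything is the identity
  pr <- gen_problem(99)
  expect_equal(as.integer(sffs_select(pr$x, pr$labels, 6)), 1:6)

  # floating search never does worse than plain forward selection
  forward_select <- function(x, labels, k) {
    sel <- integer(0)
    for (i in seq_len(k)) {
      rest <- setdiff(seq_len(ncol(x)), sel)
      vals <- vapply(rest, function(f)
        canopycarbon:::jm_criterion(x, labels, c(sel, f), "mean"), numeric(1))
      sel <- c(sel, rest[which.max(vals)])
    }
    sort(sel)
  }
  for (seed in 11:25) {
    pr <- gen_problem(seed, n_per = 25)
    k <- 3
    s_sffs <- sffs_select(pr$x, pr$labels, k)
    s_fwd <- forward_select(pr$x, pr$labels, k)
    c_sffs <- canopycarbon:::jm_criterion(pr$x, pr$labels, s_sffs, "mean")
    c_fwd <- canopycarbon:::jm_criterion(pr$x, pr$labels, s_fwd, "mean")
    expect_gte(c_sffs, c_fwd - 1e-12)
  }

  expect_error(sffs_select(pr$x, rep("A", nrow(pr$x)), 2), "2 classes")
})

test_that("the SVM separates separable classes and majority voting is exact", {
  set.seed(6)
  n <- 60
  x <- rbind(matrix(rnorm(n * 2, 0, 0.3), ncol = 2),
             matrix(rnorm(n * 2, 3, 0.3), ncol = 2))
  y <- rep(c("A", "B"), each = n)
  clf <- train_classifier(x, y, cv = FALSE, seed = 2)
  expect_equal(mean(predict(clf, x) == y), 1)

  # classes below the pixel floor are excluded with a warning
  y2 <- c(rep("A", n), rep("B", n - 3), rep("C", 3))
  expect_warning(train_classifier(x, y2, cv = FALSE, min_pixels = 5), "C")

  # majority rule with probability tie-breaking equals a brute-force count
  set.seed(7)
  px <- rbind(matrix(rnorm(40, 0, 0.3), ncol = 2),
              matrix(rnorm(40, 3, 0.3), ncol = 2))
  ids <- sample(1:6, 40, TRUE)
  lab <- classify_itcs(clf, px, ids)
  pred <- predict(clf, px)
  for (id in unique(ids)) {
    votes <- table(pred[ids == id])
    top <- names(votes)[votes == max(votes)]
    expect_true(lab[as.character(id)] %in% top)
  }
  # an id with no pixels comes back unknown
  lab2 <- classify_itcs(clf, px, ids, itc_ids = c(unique(ids), 999L))
  expect_equal(unname(lab2["999"]), "unknown")
})

test_that("shuffled labels drop cross-validated accuracy to chance", {
  set.seed(17)
  n <- 120
  x <- rbind(matrix(rnorm(n, 0, 0.4), ncol = 2),
             matrix(rnorm(n, 3, 0.4), ncol = 2))
  y <- sample(rep(c("A", "B"), each = n / 2))   # labels divorced from x
  half <- c(seq_len(n / 4), n / 2 + seq_len(n / 4))
  clf <- train_classifier(x[half, ], y[half], cv = FALSE, seed = 3)
  acc <- mean(predict(clf, x[-half, ]) == y[-half])
  # binomial error around 1/2 for 60 held-out pixels
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / (n / 2)))
})

test_that("confusion metrics satisfy their identities on the reference matrix", {
  cm <- reference_confusion_matrix()
  m <- confusion_metrics(cm)
  # hand-computed from the counts: trace 1590, total 1883
  expect_equal(m$overall_acc_pct, 100 * 1590 / 1883)
  expect_lte(m$kappa, m$overall_acc_pct / 100)
  expect_true(m$kappa >= -1 && m$kappa <= 1)

  # perfect agreement
  mp <- confusion_metrics(diag(5))
  expect_equal(mp$overall_acc_pct, 100)
  expect_equal(mp$kappa, 1)
  expect_true(all(mp$producers_acc == 100))

  # empty reference column is excluded from the average with a warning
  cm2 <- rbind(c(5, 0, 0), c(0, 4, 0), c(0, 0, 0))
  expect_warning(m2 <- confusion_metrics(cm2), "empty reference")
  expect_equal(m2$average_acc_pct, 100)

  expect_error(confusion_metrics(matrix(0, 2, 2)), "empty")

  # builder orientation: rows predicted, columns reference
  b <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"))
  expect_equal(b["A", "B"], 1)
  expect_equal(b["B", "A"], 0)
})
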