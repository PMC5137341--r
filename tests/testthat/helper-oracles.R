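# Independent brute-force oracles used by the oracle-equivalence tests.
# These re-derive each rule from its definition with no shared code paths.

# All-pairs circular-window local-maxima scan.
oracle_local_maxima <- function(values, resolution, window_diameter,
                                min_tree_height) {
  nr <- nrow(values); nc <- ncol(values)
  radius <- window_diameter / 2
  out <- NULL
  for (r in 1:nr) for (c in 1:nc) {
    v <- values[r, c]
    if (v <= min_tree_height) next
    ge_all <- TRUE; any_lower <- FALSE; tied_smaller <- FALSE
    for (r2 in 1:nr) for (c2 in 1:nc) {
      if (r2 == r && c2 == c) next
      d2 <- ((r2 - r) * resolution)^2 + ((c2 - c) * resolution)^2
      if (d2 > radius^2 + 1e-12) next
      w <- values[r2, c2]
      if (w > v) ge_all <- FALSE
      if (w < v) any_lower <- TRUE
      if (w == v && (r2 < r || (r2 == r && c2 < c))) tied_smaller <- TRUE
    }
    if (ge_all && any_lower && !tied_smaller)
      out <- rbind(out, c(r, c))
  }
  out
}

# Round-synchronous BFS region grower with apex-then-id conflict resolution.
oracle_grow <- function(values, seeds, frac, abs_thr) {
  nr <- nrow(values); nc <- ncol(values)
  lab <- matrix(0L, nr, nc)
  apex <- seeds$apex_height
  for (s in seq_len(nrow(seeds))) lab[seeds$row[s], seeds$col[s]] <- s
  repeat {
    claims <- list()
    for (r in 1:nr) for (c in 1:nc) {
      if (lab[r, c] != 0L) next
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r2 <- r + d[1]; c2 <- c + d[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        id <- lab[r2, c2]
        if (id == 0L) next
        gap <- apex[id] - values[r, c]
        if (gap < frac * apex[id] && gap < abs_thr)
          claims[[length(claims) + 1L]] <- c(r, c, id)
      }
    }
    if (!length(claims)) break
    cl <- unique(do.call(rbind, claims))
    key <- paste(cl[, 1], cl[, 2])
    for (k in unique(key)) {
      sub <- cl[key == k, , drop = FALSE]
      ids <- sub[, 3]
      win <- ids[order(-apex[ids], ids)][1]
      lab[sub[1, 1], sub[1, 2]] <- win
    }
  }
  lab
}

# Gift-wrapping (Jarvis march) convex hull area.
oracle_hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n < 3) return(0)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(1:n, p)
    q <- cand[1]
    for (r in cand[-1]) {
      cr <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
            (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
      d_q <- sum((pts[q, ] - pts[p, ])^2)
      d_r <- sum((pts[r, ] - pts[p, ])^2)
      if (cr < 0 || (cr == 0 && d_r > d_q)) q <- r
    }
    if (q == start) break
    hull <- c(hull, q)
    if (length(hull) > n) break
  }
  h <- pts[hull, , drop = FALSE]
  m <- nrow(h)
  i2 <- c(2:m, 1)
  abs(sum(h[, 1] * h[i2, 2] - h[i2, 1] * h[, 2])) / 2
}

# Exhaustive matching oracle applying the containment + height-contest rules.
oracle_match <- function(itcs, trees) {
  tab <- itcs$table
  taken <- rep(FALSE, nrow(trees))
  pairs <- NULL
  for (i in order(tab$id)) {
    ring <- itcs$polygons[[i]]
    cand <- c()
    for (t in seq_len(nrow(trees))) {
      if (taken[t]) next
      if (pt_in_ring(trees$x[t], trees$y[t], ring)) cand <- c(cand, t)
    }
    if (!length(cand)) next
    gap <- abs(trees$height_m[cand] - tab$height_m[i])
    best <- cand[order(gap, -trees$dbh_cm[cand], trees$id[cand])][1]
    taken[best] <- TRUE
    pairs <- rbind(pairs, c(tab$id[i], trees$id[best]))
  }
  pairs
}

# Winding-free convex containment test (boundary inclusive), written
# independently of the package's helper.
pt_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  sgn <- 0
  for (i in 1:n) {
    j <- if (i == n) 1 else i + 1
    cr <- (ring[j, 1] - ring[i, 1]) * (py - ring[i, 2]) -
          (ring[j, 2] - ring[i, 2]) * (px - ring[i, 1])
    if (abs(cr) < 1e-9) next
    s <- sign(cr)
    if (sgn == 0) sgn <- s else if (s != sgn) return(FALSE)
  }
  TRUE
}

# Small random CHM-like grid with a few smooth bumps.
random_bumpy_grid <- function(nr, nc, n_bumps = 3, seed = 1) {
  set.seed(seed)
  v <- matrix(stats::runif(nr * nc, 0, 1), nr, nc)
  for (b in seq_len(n_bumps)) {
    r0 <- stats::runif(1, 1, nr); c0 <- stats::runif(1, 1, nc)
    h <- stats::runif(1, 5, 25); w <- stats::runif(1, 2, 6)
    d2 <- outer(1:nr, 1:nc, function(r, c) (r - r0)^2 + (c - c0)^2)
    v <- pmax(v, h * exp(-d2 / (2 * w^2)))
  }
  v
}

# Reference 7-species crown-level confusion matrix used by the accuracy
# metric checks (rows predicted, columns reference).
reference_confusion_matrix <- function() {
  species <- c("Abies_alba", "Angiosperm", "Picea_abies", "Larix_decidua",
               "Pinus_cembra", "Pinus_nigra", "Pinus_sylvestris")
  m <- matrix(c(
    32,   2,  46,   7,  0,  0, 0,
     3, 483,  44,  18,  4,  0, 0,
     7,   7, 683,  18,  1,  0, 0,
     0,  36,  83, 334, 10,  2, 0,
     0,   1,   2,   0, 41,  0, 0,
     0,   0,   0,   2,  0, 14, 0,
     0,   0,   0,   0,  0,  0, 3), 7, 7, byrow = TRUE,
    dimnames = list(species, species))
  m
}
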