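#' Crown delineation parameters
#'
#' Controls the local-maxima tree-top finder and the region grower. Defaults
#' are plausible settings for spruce/larch-dominated Alpine stands and should
#' be tuned per site.
#'
#' @param window_diameter diameter (m) of the circular moving window used for
#'   local-maxima detection.
#' @param min_tree_height small-tree cut-off (m); pixels at or below it can
#'   never seed a crown.
#' @param frac_threshold a neighbouring pixel joins a crown while its drop
#'   below the seed apex is less than this fraction of the apex height.
#' @param abs_threshold ... and less than this absolute drop (m).
#' @param low_point_cutoff returns at or below this height (m) are discarded
#'   before convex hulling.
#' @return an object of class `delineation_params`.
#' @export
delineation_params <- function(window_diameter = 2.5, min_tree_height = 2,
                               frac_threshold = 0.45, abs_threshold = 6,
                               low_point_cutoff = 2) {
  stopifnot(window_diameter > 0, min_tree_height > 0, abs_threshold > 0,
            low_point_cutoff > 0,
            frac_threshold > 0, frac_threshold < 1)
  structure(list(window_diameter = window_diameter,
                 min_tree_height = min_tree_height,
                 frac_threshold = frac_threshold,
                 abs_threshold = abs_threshold,
                 low_point_cutoff = low_point_cutoff),
            class = "delineation_params")
}

default_delineation_params <- function() delineation_params()

# Offsets (dr, dc) whose pixel-centre distance is within the window radius.
window_offsets <- function(resolution, window_diameter) {
  radius <- window_diameter / 2
  half <- floor(radius / resolution)
  if (half < 1L)
    stop("moving window spans fewer than 3 pixels at this resolution; ",
         "increase window_diameter or refine the CHM", call. = FALSE)
  off <- expand.grid(dr = -half:half, dc = -half:half)
  d2 <- (off$dr * resolution)^2 + (off$dc * resolution)^2
  off <- off[d2 <= radius^2 + 1e-12 & !(off$dr == 0 & off$dc == 0), ]
  off
}

#' Find tree tops as local maxima of a smoothed CHM
#'
#' A pixel is a tree top when its height exceeds the small-tree cut-off, is
#' not exceeded by any pixel whose centre lies within the circular window,
#' and strictly exceeds at least one of them; among equal-valued candidates
#' sharing a window only the one with the smallest (row, col) in
#' lexicographic order is kept, so a flat plateau yields at most one seed and
#' a perfectly constant grid yields none.
#'
#' @param chm a smoothed [raster_grid()].
#' @param params a [delineation_params()].
#' @return data frame of class `tree_tops` with `row`, `col`, `x`, `y`,
#'   `apex_height`.
#' @export
find_local_maxima <- function(chm, params = delineation_params()) {
  stopifnot(inherits(chm, "raster_grid"))
  v <- chm$values
  nr <- nrow(v); nc <- ncol(v)
  off <- window_offsets(chm$resolution, params$window_diameter)
  keep <- v > params$min_tree_height
  any_lower <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(off))) {
    dr <- off$dr[i]; dc <- off$dc[i]
    if (abs(dr) >= nr || abs(dc) >= nc) next
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    rt <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    ct <- max(1, 1 - dc):min(nc, nc - dc)
    nb <- v[rs, cs, drop = FALSE]
    me <- v[rt, ct, drop = FALSE]
    blk <- matrix(FALSE, nr, nc)   # neighbour disqualifies this pixel
    eq <- nb == me
    # lexicographically smaller neighbour: dr < 0, or dr == 0 and dc < 0
    lex_smaller <- dr < 0 || (dr == 0 && dc < 0)
    blk[rt, ct] <- (nb > me) | (eq & lex_smaller)
    keep <- keep & !blk
    any_lower[rt, ct] <- any_lower[rt, ct] | (nb < me)
  }
  keep <- keep & any_lower
  idx <- which(keep)
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  o <- order(row, col)
  w <- pixel_to_world(chm, row[o], col[o])
  tops <- data.frame(row = row[o], col = col[o], x = w$x, y = w$y,
                     apex_height = v[idx][o])
  class(tops) <- c("tree_tops", "data.frame")
  tops
}

#' Grow crown regions around tree tops
#'
#' Four-neighbour region growing on the CHM. A pixel joins the region of seed
#' `s` when it is 4-connected to `s` through pixels whose drop below the seed
#' apex is less than `frac_threshold * apex` and less than `abs_threshold`.
#' Regions grow in parallel rounds until no pixel is added; a pixel claimable
#' by two regions in the same round goes to the seed with the greater apex
#' (ties to the smaller seed id). Unclaimed pixels are labelled 0.
#'
#' @param chm a smoothed [raster_grid()].
#' @param seeds a `tree_tops` data frame ([find_local_maxima()]); seed id is
#'   the row number.
#' @param params a [delineation_params()].
#' @return a [raster_grid()] label map (integer region ids, 0 = background).
#' @export
grow_crowns <- function(chm, seeds, params = delineation_params()) {
  stopifnot(inherits(chm, "raster_grid"), is.data.frame(seeds))
  v <- chm$values
  nr <- nrow(v); nc <- ncol(v)
  lab <- matrix(0L, nr, nc)
  low <- which(seeds$apex_height < params$min_tree_height)
  if (length(low)) {
    warning("skipping ", length(low), " seed(s) below the small-tree cut-off")
  }
  active <- setdiff(seq_len(nrow(seeds)), low)
  if (!length(active)) {
    return(raster_grid(lab, origin_x = chm$origin_x, origin_y = chm$origin_y,
                       resolution = chm$resolution, nodata = 0))
  }
  apex <- seeds$apex_height
  lab[cbind(seeds$row[active], seeds$col[active])] <- active
  frontier <- cbind(seeds$row[active], seeds$col[active])
  frontier_id <- as.integer(active)
  shifts <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  while (nrow(frontier) > 0L) {
    cand_r <- integer(0); cand_c <- integer(0); cand_id <- integer(0)
    for (k in 1:4) {
      rr <- frontier[, 1] + shifts[k, 1]
      cc <- frontier[, 2] + shifts[k, 2]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      if (!any(ok)) next
      rr <- rr[ok]; cc <- cc[ok]; id <- frontier_id[ok]
      free <- lab[cbind(rr, cc)] == 0L
      rr <- rr[free]; cc <- cc[free]; id <- id[free]
      if (!length(rr)) next
      gap <- apex[id] - v[cbind(rr, cc)]
      fit <- gap < params$frac_threshold * apex[id] & gap < params$abs_threshold
      cand_r <- c(cand_r, rr[fit]); cand_c <- c(cand_c, cc[fit])
      cand_id <- c(cand_id, id[fit])
    }
    if (!length(cand_r)) break
    # resolve competing claims: greater apex wins, then smaller seed id
    o <- order(cand_r, cand_c, -apex[cand_id], cand_id)
    pix <- (cand_c[o] - 1L) * nr + cand_r[o]
    first <- !duplicated(pix)
    rr <- cand_r[o][first]; cc <- cand_c[o][first]; id <- cand_id[o][first]
    lab[cbind(rr, cc)] <- id
    frontier <- cbind(rr, cc)
    frontier_id <- id
  }
  raster_grid(lab, origin_x = chm$origin_x, origin_y = chm$origin_y,
              resolution = chm$resolution, nodata = 0)
}

#' Extract first returns per crown region
#'
#' Keeps, for every labelled region, the first returns above the low-point
#' cut-off whose coordinates fall in the region's pixels. Regions left with
#' fewer than 3 points cannot be hulled and are dropped with a warning.
#'
#' @param labels label-map [raster_grid()] from [grow_crowns()].
#' @param cloud the [point_cloud()] the CHM was built from.
#' @param params a [delineation_params()].
#' @return named list mapping region id to a data frame of points.
#' @export
extract_crown_returns <- function(labels, cloud, params = delineation_params()) {
  stopifnot(inherits(labels, "raster_grid"), inherits(cloud, "point_cloud"))
  present <- sort(unique(labels$values[labels$values > 0L]))
  keep <- cloud$return_number == 1L & cloud$z > params$low_point_cutoff
  d <- cloud[keep, , drop = FALSE]
  reg <- integer(0)
  if (nrow(d) > 0L) {
    p <- world_to_pixel(labels, d$x, d$y)
    inb <- in_bounds(labels, p$row, p$col)
    d <- d[inb, , drop = FALSE]
    reg <- labels$values[cbind(p$row[inb], p$col[inb])]
    d <- d[reg > 0L, , drop = FALSE]
    reg <- reg[reg > 0L]
  }
  out <- split(d, reg)
  n <- vapply(out, nrow, integer(1))
  n_dropped <- sum(n < 3L) + length(setdiff(present, as.integer(names(out))))
  if (n_dropped > 0L)
    warning("dropping ", n_dropped,
            " region(s) with fewer than 3 first returns")
  out[n >= 3L]
}

#' Convex-hull crown polygons
#'
#' Applies a 2D convex hull to each region's first returns; the hull becomes
#' the crown polygon, its shoelace area the crown area (m2), and the crown
#' height is the 99th percentile of the region's first-return heights
#' (linear interpolation between order statistics).
#'
#' @param region_points named list from [extract_crown_returns()].
#' @param seeds optional `tree_tops` data frame; when given, seed coordinates
#'   and apex height are attached by region id.
#' @return an [itc_set()].
#' @export
hull_crowns <- function(region_points, seeds = NULL) {
  ids <- as.integer(names(region_points))
  rows <- list(); polys <- list()
  dropped <- 0L
  for (i in seq_along(region_points)) {
    pts <- region_points[[i]]
    h <- grDevices::chull(pts$x, pts$y)       # clockwise vertex order
    ring <- cbind(pts$x[h], pts$y[h])[rev(seq_along(h)), , drop = FALSE]
    area <- polygon_area(ring)
    if (nrow(ring) < 3L || area <= 0) {
      dropped <- dropped + 1L
      next
    }
    id <- ids[i]
    sx <- if (!is.null(seeds)) seeds$x[id] else mean(ring[, 1])
    sy <- if (!is.null(seeds)) seeds$y[id] else mean(ring[, 2])
    rows[[length(rows) + 1L]] <- data.frame(
      id = id, x = sx, y = sy,
      height_m = unname(stats::quantile(pts$z, 0.99, type = 7)),
      crown_area_m2 = area,
      apex_height = if (!is.null(seeds)) seeds$apex_height[id] else NA_real_)
    polys[[length(polys) + 1L]] <- ring
  }
  if (dropped > 0L)
    warning("dropping ", dropped, " region(s) with collinear points")
  if (!length(rows)) {
    tab <- data.frame(id = integer(), x = numeric(), y = numeric(),
                      height_m = numeric(), crown_area_m2 = numeric(),
                      apex_height = numeric())
    return(itc_set(tab, list()))
  }
  itc_set(do.call(rbind, rows), polys)
}

#' Delineate individual tree crowns from a point cloud
#'
#' Full delineation chain: rasterize the cloud to a CHM, low-pass filter it,
#' locate tree tops with a circular moving window, grow crown regions by the
#' relative and absolute height-drop rules, extract each region's first
#' returns above the low-point cut-off, and convex-hull them into crown
#' polygons. Deterministic for fixed inputs and parameters.
#'
#' @param cloud a [point_cloud()].
#' @param chm_params a [chm_params()] (default settings when `NULL`).
#' @param delin_params a [delineation_params()] (default settings when
#'   `NULL`).
#' @return an [itc_set()]; the smoothed CHM and label map are attached as
#'   attributes `chm` and `labels`.
#' @export
delineate <- function(cloud, chm_params = NULL, delin_params = NULL) {
  if (is.null(chm_params)) chm_params <- default_chm_params()
  if (is.null(delin_params)) delin_params <- default_delineation_params()
  chm <- smooth_chm(rasterize_chm(cloud, chm_params), chm_params)
  seeds <- find_local_maxima(chm, delin_params)
  if (nrow(seeds) == 0L) {
    itcs <- hull_crowns(structure(list(), names = character(0)))
  } else {
    labels <- grow_crowns(chm, seeds, delin_params)
    pts <- extract_crown_returns(labels, cloud, delin_params)
    itcs <- hull_crowns(pts, seeds)
    attr(itcs, "labels") <- labels
  }
  attr(itcs, "chm") <- chm
  itcs
}
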