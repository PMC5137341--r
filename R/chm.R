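#' Canopy height model parameters
#'
#' @param resolution CHM pixel size in metres (default 0.5 m, adequate for
#'   point densities of tens of pulses per m2).
#' @param smoothing_kernel `"mean3x3"` (default) or `"gaussian"`.
#' @param gaussian_sigma Gaussian kernel sigma in pixels (used when
#'   `smoothing_kernel = "gaussian"`).
#' @return an object of class `chm_params`.
#' @export
chm_params <- function(resolution = 0.5,
                       smoothing_kernel = c("mean3x3", "gaussian"),
                       gaussian_sigma = 1) {
  smoothing_kernel <- match.arg(smoothing_kernel)
  stopifnot(resolution > 0)
  if (smoothing_kernel == "gaussian") stopifnot(gaussian_sigma > 0)
  structure(list(resolution = resolution, smoothing_kernel = smoothing_kernel,
                 gaussian_sigma = gaussian_sigma), class = "chm_params")
}

default_chm_params <- function() chm_params()

#' Rasterize a point cloud into a canopy height model
#'
#' Each pixel takes the maximum return height of the points falling in it.
#' Pixels without points are filled with the mean of their non-empty
#' 8-neighbours (computed against the original occupancy), or 0 when all
#' neighbours are empty, so no nodata remains inside the cloud's bounding box.
#'
#' @param cloud a [point_cloud()].
#' @param params a [chm_params()].
#' @return a [raster_grid()] canopy height model.
#' @export
rasterize_chm <- function(cloud, params = chm_params()) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(params, "chm_params"))
  res <- params$resolution
  x0 <- min(cloud$x); y1 <- max(cloud$y)
  nc <- max(1L, ceiling((max(cloud$x) - x0) / res + 1e-12))
  nr <- max(1L, ceiling((y1 - min(cloud$y)) / res + 1e-12))
  col <- pmin(nc, as.integer(floor((cloud$x - x0) / res)) + 1L)
  row <- pmin(nr, as.integer(floor((y1 - cloud$y) / res)) + 1L)
  v <- matrix(NA_real_, nr, nc)
  idx <- (col - 1L) * nr + row
  mx <- tapply(cloud$z, idx, max)
  v[as.integer(names(mx))] <- mx
  # fill empties from originally non-empty 8-neighbourhood
  empty <- is.na(v)
  if (any(empty)) {
    occ <- !empty
    s <- shift_sum(ifelse(occ, v, 0))
    n <- shift_sum(occ * 1)
    fill <- ifelse(n > 0, s / n, 0)
    v[empty] <- fill[empty]
  }
  raster_grid(v, origin_x = x0, origin_y = y1, resolution = res)
}

# Sum over the 8-neighbourhood (excluding centre) by matrix shifting.
shift_sum <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    if (abs(dr) >= nr || abs(dc) >= nc) next
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    rt <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    ct <- max(1, 1 - dc):min(nc, nc - dc)
    out[rt, ct] <- out[rt, ct] + m[rs, cs]
  }
  out
}

#' Low-pass filter a canopy height model
#'
#' Smoothing reduces the number of spurious local maxima before tree-top
#' detection. The 3x3 mean filter uses the available neighbourhood at edges;
#' the Gaussian kernel is truncated at 3 sigma and renormalized at edges.
#' Either way smoothed values are convex combinations of the input, so the
#' value range can only contract.
#'
#' @param chm a [raster_grid()] with no interior nodata (see
#'   [rasterize_chm()]).
#' @param params a [chm_params()].
#' @return a smoothed [raster_grid()] with identical geometry.
#' @export
smooth_chm <- function(chm, params = chm_params()) {
  stopifnot(inherits(chm, "raster_grid"), inherits(params, "chm_params"))
  if (params$smoothing_kernel == "mean3x3") {
    k <- matrix(1, 3, 3)
  } else {
    sg <- params$gaussian_sigma
    half <- max(1L, ceiling(3 * sg))
    d <- (-half):half
    g <- exp(-d^2 / (2 * sg^2))
    k <- outer(g, g)
  }
  out <- convolve_renorm(chm$values, k)
  raster_grid(out, origin_x = chm$origin_x, origin_y = chm$origin_y,
              resolution = chm$resolution, nodata = chm$nodata)
}

# Kernel smoothing with edge renormalization (kernel weights that fall
# outside the grid are dropped and the remainder rescaled).
convolve_renorm <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  kh <- (nrow(k) - 1L) %/% 2L; kw <- (ncol(k) - 1L) %/% 2L
  num <- matrix(0, nr, nc)
  den <- matrix(0, nr, nc)
  for (dr in -kh:kh) for (dc in -kw:kw) {
    w <- k[dr + kh + 1L, dc + kw + 1L]
    if (w == 0) next
    if (abs(dr) >= nr || abs(dc) >= nc) next
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    rt <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    ct <- max(1, 1 - dc):min(nc, nc - dc)
    num[rt, ct] <- num[rt, ct] + w * m[rs, cs]
    den[rt, ct] <- den[rt, ct] + w
  }
  num / den
}
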