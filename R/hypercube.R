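#' Hyperspectral image cube
#'
#' A georeferenced multi-band raster: a 3D array `[row, col, band]` of
#' reflectances sharing the [raster_grid()] pixel conventions, plus band
#' centre wavelengths in nanometres.
#'
#' @param values numeric array `[n_rows, n_cols, n_bands]`, reflectances >= 0.
#' @param origin_x,origin_y top-left corner world coordinates (m).
#' @param resolution pixel size in metres.
#' @param wavelengths numeric vector of band wavelengths (nm).
#' @return an object of class `hyper_cube`.
#' @export
hyper_cube <- function(values, origin_x = 0,
                       origin_y = dim(values)[1] * resolution,
                       resolution = 1, wavelengths = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3L, resolution > 0)
  if (is.null(wavelengths))
    wavelengths <- seq(400, 990, length.out = dim(values)[3])
  stopifnot(length(wavelengths) == dim(values)[3])
  if (any(values < 0, na.rm = TRUE))
    stop("negative reflectances in hyperspectral cube", call. = FALSE)
  structure(list(values = values, origin_x = origin_x, origin_y = origin_y,
                 resolution = resolution, wavelengths = wavelengths),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("hyper_cube: %d x %d pixels, %d bands (%.0f-%.0f nm) at %.3g m\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              x$resolution))
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$values)

#' Sum-normalize hyperspectral pixels
#'
#' Divides every pixel's spectrum by its band sum, so each spectrum sums to
#' one. This suppresses brightness differences between flight strips while
#' preserving spectral shape. Zero-sum pixels are flagged `NA` with a warning.
#'
#' @param cube a [hyper_cube()].
#' @return a [hyper_cube()] of normalized reflectances.
#' @export
normalize_pixels <- function(cube) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$values)
  m <- matrix(cube$values, nrow = d[1] * d[2], ncol = d[3])
  s <- rowSums(m)
  zero <- !is.na(s) & s == 0
  if (any(zero)) {
    warning(sum(zero), " zero-sum pixel(s) flagged as nodata")
    s[zero] <- NA_real_
  }
  out <- m / s
  cube$values <- array(out, dim = d)
  cube
}

# Raster geometry view of a cube (for shared pixel/world helpers).
cube_grid <- function(cube) {
  raster_grid(matrix(0, dim(cube$values)[1], dim(cube$values)[2]),
              origin_x = cube$origin_x, origin_y = cube$origin_y,
              resolution = cube$resolution)
}
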