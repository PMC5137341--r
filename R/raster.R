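#' Georeferenced single-band raster grid
#'
#' Lightweight in-memory raster used for canopy height models, crown label
#' maps and carbon density maps. Row 1 is the northernmost row; world
#' coordinates are anchored at the top-left pixel corner and each pixel
#' covers a half-open square of side `resolution`.
#'
#' @param values numeric matrix (rows run north to south).
#' @param origin_x,origin_y world coordinates (m) of the top-left corner.
#' @param resolution pixel size in metres (> 0).
#' @param nodata sentinel value for missing cells.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin_x = 0, origin_y = nrow(values) * resolution,
                        resolution = 1, nodata = -9999) {
  values <- as.matrix(values)
  stopifnot(is.numeric(resolution), length(resolution) == 1L, resolution > 0)
  g <- structure(
    list(values = values, origin_x = origin_x, origin_y = origin_y,
         resolution = resolution, nodata = nodata),
    class = "raster_grid")
  g
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[x$values != x$nodata & is.finite(x$values)]
  cat(sprintf("raster_grid: %d x %d pixels at %.3g m\n",
              nrow(x$values), ncol(x$values), x$resolution))
  cat(sprintf("  origin (top-left): %.2f, %.2f\n", x$origin_x, x$origin_y))
  if (length(v)) cat(sprintf("  values: [%.3f, %.3f]\n", min(v), max(v)))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Pixel centre to world coordinates
#'
#' @param grid a [raster_grid()].
#' @param row,col 1-based pixel indices.
#' @return list with numeric vectors `x`, `y` (pixel centres, metres).
#' @export
pixel_to_world <- function(grid, row, col) {
  list(x = grid$origin_x + (col - 0.5) * grid$resolution,
       y = grid$origin_y - (row - 0.5) * grid$resolution)
}

#' World coordinates to pixel indices
#'
#' Half-open pixel convention: a point on the shared edge of two pixels
#' belongs to the pixel to its east/south.
#'
#' @param grid a [raster_grid()].
#' @param x,y world coordinates (m).
#' @return list with integer vectors `row`, `col` (may fall outside the grid).
#' @export
world_to_pixel <- function(grid, x, y) {
  list(row = as.integer(floor((grid$origin_y - y) / grid$resolution)) + 1L,
       col = as.integer(floor((x - grid$origin_x) / grid$resolution)) + 1L)
}

in_bounds <- function(grid, row, col) {
  row >= 1L & row <= nrow(grid$values) & col >= 1L & col <= ncol(grid$values)
}

#' Write a raster grid as an ESRI ASCII grid
#'
#' Plain-text `.asc` format readable by mainstream GIS software; the nodata
#' sentinel is preserved in the header.
#'
#' @param grid a [raster_grid()].
#' @param path output file path.
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open raster path for writing: ", path, call. = FALSE))
  on.exit(close(con))
  v <- grid$values
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$origin_x),
    sprintf("yllcorner %.10g", grid$origin_y - nrow(v) * grid$resolution),
    sprintf("cellsize %.10g", grid$resolution),
    sprintf("NODATA_value %.10g", grid$nodata)), con)
  utils::write.table(format(v, digits = 12, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file written by [write_raster()] or other GIS software.
#' @return a [raster_grid()].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 6L)
  hdr <- hdr[grepl("^[a-zA-Z]", trimws(hdr))]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% key)) stop("malformed ASCII grid header in ", path, call. = FALSE)
  nodata <- if ("nodata_value" %in% key) val[["nodata_value"]] else -9999
  m <- matrix(scan(path, skip = length(hdr), quiet = TRUE),
              nrow = val[["nrows"]], ncol = val[["ncols"]], byrow = TRUE)
  raster_grid(m,
              origin_x = val[["xllcorner"]],
              origin_y = val[["yllcorner"]] + val[["nrows"]] * val[["cellsize"]],
              resolution = val[["cellsize"]], nodata = nodata)
}
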