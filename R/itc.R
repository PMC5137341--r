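#' Individual tree crown (ITC) collection
#'
#' An `itc_set` couples a per-crown attribute table with the convex crown
#' polygons. Attributes follow the pipeline's unit conventions: heights and
#' coordinates in metres, crown area in m2, DBH in cm, biomass in kg,
#' carbon in kg.
#'
#' @param table data frame with at least `id`, `x`, `y` (seed position),
#'   `height_m`, `crown_area_m2`; optionally `species`, `dbh_cm`, `agb_kg`,
#'   `carbon_kg`, `apex_height`.
#' @param polygons list (parallel to `table` rows) of n x 2 matrices of
#'   polygon vertices (open rings, counter-clockwise).
#' @return an object of class `itc_set`.
#' @export
itc_set <- function(table, polygons) {
  stopifnot(is.data.frame(table), is.list(polygons),
            nrow(table) == length(polygons))
  need <- c("id", "x", "y", "height_m", "crown_area_m2")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("itc_set table lacks: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!"species" %in% names(table))
    table[["species"]] <- rep(NA_character_, nrow(table))
  for (col in c("dbh_cm", "agb_kg", "carbon_kg"))
    if (!col %in% names(table)) table[[col]] <- rep(NA_real_, nrow(table))
  structure(list(table = table, polygons = polygons), class = "itc_set")
}

#' @export
length.itc_set <- function(x) nrow(x$table)

#' @export
print.itc_set <- function(x, ...) {
  cat(sprintf("itc_set: %d crowns\n", nrow(x$table)))
  if (nrow(x$table)) {
    cat(sprintf("  height: [%.1f, %.1f] m  crown area: [%.1f, %.1f] m2\n",
                min(x$table$height_m), max(x$table$height_m),
                min(x$table$crown_area_m2), max(x$table$crown_area_m2)))
    if (any(!is.na(x$table$carbon_kg)))
      cat(sprintf("  total carbon: %.1f kg\n", sum(x$table$carbon_kg, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
as.data.frame.itc_set <- function(x, ...) x$table

# Shoelace area of an open vertex ring (absolute value).
polygon_area <- function(ring) {
  n <- nrow(ring)
  if (n < 3L) return(0)
  i2 <- c(2:n, 1L)
  abs(sum(ring[, 1] * ring[i2, 2] - ring[i2, 1] * ring[, 2])) / 2
}

# Simple-ring check: no two non-adjacent edges intersect.
is_simple_ring <- function(ring) {
  n <- nrow(ring)
  if (n < 3L) return(FALSE)
  seg <- cbind(ring, ring[c(2:n, 1L), , drop = FALSE])
  inter <- function(a, b) {
    d1 <- cross2(b[3:4] - b[1:2], a[1:2] - b[1:2])
    d2 <- cross2(b[3:4] - b[1:2], a[3:4] - b[1:2])
    d3 <- cross2(a[3:4] - a[1:2], b[1:2] - a[1:2])
    d4 <- cross2(a[3:4] - a[1:2], b[3:4] - a[1:2])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  if (n > 3L)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      if (!adjacent && inter(seg[i, ], seg[j, ])) return(FALSE)
    }
  TRUE
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

# Point-in-convex-polygon with boundary counted as inside.
point_in_polygon <- function(px, py, ring, tol = 1e-9) {
  n <- nrow(ring)
  if (n < 3L) return(rep(FALSE, length(px)))
  inside <- rep(TRUE, length(px))
  # orientation sign of the ring
  i2 <- c(2:n, 1L)
  orient <- sign(sum(ring[, 1] * ring[i2, 2] - ring[i2, 1] * ring[, 2]))
  if (orient == 0) return(rep(FALSE, length(px)))
  for (i in seq_len(n)) {
    j <- i2[i]
    cr <- (ring[j, 1] - ring[i, 1]) * (py - ring[i, 2]) -
          (ring[j, 2] - ring[i, 2]) * (px - ring[i, 1])
    inside <- inside & (orient * cr >= -tol)
  }
  inside
}

#' Write ITC polygons to GeoJSON
#'
#' Emits a GeoJSON `FeatureCollection` with one polygon feature per crown and
#' the attributes `id`, `species`, `height_m`, `crown_area_m2`, `dbh_cm`,
#' `agb_kg`, `carbon_kg`.
#'
#' @param itcs an [itc_set()].
#' @param path output `.geojson` path.
#' @export
write_itc_polygons <- function(itcs, path) {
  stopifnot(inherits(itcs, "itc_set"))
  feats <- vector("list", length(itcs))
  for (i in seq_along(feats)) {
    ring <- itcs$polygons[[i]]
    if (!is_simple_ring(ring))
      stop("self-intersecting polygon for ITC id ", itcs$table$id[i], call. = FALSE)
    closed <- rbind(ring, ring[1L, , drop = FALSE])
    r <- itcs$table[i, ]
    feats[[i]] <- list(
      type = "Feature",
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(closed)), function(k)
                        c(closed[k, 1], closed[k, 2])))),
      properties = list(id = r$id, species = r$species, height_m = r$height_m,
                        crown_area_m2 = r$crown_area_m2, dbh_cm = r$dbh_cm,
                        agb_kg = r$agb_kg, carbon_kg = r$carbon_kg))
  }
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(NULL)
}

#' Read ITC polygons from GeoJSON
#'
#' @param path `.geojson` file written by [write_itc_polygons()].
#' @return an [itc_set()]; seed `x`, `y` are taken as the polygon centroid if
#'   not stored.
#' @export
read_itc_polygons <- function(path) {
  fc <- jsonlite::read_json(path)
  feats <- fc$features
  if (length(feats) == 0L)
    return(itc_set(data.frame(id = integer(), x = numeric(), y = numeric(),
                              height_m = numeric(), crown_area_m2 = numeric()),
                   list()))
  rows <- vector("list", length(feats))
  polys <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    ring <- ring[-nrow(ring), , drop = FALSE]     # drop closing vertex
    pr <- f$properties
    num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
    rows[[i]] <- data.frame(
      id = as.integer(pr$id), x = mean(ring[, 1]), y = mean(ring[, 2]),
      height_m = num(pr$height_m), crown_area_m2 = num(pr$crown_area_m2),
      species = if (is.null(pr$species)) NA_character_ else as.character(pr$species),
      dbh_cm = num(pr$dbh_cm), agb_kg = num(pr$agb_kg),
      carbon_kg = num(pr$carbon_kg))
    polys[[i]] <- ring
  }
  itc_set(do.call(rbind, rows), polys)
}
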