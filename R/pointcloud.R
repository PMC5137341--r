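#' Height-normalized laser-scanning point cloud
#'
#' A data frame of laser returns with columns `x`, `y` (projected metres),
#' `z` (metres above ground after height normalization), `return_number`,
#' `num_returns` and `is_ground`. Small negative heights (down to -0.5 m)
#' are tolerated as normalization noise.
#'
#' @param x,y,z numeric coordinate vectors (metres).
#' @param return_number,num_returns integer return attributes
#'   (`return_number <= num_returns`).
#' @param is_ground logical ground-classification flag.
#' @return an object of class `point_cloud` (a data frame).
#' @export
point_cloud <- function(x, y, z, return_number = 1L, num_returns = 1L,
                        is_ground = FALSE) {
  d <- data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                  return_number = as.integer(return_number),
                  num_returns = as.integer(num_returns),
                  is_ground = as.logical(is_ground))
  validate_point_cloud(d)
  class(d) <- c("point_cloud", "data.frame")
  d
}

validate_point_cloud <- function(d) {
  if (nrow(d) == 0L) stop("empty point cloud", call. = FALSE)
  bad <- which(!is.finite(d$x) | !is.finite(d$y) | !is.finite(d$z))
  if (length(bad))
    stop("non-finite coordinates at record(s) ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  bad <- which(d$z < -0.5)
  if (length(bad))
    stop("height below -0.5 m (cloud not height-normalized?) at record(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  bad <- which(d$return_number < 1L | d$return_number > d$num_returns)
  if (length(bad))
    stop("return_number outside [1, num_returns] at record(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  invisible(d)
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d returns (%d first returns)\n",
              nrow(x), sum(x$return_number == 1L)))
  cat(sprintf("  x: [%.2f, %.2f]  y: [%.2f, %.2f]  z: [%.2f, %.2f]\n",
              min(x$x), max(x$x), min(x$y), max(x$y), min(x$z), max(x$z)))
  invisible(x)
}

#' Read a point cloud from LAS or XYZ-CSV
#'
#' The XYZ-CSV dialect is a comma-separated UTF-8 table with a header row and
#' columns `x,y,z[,return_number,num_returns,classification]`. LAS files are
#' read with a built-in binary reader covering the LAS 1.0-1.4 core header
#' and point record formats 0-3 (coordinates, return byte, classification).
#' Records with missing return numbers receive `return_number = 1`,
#' `num_returns = 1` with a warning.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"las"` or `"xyz_csv"`.
#' @return a [point_cloud()].
#' @export
read_point_cloud <- function(path, format = c("auto", "las", "xyz_csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("point-cloud file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.las$", path, ignore.case = TRUE)) "las" else "xyz_csv"
  d <- if (format == "las") read_las(path) else read_xyz_csv(path)
  validate_point_cloud(d)
  class(d) <- c("point_cloud", "data.frame")
  d
}

read_xyz_csv <- function(path) {
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) stop("unreadable XYZ-CSV file ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  names(d) <- tolower(names(d))
  miss <- setdiff(c("x", "y", "z"), names(d))
  if (length(miss))
    stop("XYZ-CSV ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(d) == 0L) stop("empty point cloud in ", path, call. = FALSE)
  if (!("return_number" %in% names(d)) || !("num_returns" %in% names(d))) {
    warning("return numbers missing in ", basename(path),
            "; assuming single returns")
    d$return_number <- 1L
    d$num_returns <- 1L
  }
  d$is_ground <- if ("classification" %in% names(d)) d$classification == 2L else FALSE
  d[c("x", "y", "z", "return_number", "num_returns", "is_ground")]
}

#' Write a point cloud
#'
#' @param cloud a [point_cloud()].
#' @param path output path.
#' @param format `"auto"` (by extension), `"las"` (point format 0) or
#'   `"xyz_csv"`.
#' @export
write_point_cloud <- function(cloud, path, format = c("auto", "las", "xyz_csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.las$", path, ignore.case = TRUE)) "las" else "xyz_csv"
  if (format == "las") return(write_las(cloud, path))
  d <- as.data.frame(cloud)
  d$classification <- ifelse(d$is_ground, 2L, 1L)
  utils::write.csv(
    d[c("x", "y", "z", "return_number", "num_returns", "classification")],
    path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

# --- minimal LAS 1.2 binary reader/writer (point formats 0-3) ---------------

read_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4, useBytes = TRUE)
  if (!identical(sig, "LASF"))
    stop("not a LAS file (bad signature) in ", path, call. = FALSE)
  invisible(readBin(con, "raw", 20))            # source id .. project guid
  ver <- readBin(con, "integer", 2, size = 1, signed = FALSE)
  invisible(readBin(con, "raw", 64))            # system id + software
  invisible(readBin(con, "integer", 2, size = 2, signed = FALSE)) # day, year
  invisible(readBin(con, "integer", 1, size = 2, signed = FALSE)) # header size
  offset <- readBin(con, "integer", 1, size = 4)
  invisible(readBin(con, "integer", 1, size = 4))  # n VLRs
  fmt <- readBin(con, "integer", 1, size = 1, signed = FALSE)
  reclen <- readBin(con, "integer", 1, size = 2, signed = FALSE)
  npts <- readBin(con, "integer", 1, size = 4)
  invisible(readBin(con, "integer", 5, size = 4))  # by-return counts
  scale <- readBin(con, "double", 3)
  off3 <- readBin(con, "double", 3)
  if (fmt > 3L) stop("unsupported LAS point format ", fmt, " in ", path, call. = FALSE)
  if (npts <= 0L) stop("empty point cloud in ", path, call. = FALSE)
  seek(con, offset)
  raw <- readBin(con, "raw", npts * reclen)
  if (length(raw) < npts * reclen)
    stop("truncated LAS record section in ", path, " (record ",
         length(raw) %/% reclen + 1L, ")", call. = FALSE)
  rec <- matrix(raw, nrow = reclen)
  int4 <- function(rows) {
    b <- rec[rows, , drop = FALSE]
    readBin(as.vector(b), "integer", n = npts, size = 4)
  }
  xi <- int4(1:4); yi <- int4(5:8); zi <- int4(9:12)
  flags <- as.integer(rec[15, ])                 # return byte
  cls <- as.integer(rec[16, ])
  data.frame(
    x = xi * scale[1] + off3[1],
    y = yi * scale[2] + off3[2],
    z = zi * scale[3] + off3[3],
    return_number = pmax(1L, bitwAnd(flags, 7L)),
    num_returns = pmax(1L, bitwAnd(bitwShiftR(flags, 3L), 7L)),
    is_ground = bitwAnd(cls, 31L) == 2L)
}

write_las <- function(cloud, path) {
  stopifnot(nrow(cloud) > 0L)
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open LAS path for writing: ", path, call. = FALSE))
  on.exit(close(con))
  n <- nrow(cloud)
  off3 <- c(floor(min(cloud$x)), floor(min(cloud$y)), 0)
  # finest scale the int32 record supports for this extent (>= 1e-7 m)
  rng <- pmax(c(max(cloud$x) - off3[1], max(cloud$y) - off3[2],
                max(abs(cloud$z))), 1)
  scale <- pmax(rng / 2e9, 1e-7)
  header_size <- 227L
  writeChar("LASF", con, eos = NULL)
  writeBin(rep(0L, 2), con, size = 2)              # source id, global enc
  writeBin(rep(as.raw(0), 16), con)                # project guid
  writeBin(c(1L, 2L), con, size = 1)               # version 1.2
  writeBin(rep(as.raw(0), 64), con)                # system + software id
  writeBin(c(1L, 2020L), con, size = 2)            # day, year
  writeBin(header_size, con, size = 2)
  writeBin(as.integer(header_size), con, size = 4) # offset to points
  writeBin(0L, con, size = 4)                      # n VLRs
  writeBin(0L, con, size = 1)                      # point format 0
  writeBin(20L, con, size = 2)                     # record length
  writeBin(n, con, size = 4)
  by_ret <- integer(5)
  tb <- table(factor(pmin(cloud$return_number, 5L), levels = 1:5))
  by_ret[] <- as.integer(tb)
  writeBin(by_ret, con, size = 4)
  writeBin(scale, con)
  writeBin(off3, con)
  writeBin(c(max(cloud$x), min(cloud$x), max(cloud$y), min(cloud$y),
             max(cloud$z), min(cloud$z)), con)
  xi <- as.integer(round((cloud$x - off3[1]) / scale[1]))
  yi <- as.integer(round((cloud$y - off3[2]) / scale[2]))
  zi <- as.integer(round((cloud$z - off3[3]) / scale[3]))
  flags <- bitwOr(pmin(cloud$return_number, 7L),
                  bitwShiftL(pmin(cloud$num_returns, 7L), 3L))
  cls <- ifelse(cloud$is_ground, 2L, 1L)
  rec <- matrix(as.raw(0), nrow = 20L, ncol = n)
  rec[1:4, ] <- matrix(writeBin(xi, raw(), size = 4), nrow = 4)
  rec[5:8, ] <- matrix(writeBin(yi, raw(), size = 4), nrow = 4)
  rec[9:12, ] <- matrix(writeBin(zi, raw(), size = 4), nrow = 4)
  rec[15, ] <- as.raw(flags)
  rec[16, ] <- as.raw(cls)
  writeBin(as.vector(rec), con)
  invisible(NULL)
}
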