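#' Lightweight geographic grid (lon/lat raster)
#'
#' `geogrid` is the package's in-memory raster: a numeric matrix on a
#' regular longitude/latitude grid. Rows run north to south, columns west
#' to east, and a cell's value refers to its center (half-open cell
#' intervals). Missing data are `NA`.
#'
#' @param values numeric matrix; rows are latitude bands from north to
#'   south, columns longitude bands from west to east.
#' @param xmin,xmax,ymin,ymax extent of the grid edges, decimal degrees.
#' @param name optional layer name (e.g. a trait label), kept as metadata.
#' @return an object of class `geogrid`.
#' @examples
#' g <- geogrid(matrix(1:12, 3, 4), 0, 4, 0, 3)
#' gg_res(g)
#' @export
geogrid <- function(values, xmin, xmax, ymin, ymax, name = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (xmax <= xmin || ymax <= ymin)
    stop("geogrid: extent is empty (xmax <= xmin or ymax <= ymin)")
  structure(
    list(values = values, xmin = xmin, xmax = xmax, ymin = ymin,
         ymax = ymax, name = name),
    class = "geogrid")
}

#' @export
print.geogrid <- function(x, ...) {
  r <- gg_res(x)
  cat(sprintf("geogrid%s: %d x %d cells, extent [%g, %g] x [%g, %g], res %g x %g\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              nrow(x$values), ncol(x$values),
              x$xmin, x$xmax, x$ymin, x$ymax, r[1], r[2]))
  v <- x$values[!is.na(x$values)]
  if (length(v))
    cat(sprintf("  values: [%g, %g], %d NA\n", min(v), max(v),
                sum(is.na(x$values))))
  invisible(x)
}

#' Grid resolution in degrees
#' @param g a [geogrid]
#' @return numeric length 2: (lon, lat) cell size.
#' @export
gg_res <- function(g) {
  c((g$xmax - g$xmin) / ncol(g$values), (g$ymax - g$ymin) / nrow(g$values))
}

#' Cell-center coordinates
#' @param g a [geogrid]
#' @return list with `lon` (west to east) and `lat` (north to south)
#'   center vectors.
#' @export
gg_centers <- function(g) {
  r <- gg_res(g)
  list(lon = g$xmin + (seq_len(ncol(g$values)) - 0.5) * r[1],
       lat = g$ymax - (seq_len(nrow(g$values)) - 0.5) * r[2])
}

## row/col of the cell containing each point; NA outside the extent.
gg_cell <- function(g, lon, lat) {
  r <- gg_res(g)
  col <- floor((lon - g$xmin) / r[1]) + 1L
  row <- floor((g$ymax - lat) / r[2]) + 1L
  ## points exactly on the east/south edge belong to the last cell
  col[lon == g$xmax] <- ncol(g$values)
  row[lat == g$ymin] <- nrow(g$values)
  bad <- lon < g$xmin | lon > g$xmax | lat < g$ymin | lat > g$ymax
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = row, col = col)
}

#' Extract cell values at point locations
#'
#' Nearest-cell (containing-cell) lookup. Points outside the extent give
#' `NA`.
#' @param g a [geogrid]
#' @param lon,lat point coordinates, degrees.
#' @return numeric vector of cell values.
#' @export
gg_extract <- function(g, lon, lat) {
  rc <- gg_cell(g, lon, lat)
  out <- rep(NA_real_, length(lon))
  ok <- !is.na(rc[, 1])
  out[ok] <- g$values[cbind(rc[ok, 1], rc[ok, 2])]
  out
}

#' Block-mean aggregation to a coarser grid
#'
#' Aggregates by an integer factor using the mean over valid (non-`NA`)
#' fine cells. A coarse cell whose valid fine-cell fraction falls below
#' `min_valid` becomes `NA`. With `min_valid = 0` any coarse cell with at
#' least one valid fine cell gets a value; the valid-cell mean is
#' conserved between input and output.
#'
#' @param g a [geogrid]
#' @param fact integer aggregation factor (applies to both axes).
#' @param min_valid minimum fraction of valid fine cells per coarse cell,
#'   in \[0, 1\].
#' @return a coarser [geogrid].
#' @export
gg_aggregate <- function(g, fact, min_valid = 0) {
  fact <- as.integer(fact)
  if (fact < 1) stop("gg_aggregate: fact must be a positive integer")
  nr <- nrow(g$values); nc <- ncol(g$values)
  if (nr %% fact != 0 || nc %% fact != 0)
    stop(sprintf("gg_aggregate: grid %d x %d not divisible by fact %d",
                 nr, nc, fact))
  if (fact == 1) return(g)
  NR <- nr %/% fact; NC <- nc %/% fact
  bi <- (seq_len(nr) - 1L) %/% fact + 1L
  bj <- (seq_len(nc) - 1L) %/% fact + 1L
  idx <- factor(bi[row(g$values)] + NR * (bj[col(g$values)] - 1L),
                levels = seq_len(NR * NC))
  v <- as.vector(g$values)
  sums <- tapply(ifelse(is.na(v), 0, v), idx, sum)
  nval <- tapply(!is.na(v), idx, sum)
  out <- as.numeric(sums) / as.numeric(nval)
  out[nval == 0 | nval / fact^2 < min_valid] <- NA_real_
  geogrid(matrix(out, NR, NC), g$xmin, g$xmax, g$ymin, g$ymax,
          name = g$name)
}

#' Bilinear interpolation at point locations
#'
#' Interpolates between the four surrounding cell centers; outside the
#' outermost centers the value is clamped to the edge cell (constant
#' extrapolation). `NA` in any contributing cell propagates.
#'
#' @inheritParams gg_extract
#' @return numeric vector of interpolated values.
#' @export
gg_bilinear <- function(g, lon, lat) {
  cen <- gg_centers(g)
  nx <- length(cen$lon); ny <- length(cen$lat)
  ## fractional index along each axis (lat centers run north->south)
  fx <- (lon - cen$lon[1]) / (gg_res(g)[1])
  fy <- (cen$lat[1] - lat) / (gg_res(g)[2])
  fx <- pmin(pmax(fx, 0), nx - 1)
  fy <- pmin(pmax(fy, 0), ny - 1)
  x0 <- pmin(floor(fx), nx - 2); x1 <- x0 + 1
  y0 <- pmin(floor(fy), ny - 2); y1 <- y0 + 1
  if (nx == 1) { x0 <- x1 <- 0; }
  if (ny == 1) { y0 <- y1 <- 0; }
  wx <- fx - x0; wy <- fy - y0
  v <- g$values
  at <- function(r, c) v[cbind(r + 1L, c + 1L)]
  (1 - wx) * (1 - wy) * at(y0, x0) + wx * (1 - wy) * at(y0, x1) +
    (1 - wx) * wy * at(y1, x0) + wx * wy * at(y1, x1)
}

#' Crop a grid to a row/column window
#' @param g a [geogrid]
#' @param rows,cols integer ranges of rows (from north) and columns
#'   (from west) to keep; must be contiguous.
#' @return a [geogrid] covering the window.
#' @export
gg_crop <- function(g, rows, cols) {
  rows <- sort(unique(as.integer(rows))); cols <- sort(unique(as.integer(cols)))
  if (any(diff(rows) != 1) || any(diff(cols) != 1))
    stop("gg_crop: rows and cols must be contiguous ranges")
  r <- gg_res(g)
  geogrid(g$values[rows, cols, drop = FALSE],
          xmin = g$xmin + (min(cols) - 1) * r[1],
          xmax = g$xmin + max(cols) * r[1],
          ymin = g$ymax - max(rows) * r[2],
          ymax = g$ymax - (min(rows) - 1) * r[2],
          name = g$name)
}

#' @export
as.data.frame.geogrid <- function(x, ...) {
  cen <- gg_centers(x)
  data.frame(lon = rep(cen$lon, each = nrow(x$values)),
             lat = rep(cen$lat, times = ncol(x$values)),
             value = as.vector(x$values))
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text raster exchange format (`.asc`): a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of values from north to south.
#' Requires square cells.
#'
#' @param path file path.
#' @return `read_asc` returns a [geogrid]; `write_asc` returns `path`
#'   invisibly.
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (!k %in% key) stop("read_asc: header missing ", k)
  nod <- if ("nodata_value" %in% key) val[["nodata_value"]] else -9999
  vals <- scan(path, skip = length(hdr), quiet = TRUE)
  m <- matrix(vals, nrow = val[["nrows"]], ncol = val[["ncols"]],
              byrow = TRUE)
  m[m == nod] <- NA_real_
  cs <- val[["cellsize"]]
  geogrid(m, xmin = val[["xllcorner"]],
          xmax = val[["xllcorner"]] + val[["ncols"]] * cs,
          ymin = val[["yllcorner"]],
          ymax = val[["yllcorner"]] + val[["nrows"]] * cs)
}

#' @rdname read_asc
#' @param g a [geogrid] with square cells.
#' @param nodata value written for `NA` cells.
#' @export
write_asc <- function(g, path, nodata = -9999) {
  r <- gg_res(g)
  if (abs(r[1] - r[2]) > 1e-9 * max(r))
    stop("write_asc: ESRI ASCII requires square cells")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(g$values)),
    paste("nrows", nrow(g$values)),
    paste("xllcorner", format(g$xmin, digits = 15)),
    paste("yllcorner", format(g$ymin, digits = 15)),
    paste("cellsize", format(r[1], digits = 15)),
    paste("NODATA_value", nodata)), con)
  m <- g$values
  m[is.na(m)] <- nodata
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
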