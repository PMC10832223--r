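#' Regular analysis grid
#'
#' A light-weight description of a regular raster grid in a projected,
#' metric coordinate system.  Rasters on the grid are plain numeric
#' matrices with \code{n_rows} rows and \code{n_cols} columns; row 1 is the
#' northernmost row (standard north-up raster orientation) and cells are
#' half-open intervals \code{[x, x + cell_size)} on both axes.
#'
#' @param xmin,ymin coordinates (metres) of the lower-left corner.
#' @param n_rows,n_cols grid dimensions.
#' @param cell_size cell edge length in metres.
#' @param lon0,lat0 geographic anchor (degrees) of the projected origin,
#'   used for inverse projection when solar geometry needs longitude and
#'   latitude.  The projection is a local equirectangular approximation,
#'   adequate over study-area extents of tens of kilometres.
#' @return an object of class \code{"zr_grid"}.
#' @export
make_grid <- function(xmin, ymin, n_rows, n_cols, cell_size,
                      lon0 = 35.0, lat0 = -1.5) {
  stopifnot(cell_size > 0, n_rows >= 1, n_cols >= 1)
  structure(list(xmin = xmin, ymin = ymin,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size, lon0 = lon0, lat0 = lat0),
            class = "zr_grid")
}

#' @export
print.zr_grid <- function(x, ...) {
  cat(sprintf("<zr_grid> %d x %d cells of %g m; origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$xmin, x$ymin))
  invisible(x)
}

grid_equal <- function(a, b) {
  isTRUE(all.equal(a[c("xmin", "ymin", "n_rows", "n_cols", "cell_size")],
                   b[c("xmin", "ymin", "n_rows", "n_cols", "cell_size")]))
}

cell_area_m2 <- function(grid) grid$cell_size^2

#' Cell centre coordinates
#'
#' @param grid a \code{zr_grid}.
#' @return list with \code{x} (length \code{n_cols}, west to east) and
#'   \code{y} (length \code{n_rows}, north to south, matching row order).
#' @keywords internal
cell_centers <- function(grid) {
  cs <- grid$cell_size
  list(x = grid$xmin + (seq_len(grid$n_cols) - 0.5) * cs,
       y = grid$ymin + (grid$n_rows - seq_len(grid$n_rows) + 0.5) * cs)
}

#' Row/column index of points on a grid
#'
#' Points outside the extent get NA indices.  Cells are half-open, so a
#' point exactly on the eastern or northern edge is outside.
#'
#' @param grid a \code{zr_grid}; \code{x,y} numeric vectors.
#' @return list of integer vectors \code{row}, \code{col}.
#' @keywords internal
cell_index <- function(grid, x, y) {
  cs <- grid$cell_size
  col <- floor((x - grid$xmin) / cs) + 1L
  row <- grid$n_rows - floor((y - grid$ymin) / cs)
  bad <- col < 1L | col > grid$n_cols | row < 1L | row > grid$n_rows |
    !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at point locations
#'
#' @param r numeric matrix on \code{grid}.
#' @param grid a \code{zr_grid}.
#' @param x,y point coordinates (metres).
#' @return numeric vector; NA for points off the grid.
#' @export
raster_values <- function(r, grid, x, y) {
  idx <- cell_index(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$row)
  out[ok] <- r[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Convert projected coordinates to longitude/latitude
#'
#' Local equirectangular inverse about the grid's geographic anchor.
#'
#' @inheritParams raster_values
#' @return data.frame with columns \code{lon}, \code{lat} (degrees).
#' @export
grid_to_lonlat <- function(grid, x, y) {
  m_per_deg_lat <- 111132.0
  m_per_deg_lon <- 111320.0 * cos(grid$lat0 * pi / 180)
  data.frame(lon = grid$lon0 + (x - grid$xmin) / m_per_deg_lon,
             lat = grid$lat0 + (y - grid$ymin) / m_per_deg_lat)
}

#' Write / read a raster as ESRI ASCII grid
#'
#' Plain-text raster interchange; one file per layer.  Orientation matches
#' the in-memory convention (first data row is the northernmost).
#'
#' @param r numeric matrix on \code{grid}.
#' @param grid a \code{zr_grid}.
#' @param path output file path (conventionally \code{.asc}).
#' @export
write_ascii_grid <- function(r, grid, path) {
  stopifnot(nrow(r) == grid$n_rows, ncol(r) == grid$n_cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$n_cols),
               sprintf("nrows %d", grid$n_rows),
               sprintf("xllcorner %.10g", grid$xmin),
               sprintf("yllcorner %.10g", grid$ymin),
               sprintf("cellsize %.10g", grid$cell_size),
               "NODATA_value -9999"), con)
  rr <- r
  rr[is.na(rr)] <- -9999
  write.table(format(rr, trim = TRUE, digits = 10), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @return \code{read_ascii_grid}: list with \code{grid} and matrix
#'   \code{values}.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- as.numeric(kv[, 2])
  names(h) <- tolower(kv[, 1])
  vals <- scan(path, skip = 6L, quiet = TRUE)
  m <- matrix(vals, nrow = h[["nrows"]], ncol = h[["ncols"]], byrow = TRUE)
  m[m == h[["nodata_value"]]] <- NA_real_
  list(grid = make_grid(h[["xllcorner"]], h[["yllcorner"]],
                        h[["nrows"]], h[["ncols"]], h[["cellsize"]]),
       values = m)
}

#' Write zone polygons as GeoJSON
#'
#' @param zones list of zones, each \code{list(name, coords)} where
#'   \code{coords} is a closed two-column matrix of ring vertices in
#'   projected metres.
#' @param path output path.
#' @export
write_zones_geojson <- function(zones, path) {
  feats <- lapply(zones, function(z) {
    ring <- lapply(seq_len(nrow(z$coords)), function(i) unname(z$coords[i, ]))
    list(type = "Feature",
         properties = list(name = z$name),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_zones_geojson
#' @export
read_zones_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    coords <- do.call(rbind, lapply(ring, function(p) unlist(p)))
    list(name = f$properties$name, coords = coords)
  })
}
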