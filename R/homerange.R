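#' Fit a Weibull step-speed model
#'
#' Step speeds (metres/second) are distances between consecutive fixes
#' divided by the elapsed time.  A Weibull distribution is fitted by
#' maximum likelihood (\code{MASS::fitdistr}); \code{vmax} is set to 1.05
#' times the fastest observed step so every observed step retains positive
#' density in the elliptical time-density construction.
#'
#' @param traj a \code{trajectory} (fixes ordered, timestamps strictly
#'   increasing).
#' @return object of class \code{"speed_model"}: \code{shape},
#'   \code{scale} (m/s), \code{vmax} (m/s), \code{n_steps}.
#' @export
fit_speed_model <- function(traj) {
  f <- traj$fixes
  if (nrow(f) < 2L) stop("degenerate-speed error: fewer than 2 fixes")
  dt <- diff(as.numeric(f$timestamp))
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  v <- sqrt(diff(f$x)^2 + diff(f$y)^2) / dt
  v <- v[v > 0]
  if (length(v) < 10L) stop("degenerate-speed error: fewer than 10 positive-speed steps")
  if (sd(v) / mean(v) < 1e-8) {
    # point-mass limit: all steps at the same speed
    sm <- list(shape = 1e3, scale = mean(v), vmax = 1.05 * max(v),
               n_steps = length(v))
  } else {
    # fit on mean-normalized speeds (shape is scale-invariant) for a
    # well-conditioned optimization, then rescale
    v0 <- mean(v)
    fit <- MASS::fitdistr(v / v0, "weibull", lower = c(1e-6, 1e-9))
    sm <- list(shape = unname(fit$estimate["shape"]),
               scale = unname(fit$estimate["scale"]) * v0,
               vmax = 1.05 * max(v), n_steps = length(v))
  }
  structure(sm, class = "speed_model")
}

#' @export
print.speed_model <- function(x, ...) {
  cat(sprintf("<speed_model> Weibull(shape=%.3g, scale=%.3g m/s), vmax=%.3g m/s (%d steps)\n",
              x$shape, x$scale, x$vmax, x$n_steps))
  invisible(x)
}

#' Elliptical time-density surface
#'
#' For every consecutive pair of fixes (p1, t1), (p2, t2) and every cell
#' centre c, the speed required to pass through c in the available time is
#' \code{v(c) = (|p1 - c| + |c - p2|) / (t2 - t1)}.  The cell gets the
#' Weibull density of that speed, zero beyond \code{vmax} (so each step's
#' support is the ellipse with foci p1, p2 and major axis vmax * dt).
#' Per-step weights are normalized to the step duration, summed over
#' steps, and the surface is normalized to integrate to 1 over the grid.
#'
#' @param traj a \code{trajectory}; all fixes must fall inside the grid.
#' @param grid a \code{\link{make_grid}} grid.
#' @param speed a \code{\link{fit_speed_model}} result.
#' @return object of class \code{"etd_raster"}: \code{grid} plus
#'   \code{density} (matrix, units 1/m^2).
#' @export
etd_density <- function(traj, grid, speed) {
  f <- traj$fixes
  idx <- cell_index(grid, f$x, f$y)
  if (anyNA(idx$row)) stop("extent error: fix outside grid")
  cc <- cell_centers(grid)
  dens <- matrix(0, grid$n_rows, grid$n_cols)
  tt <- as.numeric(f$timestamp)
  cs <- grid$cell_size
  for (i in seq_len(nrow(f) - 1L)) {
    dt <- tt[i + 1L] - tt[i]
    p1 <- c(f$x[i], f$y[i]); p2 <- c(f$x[i + 1L], f$y[i + 1L])
    a <- speed$vmax * dt / 2          # ellipse semi-major axis
    ctr <- (p1 + p2) / 2
    colr <- which(cc$x >= ctr[1] - a - cs & cc$x <= ctr[1] + a + cs)
    rowr <- which(cc$y >= ctr[2] - a - cs & cc$y <= ctr[2] + a + cs)
    if (!length(colr) || !length(rowr)) next
    xg <- matrix(cc$x[colr], length(rowr), length(colr), byrow = TRUE)
    yg <- matrix(cc$y[rowr], length(rowr), length(colr))
    v <- (sqrt((xg - p1[1])^2 + (yg - p1[2])^2) +
          sqrt((xg - p2[1])^2 + (yg - p2[2])^2)) / dt
    w <- dweibull(v, speed$shape, speed$scale)
    w[v > speed$vmax] <- 0
    s <- sum(w)
    if (s > 0) dens[rowr, colr] <- dens[rowr, colr] + w * (dt / s)
  }
  tot <- sum(dens) * cell_area_m2(grid)
  if (tot <= 0) stop("empty-input error: zero total density")
  structure(list(grid = grid, density = dens / tot), class = "etd_raster")
}

#' @export
print.etd_raster <- function(x, ...) {
  cat(sprintf("<etd_raster> %d x %d, %d cells with positive density\n",
              x$grid$n_rows, x$grid$n_cols, sum(x$density > 0)))
  invisible(x)
}

new_homerange <- function(grid, cells, percentile) {
  structure(list(grid = grid, cells = sort(as.integer(cells)),
                 percentile = percentile,
                 area_km2 = length(cells) * cell_area_m2(grid) / 1e6),
            class = "homerange")
}

#' Percentile home range from an ETD surface
#'
#' The smallest set of highest-density cells whose cumulative probability
#' mass reaches the requested percentile; cells tied with the last
#' included density are all included.  The 100th percentile is the full
#' positive support.
#'
#' @param etd an \code{\link{etd_density}} result.
#' @param percentile fraction in (0, 1].
#' @return object of class \code{"homerange"}: \code{grid}, integer cell
#'   indices \code{cells}, \code{percentile}, \code{area_km2}.
#' @export
percentile_homerange <- function(etd, percentile = 1) {
  stopifnot(percentile > 0, percentile <= 1)
  p <- as.vector(etd$density) * cell_area_m2(etd$grid)
  if (all(p == 0)) stop("empty-input error: empty density")
  o <- order(p, decreasing = TRUE)
  cum <- cumsum(p[o])
  k <- which(cum >= percentile - 1e-12)[1]
  if (is.na(k)) k <- sum(p > 0)
  thr <- p[o[k]]
  cells <- which(p >= thr & p > 0)
  new_homerange(etd$grid, cells, percentile)
}

#' @export
print.homerange <- function(x, ...) {
  cat(sprintf("<homerange> %.0fth percentile: %d cells, %.2f km^2\n",
              100 * x$percentile, length(x$cells), x$area_km2))
  invisible(x)
}

#' Overlap metrics between two home ranges
#'
#' Reports both areas, the Jaccard overlap |A n B| / |A u B|, and the two
#' directed fractions |A n B|/|A| and |A n B|/|B| plus their mean (the
#' headline overlap figure, since "percent overlap" between two seasonal
#' ranges is denominator-ambiguous).
#'
#' @param hr_a,hr_b \code{homerange} objects on the same grid.
#' @return named list of metrics.
#' @export
range_metrics <- function(hr_a, hr_b) {
  if (!grid_equal(hr_a$grid, hr_b$grid)) stop("grid error: mismatched grids")
  inter <- length(intersect(hr_a$cells, hr_b$cells))
  uni <- length(union(hr_a$cells, hr_b$cells))
  fa <- inter / length(hr_a$cells)
  fb <- inter / length(hr_b$cells)
  list(area_a_km2 = hr_a$area_km2, area_b_km2 = hr_b$area_km2,
       overlap_fraction = if (uni > 0) inter / uni else NA_real_,
       overlap_of_a = fa, overlap_of_b = fb,
       overlap_directed_mean = mean(c(fa, fb)))
}

#' Export a home range as a GeoJSON MultiPolygon of its cells
#' @param hr a \code{homerange}; \code{path} output path.
#' @param path output file.
#' @export
write_homerange_geojson <- function(hr, path) {
  g <- hr$grid; cs <- g$cell_size
  rw <- (hr$cells - 1L) %% g$n_rows + 1L
  cl <- (hr$cells - 1L) %/% g$n_rows + 1L
  x0 <- g$xmin + (cl - 1L) * cs
  y0 <- g$ymin + (g$n_rows - rw) * cs
  polys <- lapply(seq_along(hr$cells), function(i) {
    list(list(c(x0[i], y0[i]), c(x0[i] + cs, y0[i]),
              c(x0[i] + cs, y0[i] + cs), c(x0[i], y0[i] + cs),
              c(x0[i], y0[i])))
  })
  jsonlite::write_json(
    list(type = "Feature",
         properties = list(percentile = hr$percentile,
                           area_km2 = hr$area_km2),
         geometry = list(type = "MultiPolygon", coordinates = polys)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
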