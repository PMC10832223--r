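#' Draw available (unused) points within a home range
#'
#' The use-available design: for every used GPS fix, \code{ratio} random
#' unused locations are drawn uniformly over the individual's home-range
#' area (a cell is chosen area-weighted -- cells are equal-area, so
#' uniformly -- and the position is uniform within the cell).  Each
#' available point receives an independent random timestamp uniform
#' between the individual's first and last fix, so its NDVI, season and
#' day/night attributes reflect a random time, not the paired fix's time.
#'
#' @param traj a \code{trajectory} (supplies the used count and the time
#'   span).
#' @param hr the individual's \code{homerange} (availability domain).
#' @param ratio available points per used fix (default 10).
#' @param seed optional integer seed.
#' @return data.frame of available observations: \code{individual_id},
#'   \code{used} (0), \code{timestamp}, \code{x}, \code{y}.
#' @export
draw_available <- function(traj, hr, ratio = 10L, seed = NULL) {
  if (length(hr$cells) == 0L) stop("empty-domain error: empty home range")
  stopifnot(ratio >= 1L)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(traj$fixes) * as.integer(ratio)
  g <- hr$grid; cs <- g$cell_size
  cells <- hr$cells[sample.int(length(hr$cells), n, replace = TRUE)]
  rw <- (cells - 1L) %% g$n_rows + 1L
  cl <- (cells - 1L) %/% g$n_rows + 1L
  x <- g$xmin + (cl - 1L + runif(n)) * cs
  y <- g$ymin + (g$n_rows - rw + runif(n)) * cs
  t0 <- as.numeric(min(traj$fixes$timestamp))
  t1 <- as.numeric(max(traj$fixes$timestamp))
  ts <- as.POSIXct(runif(n, t0, t1), origin = "1970-01-01", tz = "UTC")
  data.frame(individual_id = traj$individual_id, used = 0L,
             timestamp = ts, x = x, y = y)
}

#' Build the combined used + available observation table
#'
#' @inheritParams draw_available
#' @return data.frame with the used fixes (\code{used = 1}) followed by
#'   the available sample (\code{used = 0}), plus a \code{sex} column.
#' @export
build_observations <- function(traj, hr, ratio = 10L, seed = NULL) {
  used <- data.frame(individual_id = traj$individual_id, used = 1L,
                     timestamp = traj$fixes$timestamp,
                     x = traj$fixes$x, y = traj$fixes$y)
  out <- rbind(used, draw_available(traj, hr, ratio = ratio, seed = seed))
  out$sex <- if (is.null(traj$sex)) NA_character_ else traj$sex
  out
}

#' Assign management-zone labels by point-in-polygon test
#'
#' Each observation gets the name of the (non-overlapping) zone polygon
#' containing it; points outside every polygon are labelled
#' \code{"outside"} (a valid label -- such points are excluded later when
#' zonal model subsets are formed, mirroring the retention of only data
#' that intersect the covariate extent).
#'
#' @param obs observation data.frame with \code{x}, \code{y}.
#' @param zones list of zones (\code{list(name, coords)}).
#' @return \code{obs} with a \code{zone} column.
#' @export
assign_zone <- function(obs, zones) {
  zone <- rep("outside", nrow(obs))
  pts <- cbind(obs$x, obs$y)
  for (z in zones) {
    unassigned <- zone == "outside"
    if (!any(unassigned)) break
    inside <- mgcv::in.out(z$coords, pts[unassigned, , drop = FALSE])
    zone[unassigned][inside] <- z$name
  }
  obs$zone <- zone
  obs
}
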