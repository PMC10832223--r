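#' Annotate observations with static raster covariates
#'
#' Each observation receives the value of every named layer at its
#' containing cell.  Observations falling off the grid are dropped with a
#' message reporting the count (no imputation).
#'
#' @param obs observation data.frame with \code{x}, \code{y}.
#' @param landscape a \code{landscape} (or any list with \code{grid} and
#'   \code{static_layers}).
#' @param layer_names which static layers to attach (default: all).
#' @return annotated data.frame.
#' @export
annotate_raster <- function(obs, landscape,
                            layer_names = names(landscape$static_layers)) {
  idx <- cell_index(landscape$grid, obs$x, obs$y)
  off <- is.na(idx$row)
  if (any(off)) {
    message(sum(off), " observation(s) off the covariate grid dropped")
    obs <- obs[!off, , drop = FALSE]
    idx <- list(row = idx$row[!off], col = idx$col[!off])
  }
  for (nm in layer_names)
    obs[[nm]] <- landscape$static_layers[[nm]][cbind(idx$row, idx$col)]
  obs
}

# index of the date nearest each timestamp; ties go to the earlier layer
nearest_date_index <- function(dates, timestamps) {
  dsec <- as.numeric(as.POSIXct(paste(dates, "00:00:00"), tz = "UTC"))
  ts <- as.numeric(timestamps)
  i <- findInterval(ts, dsec)
  i0 <- pmax(i, 1L)
  i1 <- pmin(i + 1L, length(dsec))
  d0 <- abs(ts - dsec[i0])
  d1 <- abs(ts - dsec[i1])
  ifelse(i < 1L, 1L, ifelse(d0 <= d1, i0, i1))  # <= : tie -> earlier
}

#' Annotate observations with the nearest-in-time NDVI value
#'
#' Each observation gets the NDVI of its cell from the dated layer whose
#' date is closest to the observation timestamp; exact midpoints resolve
#' to the earlier layer.
#'
#' @param obs observation data.frame with \code{timestamp}, \code{x},
#'   \code{y}.
#' @param landscape a \code{landscape} with \code{ndvi_dates} /
#'   \code{ndvi_layers}.
#' @return \code{obs} with an \code{ndvi} column (and hidden layer index
#'   \code{.ndvi_layer} used for season joining).
#' @export
annotate_ndvi <- function(obs, landscape) {
  if (length(landscape$ndvi_dates) < 1L) stop("no NDVI layers")
  li <- nearest_date_index(landscape$ndvi_dates, obs$timestamp)
  idx <- cell_index(landscape$grid, obs$x, obs$y)
  nd <- rep(NA_real_, nrow(obs))
  for (l in unique(li)) {
    sel <- li == l & !is.na(idx$row)
    nd[sel] <- landscape$ndvi_layers[[l]][cbind(idx$row[sel], idx$col[sel])]
  }
  obs$ndvi <- nd
  obs$.ndvi_layer <- li
  obs
}

#' Classify composite dates into wet and dry seasons
#'
#' A two-component one-dimensional Gaussian mixture is fitted by EM
#' (\pkg{mclust}) to the scene-mean NDVI of each composite date; each date
#' is labelled by maximum posterior responsibility and the higher-mean
#' component is always labelled \code{wet}.  Degenerate fits are retried
#' with jittered values up to 10 times.
#'
#' @param dates Date vector (>= 4 values).
#' @param mean_ndvi scene-mean NDVI per date.
#' @return object of class \code{"season_model"}: component \code{means},
#'   \code{sds}, \code{weights}, and \code{labels} (factor wet/dry per
#'   date) plus the input \code{dates}.
#' @export
classify_seasons <- function(dates, mean_ndvi) {
  stopifnot(length(dates) == length(mean_ndvi))
  if (length(dates) < 4L) stop("need >= 4 dates to classify seasons")
  if (sd(mean_ndvi) < 1e-12)
    stop("degenerate-EM error: all NDVI values identical")
  v <- mean_ndvi
  fit <- NULL
  for (attempt in 0:10) {
    x <- if (attempt == 0) v else v + rnorm(length(v), 0, sd(v) * 1e-3)
    mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
    fit <- tryCatch(
      suppressWarnings(mclust::Mclust(x, G = 2, modelNames = c("E", "V"),
                                      verbose = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit) && !anyNA(fit$parameters$mean)) break
  }
  if (is.null(fit)) stop("degenerate-EM error: mixture fit failed after 10 restarts")
  mu <- fit$parameters$mean
  wet_comp <- which.max(mu)
  labels <- factor(ifelse(fit$classification == wet_comp, "wet", "dry"),
                   levels = c("dry", "wet"))
  sds <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sds) == 1L) sds <- rep(sds, 2L)
  structure(list(means = c(dry = unname(min(mu)), wet = unname(max(mu))),
                 sds = setNames(sds[order(mu)], c("dry", "wet")),
                 weights = setNames(fit$parameters$pro[order(mu)],
                                    c("dry", "wet")),
                 labels = labels, dates = dates),
            class = "season_model")
}

#' @export
print.season_model <- function(x, ...) {
  cat(sprintf("<season_model> dry: N(%.3f, %.3f), wet: N(%.3f, %.3f); %d/%d wet dates\n",
              x$means["dry"], x$sds["dry"], x$means["wet"], x$sds["wet"],
              sum(x$labels == "wet"), length(x$labels)))
  invisible(x)
}

#' Attach season labels to observations
#'
#' Seasons are assigned per 16-day composite period: each observation
#' inherits the wet/dry label of its nearest-in-time NDVI date.
#' Requires \code{annotate_ndvi} to have run (uses its layer index).
#'
#' @param obs annotated observations (with \code{.ndvi_layer}).
#' @param season a \code{\link{classify_seasons}} result on the same date
#'   series.
#' @return \code{obs} with a \code{season} column.
#' @export
annotate_season <- function(obs, season) {
  li <- obs$.ndvi_layer
  if (is.null(li)) stop("run annotate_ndvi before annotate_season")
  obs$season <- as.character(season$labels[li])
  obs
}

#' Solar elevation (NOAA approximation)
#'
#' Fractional-year solar position: equation of time and declination from
#' low-order trigonometric series, then elevation from the local hour
#' angle.  Accuracy is a small fraction of a degree -- ample for
#' geometric day/night labelling of hourly fixes.
#'
#' @param timestamp POSIXct (UTC).
#' @param lon,lat degrees.
#' @return solar elevation in degrees.
#' @export
solar_elevation <- function(timestamp, lon, lat) {
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  doy <- lt$yday
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  g <- 2 * pi / 365 * (doy + (hour - 12) / 24)   # fractional year (rad)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g)
                      - 0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  tst <- hour * 60 + eqtime + 4 * lon              # true solar time (min)
  ha <- (tst / 4 - 180) * pi / 180                 # hour angle (rad)
  latr <- lat * pi / 180
  sin_el <- sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha)
  asin(pmin(1, pmax(-1, sin_el))) * 180 / pi
}

#' Day/night label for timestamps at a location
#'
#' \code{"day"} iff the solar elevation exceeds 0 degrees (geometric
#' sunrise/sunset, refraction ignored).  Works at any latitude; polar day
#' and night fall out of the elevation sign.
#'
#' @inheritParams solar_elevation
#' @return character vector \code{"day"}/\code{"night"}.
#' @export
day_night <- function(timestamp, lon, lat) {
  ifelse(solar_elevation(timestamp, lon, lat) > 0, "day", "night")
}

#' Full covariate + stratum annotation
#'
#' Convenience wrapper: static rasters, nearest-in-time NDVI, season
#' label, day/night label (via the grid's geographic anchor), and removal
#' of observations with any missing covariate (counts reported by
#' message) so no missing values reach the model stage.
#'
#' @param obs observation table (from \code{\link{build_observations}} /
#'   \code{\link{assign_zone}}).
#' @param landscape the covariate \code{landscape}.
#' @param season optional \code{season_model}; fitted from the landscape's
#'   scene-mean NDVI series when NULL.
#' @return annotated, complete-case observation table (attribute
#'   \code{"season_model"} carries the mixture used).
#' @export
annotate_observations <- function(obs, landscape, season = NULL) {
  obs <- annotate_raster(obs, landscape)
  obs <- annotate_ndvi(obs, landscape)
  if (is.null(season)) {
    scene_mean <- vapply(landscape$ndvi_layers, mean, numeric(1))
    season <- classify_seasons(landscape$ndvi_dates, scene_mean)
  }
  obs <- annotate_season(obs, season)
  ll <- grid_to_lonlat(landscape$grid, obs$x, obs$y)
  obs$tod <- day_night(obs$timestamp, ll$lon, ll$lat)
  obs$.ndvi_layer <- NULL
  cc <- complete.cases(obs)
  if (any(!cc)) {
    message(sum(!cc), " observation(s) with incomplete covariates dropped")
    obs <- obs[cc, , drop = FALSE]
  }
  attr(obs, "season_model") <- season
  obs
}
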