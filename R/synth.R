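#' Configuration for the synthetic landscape and track generator
#'
#' The generator emulates a savanna study system split into contiguous
#' land-management zones: a protected reserve, community conservancies and
#' unprotected land.  Individuals select habitat within a circular home
#' range according to an exponential resource selection function whose
#' individual-level coefficients are drawn from group-level Gaussians,
#' so every downstream stage (home ranges, use-available sampling,
#' annotation, hierarchical fitting, consistency scoring) can be tested
#' against known truth.
#'
#' @param extent numeric length-2, width and height of the landscape in
#'   metres.
#' @param cell_size raster cell size in metres (default 250, the home-range
#'   analysis resolution).
#' @param n_zones number of vertical management-zone strips tiling the
#'   extent (default 3: \code{mara_reserve}, \code{conservancies},
#'   \code{unprotected}).
#' @param n_individuals number of simulated animals.
#' @param fixes_per_individual GPS fixes per animal.
#' @param fix_interval seconds between fixes (default 3600: hourly).
#' @param group_means named numeric vector of group-level mean selection
#'   coefficients, one per covariate the generator knows
#'   (\code{slope}, \code{drains}, \code{ndvi}, \code{cover_lt20},
#'   \code{cover_20_70}, \code{cover_gt70}, \code{bare}, \code{roads},
#'   \code{lodges}, \code{settlements}, \code{agriculture}).  Continuous
#'   covariates (slope, ndvi) enter the simulation intensity on their
#'   standardized scale.
#' @param group_sds named numeric vector of group-level standard
#'   deviations (recycled if length 1).
#' @param zone_group_means optional named list \code{zone -> named numeric}
#'   overriding \code{group_means} zone by zone, to simulate selection
#'   behaviour that differs across management zones.  Individual deviations
#'   from the group mean are shared across zones.
#' @param ndvi_season_amplitude amplitude (NDVI units) of the bimodal
#'   seasonal NDVI cycle (two wet peaks per year).
#' @param ndvi_noise_sd standard deviation (NDVI units) of the spatially
#'   autocorrelated per-composite NDVI field.
#' @param hr_radius home-range disc radius in metres.
#' @param start_date POSIXct/char, timestamp of the first fix (UTC).
#' @param seed integer seed; all generator randomness is a deterministic
#'   function of it.
#' @return object of class \code{"synth_config"}.
#' @export
synth_config <- function(extent = c(30000, 30000),
                         cell_size = 250,
                         n_zones = 3L,
                         n_individuals = 10L,
                         fixes_per_individual = 9000L,
                         fix_interval = 3600,
                         group_means = c(slope = -0.2, drains = 0.55,
                                         ndvi = 0.1, cover_lt20 = -0.9,
                                         cover_20_70 = 0.6, cover_gt70 = 1.5,
                                         bare = 0.3, roads = -0.15,
                                         lodges = 0.1, settlements = -0.7,
                                         agriculture = -0.15),
                         group_sds = 0.3,
                         zone_group_means = NULL,
                         ndvi_season_amplitude = 0.15,
                         ndvi_noise_sd = 0.05,
                         hr_radius = 6000,
                         start_date = "2022-01-01 00:00:00",
                         seed = 1L) {
  if (length(group_sds) == 1L && is.null(names(group_sds)))
    group_sds <- setNames(rep(group_sds, length(group_means)),
                          names(group_means))
  cfg <- list(extent = extent, cell_size = cell_size,
              n_zones = as.integer(n_zones),
              n_individuals = as.integer(n_individuals),
              fixes_per_individual = as.integer(fixes_per_individual),
              fix_interval = fix_interval,
              group_means = group_means, group_sds = group_sds,
              zone_group_means = zone_group_means,
              ndvi_season_amplitude = ndvi_season_amplitude,
              ndvi_noise_sd = ndvi_noise_sd,
              hr_radius = hr_radius,
              start_date = as.POSIXct(start_date, tz = "UTC"),
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$cell_size <= 0) stop("invalid config: cell_size must be > 0")
  if (any(cfg$extent < 3 * cfg$cell_size))
    stop("invalid config: extent smaller than 3x3 cells")
  if (cfg$n_zones < 1L) stop("invalid config: n_zones must be >= 1")
  if (cfg$fixes_per_individual < 2L)
    stop("invalid config: fixes_per_individual must be >= 2")
  if (any(cfg$group_sds < 0)) stop("invalid config: group_sds must be >= 0")
  if (!all(names(cfg$group_sds) == names(cfg$group_means)))
    stop("invalid config: group_sds names must match group_means")
  invisible(cfg)
}

zone_names_default <- c("mara_reserve", "conservancies", "unprotected")

#' Smoothed Gaussian random field on a grid
#'
#' White noise convolved with a separable isotropic Gaussian kernel
#' (bandwidth in cells), then rescaled to zero mean and unit variance.
#' @keywords internal
smooth_field <- function(n_rows, n_cols, bandwidth = 5) {
  pad <- ceiling(3 * bandwidth)
  k <- dnorm(seq(-pad, pad), sd = bandwidth)
  k <- k / sum(k)
  z <- matrix(rnorm((n_rows + 2 * pad) * (n_cols + 2 * pad)),
              n_rows + 2 * pad, n_cols + 2 * pad)
  z <- apply(z, 2, function(col) stats::filter(col, k, sides = 2))
  z <- t(apply(z, 1, function(row) stats::filter(row, k, sides = 2)))
  z <- z[pad + seq_len(n_rows), pad + seq_len(n_cols)]
  (z - mean(z)) / sd(z)
}

# distance from each grid cell centre to the nearest point of a polyline
polyline_distance <- function(grid, pts) {
  cc <- cell_centers(grid)
  px <- rep(cc$x, each = grid$n_rows)
  py <- rep(cc$y, times = grid$n_cols)
  dmin <- rep(Inf, length(px))
  for (i in seq_len(nrow(pts) - 1L)) {
    ax <- pts[i, 1]; ay <- pts[i, 2]
    bx <- pts[i + 1L, 1]; by <- pts[i + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    d <- sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
    dmin <- pmin(dmin, d)
  }
  matrix(dmin, grid$n_rows, grid$n_cols)
}

random_polyline <- function(extent, n_pts = 12, vertical = TRUE) {
  if (vertical) {
    x0 <- runif(1, 0.1, 0.9) * extent[1]
    y <- seq(0, extent[2], length.out = n_pts)
    x <- x0 + cumsum(c(0, rnorm(n_pts - 1L, 0, extent[1] / 25)))
  } else {
    y0 <- runif(1, 0.1, 0.9) * extent[2]
    x <- seq(0, extent[1], length.out = n_pts)
    y <- y0 + cumsum(c(0, rnorm(n_pts - 1L, 0, extent[2] / 25)))
  }
  cbind(x, y)
}

# n points spread over the rectangle [lo, hi] on a jittered lattice:
# spatially balanced, so subregions get close to their areal share
jittered_lattice <- function(n, lo, hi) {
  w <- hi[1] - lo[1]; h <- hi[2] - lo[2]
  ncol <- max(1L, round(sqrt(n * w / h)))
  nrow <- max(1L, ceiling(n / ncol))
  gx <- (rep(seq_len(ncol), times = nrow) - runif(nrow * ncol)) * (w / ncol)
  gy <- (rep(seq_len(nrow), each = ncol) - runif(nrow * ncol)) * (h / nrow)
  idx <- sample.int(nrow * ncol, n)
  cbind(lo[1] + gx[idx], lo[2] + gy[idx])
}

point_buffer_raster <- function(grid, pts, radius) {
  cc <- cell_centers(grid)
  px <- rep(cc$x, each = grid$n_rows)
  py <- rep(cc$y, times = grid$n_cols)
  m <- matrix(0, grid$n_rows, grid$n_cols)
  for (i in seq_len(nrow(pts)))
    m[sqrt((px - pts[i, 1])^2 + (py - pts[i, 2])^2) <= radius] <- 1
  m
}

#' Generate a synthetic landscape
#'
#' Builds an aligned raster stack on the configured grid: continuous slope,
#' mutually exclusive one-hot canopy-cover classes (<20\%, 20-70\%, >70\%,
#' bare, agriculture), 400 m buffered presence layers for drains, roads,
#' settlements and lodges, a 16-day series of spatially autocorrelated NDVI
#' layers with a bimodal seasonal mean, and vertical zone polygons tiling
#' the extent.  Deterministic under \code{config$seed}.
#'
#' Cover-class areal fractions target the study system's composition
#' (roughly 30\% open grassland, 47\% open woodland, 10\% closed canopy,
#' 2\% bare); agriculture occurs only in the unprotected zone.
#'
#' @param config a \code{\link{synth_config}}.
#' @return object of class \code{"landscape"}: list with \code{grid},
#'   \code{static_layers} (named list of matrices), \code{ndvi_dates}
#'   (Date vector), \code{ndvi_layers} (list of matrices), \code{zones}.
#' @export
generate_landscape <- function(config) {
  validate_synth_config(config)
  set.seed(config$seed)
  nr <- as.integer(floor(config$extent[2] / config$cell_size))
  nc <- as.integer(floor(config$extent[1] / config$cell_size))
  if (nr < 3L || nc < 3L) stop("invalid config: extent smaller than 3x3 cells")
  grid <- make_grid(0, 0, nr, nc, config$cell_size)

  slope <- 8 + 6 * smooth_field(nr, nc)
  slope[slope < 0] <- 0

  # zones: vertical strips, west to east
  zw <- config$extent[1] / config$n_zones
  znames <- if (config$n_zones <= 3L) zone_names_default[seq_len(config$n_zones)]
            else c(zone_names_default, paste0("zone", 4:config$n_zones))
  zones <- lapply(seq_len(config$n_zones), function(i) {
    x0 <- (i - 1) * zw; x1 <- i * zw
    list(name = znames[i],
         coords = cbind(c(x0, x1, x1, x0, x0),
                        c(0, 0, config$extent[2], config$extent[2], 0)))
  })
  cc <- cell_centers(grid)
  zone_of_cell <- matrix(pmin(config$n_zones,
                              floor(rep(cc$x, each = nr) / zw) + 1L), nr, nc)

  # canopy cover one-hot classes from a thresholded autocorrelated field;
  # a ~10% unclassified background remains (all one-hots zero), as in real
  # classified maps, which also keeps intercept + class dummies identified.
  # two correlation scales: broad structure plus fine-grained mosaic, so
  # every class occurs in every zone rather than as one large patch
  veg <- sqrt(0.6) * smooth_field(nr, nc) + sqrt(0.4) * smooth_field(nr, nc, 1.5)
  qs <- quantile(veg, cumsum(c(0.05, 0.28, 0.05, 0.45, 0.05)))
  bare <- (veg < qs[1]) * 1
  cover_lt20 <- (veg >= qs[1] & veg < qs[2]) * 1
  cover_20_70 <- (veg >= qs[3] & veg < qs[4]) * 1
  cover_gt70 <- (veg >= qs[5]) * 1
  agriculture <- matrix(0, nr, nc)
  if (any(znames == "unprotected")) {
    ag_field <- smooth_field(nr, nc)
    in_up <- zone_of_cell == which(znames == "unprotected")
    ag <- in_up & ag_field > quantile(ag_field[in_up], 0.7)
    agriculture[ag] <- 1
    bare[ag] <- 0; cover_lt20[ag] <- 0; cover_20_70[ag] <- 0; cover_gt70[ag] <- 0
  }

  buf <- 400
  # dendritic drainage stand-in: two lines per orientation, so the
  # network crosses every management-zone strip
  drains <- matrix(0, nr, nc)
  for (i in 1:4)
    drains[polyline_distance(grid, random_polyline(config$extent,
                                                   vertical = i %% 2 == 0)) <= buf] <- 1
  roads <- matrix(0, nr, nc)
  for (i in 1:2)
    roads[polyline_distance(grid, random_polyline(config$extent, n_pts = 6,
                                                  vertical = i == 2)) <= buf] <- 1
  # point features: densities scaled to the extent, placed on a jittered
  # lattice so every zone carries real exposure (lodges are spread through
  # the ecosystem; settlements occur outside the reserve strip only)
  area_km2 <- prod(config$extent) / 1e6
  n_set <- max(10L, round(area_km2 / 10))
  n_lod <- max(10L, round(area_km2 / 12))
  x_min_set <- if (config$n_zones >= 2L) config$extent[1] / config$n_zones else 0
  settle_pts <- jittered_lattice(n_set, c(x_min_set, 0),
                                 c(config$extent[1], config$extent[2]))
  settlements <- point_buffer_raster(grid, settle_pts, buf)
  lodge_pts <- jittered_lattice(n_lod, c(0, 0), config$extent)
  lodges <- point_buffer_raster(grid, lodge_pts, buf)

  # dated NDVI layers: 16-day cadence, two wet peaks per year
  span_s <- (config$fixes_per_individual - 1L) * config$fix_interval
  d0 <- as.Date(config$start_date)
  dates <- seq(d0 - 8, d0 + ceiling(span_s / 86400) + 8, by = 16)
  ndvi_layers <- lapply(dates, function(d) {
    doy <- as.numeric(format(d, "%j"))
    mu <- 0.45 + config$ndvi_season_amplitude * cos(4 * pi * (doy - 90) / 365.25)
    v <- matrix(mu, nr, nc)
    if (config$ndvi_noise_sd > 0)
      v <- v + config$ndvi_noise_sd * smooth_field(nr, nc)
    v[v > 1] <- 1; v[v < -1] <- -1
    v
  })

  structure(list(grid = grid,
                 static_layers = list(slope = slope, drains = drains,
                                      ndvi = NULL,  # time-varying, see ndvi_layers
                                      cover_lt20 = cover_lt20,
                                      cover_20_70 = cover_20_70,
                                      cover_gt70 = cover_gt70, bare = bare,
                                      roads = roads, lodges = lodges,
                                      settlements = settlements,
                                      agriculture = agriculture)[
                                        c("slope", "drains", "cover_lt20",
                                          "cover_20_70", "cover_gt70", "bare",
                                          "roads", "lodges", "settlements",
                                          "agriculture")],
                 ndvi_dates = dates, ndvi_layers = ndvi_layers,
                 zones = zones, zone_of_cell = zone_of_cell,
                 zone_names = znames),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d x %d cells, %d static layers, %d NDVI dates, %d zones\n",
              x$grid$n_rows, x$grid$n_cols, length(x$static_layers),
              length(x$ndvi_dates), length(x$zones)))
  invisible(x)
}

# per-cell covariate design matrix for the generator's intensity.
# continuous covariates enter on the landscape-wide standardized scale so
# the configured coefficients are comparable with the standardized
# coefficients a fit on the sampled data estimates.
landscape_design <- function(landscape, cells) {
  X <- sapply(names(landscape$static_layers),
              function(nm) landscape$static_layers[[nm]][cells])
  sl_all <- landscape$static_layers$slope
  X[, "slope"] <- if (sd(sl_all) > 0)
    (X[, "slope"] - mean(sl_all)) / sd(sl_all) else 0
  X
}

#' Simulate GPS tracks with known selection coefficients
#'
#' For each individual, selection coefficients are drawn from the
#' group-level Gaussians (\code{beta_ik ~ N(mu_k, sigma_k^2)}; with
#' \code{zone_group_means}, the individual deviation is shared across
#' zones and added to each zone's mean).  Fixes are then drawn from an
#' inhomogeneous point process with intensity proportional to
#' \code{exp(beta' x(s, t))} inside a circular home-range disc, by
#' rejection sampling against a uniform proposal; timestamps are regular
#' at \code{fix_interval}.  NDVI enters the intensity standardized, from
#' the layer nearest in time.
#'
#' Disc centres alternate between random interior positions and positions
#' straddling a zone boundary, so that with 3 zones some individuals span
#' two zones and zonal contrasts are estimable.
#'
#' @param config a \code{\link{synth_config}}.
#' @param landscape output of \code{\link{generate_landscape}} on the same
#'   config.
#' @return list of \code{"trajectory"} objects: each has
#'   \code{individual_id}, \code{sex}, \code{fixes} (data.frame
#'   \code{timestamp}, \code{x}, \code{y}) and \code{true_coefficients}
#'   (matrix covariate x zone).
#' @export
simulate_tracks <- function(config, landscape) {
  validate_synth_config(config)
  if (!grid_equal(landscape$grid, landscape$grid))
    stop("landscape not on config grid")
  set.seed(config$seed + 1L)
  grid <- landscape$grid
  covs <- names(config$group_means)
  znames <- landscape$zone_names

  # group means per zone (matrix covariate x zone; built explicitly so a
  # single covariate or single zone keeps matrix shape)
  mu <- matrix(unlist(lapply(znames, function(z) {
    m <- config$group_means
    if (!is.null(config$zone_group_means) &&
        !is.null(config$zone_group_means[[z]])) {
      ov <- config$zone_group_means[[z]]
      m[names(ov)] <- ov
    }
    m
  })), nrow = length(covs),
  dimnames = list(covs, znames))

  cc <- cell_centers(grid)
  px <- rep(cc$x, each = grid$n_rows)
  py <- rep(cc$y, times = grid$n_cols)
  n_bound <- length(znames) - 1L
  nd_all <- unlist(landscape$ndvi_layers)
  nd_mu <- mean(nd_all); nd_sd <- sd(nd_all)
  tracks <- vector("list", config$n_individuals)
  for (i in seq_len(config$n_individuals)) {
    r <- config$hr_radius
    if (n_bound > 0L) {
      # consecutive male/female pairs cycle across the zone boundaries so
      # every zone is visited by individuals of both sexes
      b <- ((i - 1L) %/% 2L) %% n_bound + 1L
      bx <- b * config$extent[1] / length(znames)
      cx <- bx + runif(1, -0.3, 0.3) * r
    } else {
      cx <- runif(1, r, config$extent[1] - r)
    }
    cx <- min(max(cx, r), config$extent[1] - r)
    cy <- runif(1, r, config$extent[2] - r)
    cells <- which(matrix((px - cx)^2 + (py - cy)^2 <= r^2,
                          grid$n_rows, grid$n_cols))
    X <- landscape_design(landscape, cells)
    zone_cell <- landscape$zone_of_cell[cells]

    delta <- rnorm(length(covs), 0, config$group_sds[covs])
    beta <- mu[covs, , drop = FALSE] + delta  # covariate x zone
    dimnames(beta) <- list(covs, znames)

    static_covs <- setdiff(covs, "ndvi")
    eta_static <- vapply(seq_along(cells), function(j) {
      sum(beta[static_covs, zone_cell[j]] * X[j, static_covs])
    }, numeric(1))
    b_ndvi <- if ("ndvi" %in% covs) beta["ndvi", ][zone_cell] else
      rep(0, length(cells))

    ts <- config$start_date +
      (seq_len(config$fixes_per_individual) - 1L) * config$fix_interval
    lidx <- nearest_date_index(landscape$ndvi_dates, ts)
    fix_cell <- integer(config$fixes_per_individual)
    n_prop <- 0L; n_acc <- 0L
    for (l in unique(lidx)) {
      sel <- which(lidx == l)
      nv <- landscape$ndvi_layers[[l]][cells]
      nv <- if (nd_sd > 0) (nv - nd_mu) / nd_sd else nv * 0
      eta <- eta_static + b_ndvi * nv
      w <- exp(eta - max(eta))
      need <- length(sel)
      got <- integer(0)
      while (length(got) < need) {
        m <- max(2L * (need - length(got)), 100L)
        cand <- sample.int(length(cells), m, replace = TRUE)
        acc <- runif(m) < w[cand]
        n_prop <- n_prop + m; n_acc <- n_acc + sum(acc)
        got <- c(got, cand[acc])
        if (n_prop > 1e5 && n_acc / n_prop < 1e-4)
          stop("coefficient magnitude error: rejection acceptance rate below 1e-4")
      }
      fix_cell[sel] <- got[seq_len(need)]
    }
    cells_used <- cells[fix_cell]
    rw <- row(matrix(0, grid$n_rows, grid$n_cols))[cells_used]
    cl <- col(matrix(0, grid$n_rows, grid$n_cols))[cells_used]
    n <- length(cells_used)
    x <- grid$xmin + (cl - 1L + runif(n)) * grid$cell_size
    y <- grid$ymin + (grid$n_rows - rw + runif(n)) * grid$cell_size

    tracks[[i]] <- structure(
      list(individual_id = sprintf("ind%02d", i),
           sex = if (i %% 2L == 0L) "female" else "male",
           fixes = data.frame(timestamp = ts, x = x, y = y),
           true_coefficients = beta,
           hr_center = c(cx, cy), hr_radius = r),
      class = "trajectory")
  }
  tracks
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s (%s): %d fixes, %s to %s\n",
              x$individual_id, x$sex, nrow(x$fixes),
              format(min(x$fixes$timestamp)), format(max(x$fixes$timestamp))))
  invisible(x)
}

#' The availability disc a simulated track was generated on
#'
#' Returns the generator's true availability domain as a
#' \code{\link{percentile_homerange}}-compatible home range (the set of
#' grid cells inside the disc), useful for exact parameter-recovery
#' studies where availability should match the generating process.
#'
#' @param traj a simulated \code{trajectory} (must carry \code{hr_center}).
#' @param grid the landscape grid.
#' @return a \code{"homerange"} object.
#' @export
true_availability <- function(traj, grid) {
  if (is.null(traj$hr_center)) stop("trajectory has no generator disc")
  cc <- cell_centers(grid)
  px <- rep(cc$x, each = grid$n_rows)
  py <- rep(cc$y, times = grid$n_cols)
  cells <- which((px - traj$hr_center[1])^2 + (py - traj$hr_center[2])^2 <=
                   traj$hr_radius^2)
  new_homerange(grid, cells, percentile = 1)
}

#' Write simulated tracks to CSV (+ JSON sidecar of true coefficients)
#'
#' @param tracks list of trajectories.
#' @param path CSV path; the sidecar is written next to it with extension
#'   \code{.json}.
#' @export
write_tracks <- function(tracks, path) {
  df <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(individual_id = tr$individual_id, sex = tr$sex,
               timestamp = format(tr$fixes$timestamp, "%Y-%m-%dT%H:%M:%SZ"),
               x = tr$fixes$x, y = tr$fixes$y)))
  write.csv(df, path, row.names = FALSE)
  truth <- lapply(tracks, function(tr)
    if (is.null(tr$true_coefficients)) NULL else
      as.data.frame(tr$true_coefficients))
  names(truth) <- vapply(tracks, `[[`, "", "individual_id")
  jsonlite::write_json(truth, sub("\\.csv$", ".json", path), digits = NA)
  invisible(path)
}

#' Read tracks from the CSV written by \code{write_tracks}
#' @param path CSV path.
#' @return list of \code{trajectory} objects.
#' @export
read_tracks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$individual_id), function(d) {
    d <- d[order(d$timestamp), ]
    structure(list(individual_id = d$individual_id[1], sex = d$sex[1],
                   fixes = data.frame(
                     timestamp = as.POSIXct(d$timestamp, tz = "UTC",
                                            format = "%Y-%m-%dT%H:%M:%OSZ"),
                     x = d$x, y = d$y),
                   true_coefficients = NULL),
              class = "trajectory")
  })
}

#' Write every landscape layer as an ASCII grid plus zones as GeoJSON
#' @param landscape a landscape.
#' @param dir output directory (created if needed).
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(landscape$static_layers))
    write_ascii_grid(landscape$static_layers[[nm]], landscape$grid,
                     file.path(dir, paste0(nm, ".asc")))
  for (i in seq_along(landscape$ndvi_dates))
    write_ascii_grid(landscape$ndvi_layers[[i]], landscape$grid,
                     file.path(dir, sprintf("ndvi_%s.asc",
                                            format(landscape$ndvi_dates[i]))))
  write_zones_geojson(landscape$zones, file.path(dir, "zones.geojson"))
  invisible(dir)
}
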