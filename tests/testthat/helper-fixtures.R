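# Shared small fixtures, built once per test run.

fixture_cache <- new.env(parent = emptyenv())

# compact landscape + 4 tracks spanning ~3 months of hourly fixes
small_world <- function() {
  if (!is.null(fixture_cache$world)) return(fixture_cache$world)
  cfg <- synth_config(extent = c(12000, 9000), cell_size = 250,
                      n_individuals = 4, fixes_per_individual = 2000,
                      hr_radius = 3000, seed = 7)
  L <- generate_landscape(cfg)
  tracks <- simulate_tracks(cfg, L)
  fixture_cache$world <- list(cfg = cfg, landscape = L, tracks = tracks)
  fixture_cache$world
}

# a short trajectory with hand-set fixes
make_traj <- function(x, y, t_hours, id = "t1", sex = "female") {
  structure(list(individual_id = id, sex = sex,
                 fixes = data.frame(
                   timestamp = as.POSIXct("2022-06-01", tz = "UTC") +
                     t_hours * 3600,
                   x = x, y = y),
                 true_coefficients = NULL),
            class = "trajectory")
}

# random-walk trajectory inside a grid, hourly fixes
walk_traj <- function(n = 60, step = 180, origin = c(2000, 2000), seed = 1) {
  set.seed(seed)
  dx <- cumsum(rnorm(n, 0, step)); dy <- cumsum(rnorm(n, 0, step))
  make_traj(origin[1] + dx - dx[1], origin[2] + dy - dy[1], seq_len(n) - 1)
}

# brute-force ETD surface: direct per-cell evaluation, independent of the
# packaged implementation
etd_brute <- function(traj, grid, speed) {
  cc <- zonersf:::cell_centers(grid)
  f <- traj$fixes
  tt <- as.numeric(f$timestamp)
  dens <- matrix(0, grid$n_rows, grid$n_cols)
  for (s in seq_len(nrow(f) - 1L)) {
    dt <- tt[s + 1] - tt[s]
    w <- matrix(0, grid$n_rows, grid$n_cols)
    for (r in seq_len(grid$n_rows)) for (cl in seq_len(grid$n_cols)) {
      d1 <- sqrt((cc$x[cl] - f$x[s])^2 + (cc$y[r] - f$y[s])^2)
      d2 <- sqrt((cc$x[cl] - f$x[s + 1])^2 + (cc$y[r] - f$y[s + 1])^2)
      v <- (d1 + d2) / dt
      if (v <= speed$vmax) w[r, cl] <- dweibull(v, speed$shape, speed$scale)
    }
    if (sum(w) > 0) dens <- dens + w * dt / sum(w)
  }
  dens / (sum(dens) * grid$cell_size^2)
}

# brute-force consistency: independent double loop over zone pairs and
# levels
consistency_brute <- function(tab, covariates) {
  zones <- unique(tab$zone)
  levels <- unique(tab$level)
  get1 <- function(z, l, k)
    tab$estimate[tab$zone == z & tab$level == l & tab$covariate == k]
  per_cov <- sapply(covariates, function(k) {
    terms <- c()
    for (a in seq_along(zones)) for (b in seq_along(zones)) {
      if (a >= b) next
      for (l in levels)
        terms <- c(terms, abs(get1(zones[a], l, k) - get1(zones[b], l, k)))
    }
    mean(terms)
  })
  list(per_covariate = per_cov, overall = mean(per_cov))
}

# zone-dependent group means for the end-to-end validation contrast:
# every covariate gets a strong monotone gradient across the protection
# gradient, so the true cross-zone differentiation is unambiguous
# relative to the estimation-noise floor at reduced problem sizes
validation_zone_means <- function() {
  list(
    mara_reserve  = c(slope = -1.2, drains = -0.7, ndvi = 1.0,
                      cover_lt20 = 1.0, cover_20_70 = -0.6,
                      cover_gt70 = -0.3, bare = 1.5, roads = 1.1,
                      lodges = -1.3),
    conservancies = c(slope = -0.2, drains = 0.55, ndvi = 0.1,
                      cover_lt20 = -0.9, cover_20_70 = 0.6,
                      cover_gt70 = 1.5, bare = 0.3, roads = -0.15,
                      lodges = 0.1),
    unprotected   = c(slope = 0.8, drains = 1.8, ndvi = -0.8,
                      cover_lt20 = -2.8, cover_20_70 = 1.8,
                      cover_gt70 = 3.0, bare = -0.9, roads = -1.4,
                      lodges = 1.5))
}

# random coefficient table for a strata family
random_coef_table <- function(n_cov = 5, levels = c("l1", "l2"),
                              family = "sex") {
  zones <- c("mara_reserve", "conservancies", "unprotected")
  covs <- paste0("c", seq_len(n_cov))
  g <- expand.grid(zone = zones, level = levels, covariate = covs,
                   stringsAsFactors = FALSE)
  g$family <- family
  g$estimate <- rnorm(nrow(g), 0, 2)
  g
}
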