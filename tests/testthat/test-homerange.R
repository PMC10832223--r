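test_that("speed model recovers known Weibull parameters", {
  set.seed(42)
  n <- 5000
  v <- rweibull(n, shape = 2, scale = 0.1)
  # build a track whose consecutive step speeds are exactly v (1 h steps)
  ang <- runif(n, 0, 2 * pi)
  x <- cumsum(c(0, v * 3600 * cos(ang)))
  y <- cumsum(c(0, v * 3600 * sin(ang)))
  tr <- make_traj(x, y, 0:n)
  sm <- fit_speed_model(tr)
  expect_lt(abs(sm$shape - 2) / 2, 0.05)
  expect_lt(abs(sm$scale - 0.1) / 0.1, 0.05)
  expect_equal(sm$vmax, 1.05 * max(v), tolerance = 1e-9)
})

test_that("speed model handles the constant-speed limit and tiny inputs", {
  # constant speed 0.5 m/s: 1800 m per hourly step
  tr <- make_traj(seq_len(21) * 1800, rep(0, 21), 0:20)
  sm <- fit_speed_model(tr)
  expect_gt(sm$shape, 100)            # point-mass limit
  expect_equal(sm$scale, 0.5, tolerance = 1e-6)
  expect_equal(sm$vmax, 1.05 * 0.5, tolerance = 1e-9)

  expect_error(fit_speed_model(make_traj(0, 0, 0)), "degenerate-speed")
  expect_error(fit_speed_model(make_traj(c(0, 0, 0), c(0, 0, 0), 0:2)),
               "degenerate-speed")
})

test_that("ETD surface equals a brute-force per-cell evaluation", {
  g <- make_grid(0, 0, 25, 25, 100)
  tr <- make_traj(c(800, 1600), c(1200, 1300), c(0, 1))
  sm <- structure(list(shape = 2, scale = 0.25, vmax = 0.5, n_steps = 1),
                  class = "speed_model")
  etd <- etd_density(tr, g, sm)
  brute <- etd_brute(tr, g, sm)
  expect_lt(max(abs(etd$density - brute)), 1e-9)
})

test_that("ETD density integrates to one and respects the vmax ellipse", {
  g <- make_grid(0, 0, 30, 30, 100)
  tr <- walk_traj(n = 40, step = 150, origin = c(1500, 1500), seed = 3)
  sm <- fit_speed_model(tr)
  etd <- etd_density(tr, g, sm)
  expect_equal(sum(etd$density) * 100^2, 1, tolerance = 1e-6)
  expect_true(all(etd$density >= 0))

  # support == union of per-step vmax ellipses, checked cell by cell
  cc <- zonersf:::cell_centers(g)
  f <- tr$fixes; tt <- as.numeric(f$timestamp)
  reach <- matrix(FALSE, g$n_rows, g$n_cols)
  for (s in seq_len(nrow(f) - 1)) {
    dt <- tt[s + 1] - tt[s]
    for (r in seq_len(g$n_rows)) for (cl in seq_len(g$n_cols)) {
      v <- (sqrt((cc$x[cl] - f$x[s])^2 + (cc$y[r] - f$y[s])^2) +
            sqrt((cc$x[cl] - f$x[s + 1])^2 + (cc$y[r] - f$y[s + 1])^2)) / dt
      if (v <= sm$vmax) reach[r, cl] <- TRUE
    }
  }
  expect_identical(etd$density > 0, reach)
})

test_that("ETD is invariant under grid-aligned translation of the track", {
  g <- make_grid(0, 0, 40, 40, 100)
  tr <- walk_traj(n = 25, step = 120, origin = c(1200, 1200), seed = 9)
  sm <- fit_speed_model(tr)
  d1 <- etd_density(tr, g, sm)$density
  tr2 <- tr
  tr2$fixes$x <- tr$fixes$x + 700   # 7 cells east
  tr2$fixes$y <- tr$fixes$y + 300   # 3 cells north
  d2 <- etd_density(tr2, g, sm)$density
  # shift d2 back: north shift moves content up 3 rows, east 7 cols
  core1 <- d1[4:40, 1:33]
  core2 <- d2[1:37, 8:40]
  expect_lt(max(abs(core1 - core2)), 1e-12)
})

test_that("fixes outside the grid raise an extent error", {
  g <- make_grid(0, 0, 10, 10, 100)
  tr <- make_traj(c(500, 1500), c(500, 500), c(0, 1))
  sm <- structure(list(shape = 2, scale = 0.25, vmax = 0.5, n_steps = 1),
                  class = "speed_model")
  expect_error(etd_density(tr, g, sm), "extent error")
})

test_that("percentile home ranges follow definition, ties and monotonicity", {
  g <- make_grid(0, 0, 10, 10, 100)
  dens <- matrix(0, 10, 10)
  dens[1:10, 1:10] <- 1 / (100 * 100^2)   # uniform over 100 cells
  etd <- structure(list(grid = g, density = dens), class = "etd_raster")
  expect_equal(length(percentile_homerange(etd, 0.5)$cells), 100) # all tied
  dens2 <- matrix(seq_len(100) / sum(seq_len(100)) / 100^2, 10, 10)
  etd2 <- structure(list(grid = g, density = dens2), class = "etd_raster")
  hr50 <- percentile_homerange(etd2, 0.5)
  hr95 <- percentile_homerange(etd2, 0.95)
  hr100 <- percentile_homerange(etd2, 1)
  expect_lte(length(hr50$cells), length(hr95$cells))
  expect_lte(hr95$area_km2, hr100$area_km2)
  expect_equal(length(hr100$cells), sum(dens2 > 0))
  # smallest set: cumulative mass of the chosen cells reaches 0.5
  p <- as.vector(dens2) * 100^2
  expect_gte(sum(p[hr50$cells]), 0.5)
  expect_error(percentile_homerange(
    structure(list(grid = g, density = dens * 0), class = "etd_raster"), 1),
    "empty")
})

test_that("all fixes lie inside the 100th percentile home range", {
  w <- small_world()
  tr <- w$tracks[[2]]
  sm <- fit_speed_model(tr)
  etd <- etd_density(tr, w$landscape$grid, sm)
  hr <- percentile_homerange(etd, 1)
  idx <- zonersf:::cell_index(w$landscape$grid, tr$fixes$x, tr$fixes$y)
  cells <- (idx$col - 1L) * w$landscape$grid$n_rows + idx$row
  expect_true(all(cells %in% hr$cells))
})

test_that("range overlap metrics follow set arithmetic", {
  g <- make_grid(0, 0, 10, 10, 100)
  hr <- function(cells) zonersf:::new_homerange(g, cells, 1)
  a <- hr(1:20); b <- hr(1:40); dj <- hr(60:70)
  expect_equal(range_metrics(a, a)$overlap_fraction, 1)
  expect_equal(range_metrics(a, dj)$overlap_fraction, 0)
  m <- range_metrics(a, b)      # nested, |b| = 2|a|
  expect_equal(m$overlap_fraction, 0.5)
  expect_equal(m$overlap_of_a, 1)
  expect_equal(m$overlap_of_b, 0.5)
  expect_equal(m$overlap_directed_mean, 0.75)
  g2 <- make_grid(0, 0, 5, 5, 100)
  expect_error(range_metrics(a, zonersf:::new_homerange(g2, 1:3, 1)),
               "grid error")
})
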