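test_that("invalid generator configurations are rejected", {
  expect_error(synth_config(extent = c(500, 500), cell_size = 250),
               "3x3")
  expect_error(synth_config(cell_size = -1), "cell_size")
  expect_error(synth_config(n_zones = 0), "n_zones")
  expect_error(synth_config(fixes_per_individual = 1), "fixes_per_individual")
  expect_error(synth_config(group_sds = -0.1), "group_sds")
})

test_that("zone polygons tile the extent with no overlap and no gap", {
  w <- small_world()
  L <- w$landscape
  set.seed(99)
  pts <- data.frame(x = runif(2000) * w$cfg$extent[1],
                    y = runif(2000) * w$cfg$extent[2])
  lab <- assign_zone(pts, L$zones)$zone
  expect_false(any(lab == "outside"))
  # each point in exactly one zone: counts proportional to strip areas
  expect_equal(sort(unique(lab)),
               sort(c("mara_reserve", "conservancies", "unprotected")))
  n_in <- vapply(L$zones, function(z)
    sum(mgcv::in.out(z$coords, cbind(pts$x, pts$y))), 0L)
  expect_equal(sum(n_in), 2000)  # partition: no double counting
})

test_that("landscape and tracks are bit-identical under the same seed", {
  cfg <- synth_config(extent = c(6000, 6000), cell_size = 250,
                      n_individuals = 2, fixes_per_individual = 100,
                      hr_radius = 1500, seed = 123)
  L1 <- generate_landscape(cfg)
  L2 <- generate_landscape(cfg)
  expect_identical(L1$static_layers, L2$static_layers)
  expect_identical(L1$ndvi_layers, L2$ndvi_layers)
  t1 <- simulate_tracks(cfg, L1)
  t2 <- simulate_tracks(cfg, L2)
  expect_identical(t1[[1]]$fixes, t2[[1]]$fixes)
  expect_identical(t1[[2]]$true_coefficients, t2[[2]]$true_coefficients)
})

test_that("degenerate NDVI settings give constant layers", {
  cfg <- synth_config(extent = c(6000, 6000), cell_size = 250,
                      n_individuals = 2, fixes_per_individual = 100,
                      ndvi_season_amplitude = 0, ndvi_noise_sd = 0, seed = 5)
  L <- generate_landscape(cfg)
  for (m in L$ndvi_layers) expect_true(all(m == m[1, 1]))
})

test_that("cover one-hot layers are mutually exclusive and 0/1", {
  L <- small_world()$landscape
  onehots <- c("cover_lt20", "cover_20_70", "cover_gt70", "bare",
               "agriculture")
  tot <- Reduce(`+`, L$static_layers[onehots])
  expect_true(all(tot %in% c(0, 1)))
  for (nm in c(onehots, "drains", "roads", "settlements", "lodges"))
    expect_true(all(L$static_layers[[nm]] %in% c(0, 1)))
  # agriculture restricted to the unprotected strip
  ag_cols <- which(colSums(L$static_layers$agriculture) > 0)
  expect_true(all(ag_cols > 2 * L$grid$n_cols / 3 - 1))
})

test_that("null selection produces uniform use over the disc", {
  cfg <- synth_config(extent = c(6000, 6000), cell_size = 250,
                      n_individuals = 1, fixes_per_individual = 10000,
                      n_zones = 1, hr_radius = 2000,
                      group_means = c(drains = 0), group_sds = 0, seed = 31)
  L <- generate_landscape(cfg)
  tr <- simulate_tracks(cfg, L)[[1]]
  hr <- true_availability(tr, L$grid)
  idx <- zonersf:::cell_index(L$grid, tr$fixes$x, tr$fixes$y)
  cell <- (idx$col - 1L) * L$grid$n_rows + idx$row
  counts <- table(factor(cell, levels = hr$cells))
  p <- chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.01)
})

test_that("positive drain selection concentrates fixes in drain buffers", {
  cfg <- synth_config(extent = c(6000, 6000), cell_size = 250,
                      n_individuals = 1, fixes_per_individual = 4000,
                      n_zones = 1, hr_radius = 2000,
                      group_means = c(drains = 2), group_sds = 0, seed = 13)
  L <- generate_landscape(cfg)
  tr <- simulate_tracks(cfg, L)[[1]]
  hr <- true_availability(tr, L$grid)
  areal <- mean(L$static_layers$drains[hr$cells])
  used <- mean(raster_values(L$static_layers$drains, L$grid,
                             tr$fixes$x, tr$fixes$y))
  expect_gt(areal, 0)      # the disc must actually contain drains
  expect_gt(used, areal)
})

test_that("empirical cell-use frequencies match the enumerated RSF law", {
  # sampling-correctness oracle: direct enumeration of exp(b'x)/sum
  cfg <- synth_config(extent = c(5000, 5000), cell_size = 250,
                      n_individuals = 1, fixes_per_individual = 50000,
                      n_zones = 1, hr_radius = 2000,
                      ndvi_season_amplitude = 0, ndvi_noise_sd = 0,
                      group_means = c(drains = 1, cover_gt70 = 1.2,
                                      slope = -0.4),
                      group_sds = 0, seed = 17)
  L <- generate_landscape(cfg)
  tr <- simulate_tracks(cfg, L)[[1]]
  hr <- true_availability(tr, L$grid)
  X <- zonersf:::landscape_design(L, hr$cells)
  eta <- X[, "drains"] * 1 + X[, "cover_gt70"] * 1.2 + X[, "slope"] * (-0.4)
  p_true <- exp(eta) / sum(exp(eta))
  idx <- zonersf:::cell_index(L$grid, tr$fixes$x, tr$fixes$y)
  cell <- (idx$col - 1L) * L$grid$n_rows + idx$row
  p_emp <- as.vector(table(factor(cell, levels = hr$cells))) / nrow(tr$fixes)
  expect_lt(max(abs(p_emp - p_true)), 0.01)
})

test_that("hourly sampling spans the expected duration", {
  w <- small_world()
  f <- w$tracks[[1]]$fixes
  expect_equal(as.numeric(difftime(max(f$timestamp), min(f$timestamp),
                                   units = "secs")),
               (w$cfg$fixes_per_individual - 1) * 3600)
  expect_true(all(diff(as.numeric(f$timestamp)) == 3600))
})

test_that("runaway selection coefficients trigger the acceptance-rate guard", {
  # a single strongly selected cell in a ~29k-cell disc makes the
  # uniform-proposal acceptance rate ~1/n_cells, well below the 1e-4 guard
  cfg <- synth_config(extent = c(5000, 5000), cell_size = 25,
                      n_individuals = 1, fixes_per_individual = 500,
                      n_zones = 1, hr_radius = 2400,
                      group_means = c(rare = 20), group_sds = 0, seed = 3)
  nr <- 200L
  rare <- matrix(0, nr, nr)
  rare[100, 100] <- 1
  L <- structure(list(
    grid = make_grid(0, 0, nr, nr, 25),
    static_layers = list(slope = matrix(0, nr, nr), rare = rare),
    ndvi_dates = as.Date("2022-01-01") + c(0, 16),
    ndvi_layers = list(matrix(0.4, nr, nr), matrix(0.4, nr, nr)),
    zones = list(list(name = "z1",
                      coords = cbind(c(0, 5000, 5000, 0, 0),
                                     c(0, 0, 5000, 5000, 0)))),
    zone_of_cell = matrix(1L, nr, nr), zone_names = "z1"),
    class = "landscape")
  expect_error(simulate_tracks(cfg, L), "acceptance rate")
})

test_that("tracks and landscapes round-trip through their text formats", {
  w <- small_world()
  d <- withr::local_tempdir()
  p <- file.path(d, "tracks.csv")
  write_tracks(w$tracks, p)
  back <- read_tracks(p)
  tr <- back[[w$tracks[[1]]$individual_id]]
  expect_equal(tr$fixes$x, w$tracks[[1]]$fixes$x, tolerance = 1e-6)
  expect_equal(tr$fixes$timestamp, w$tracks[[1]]$fixes$timestamp)
  expect_true(file.exists(file.path(d, "tracks.json")))

  ldir <- file.path(d, "landscape")
  write_landscape(w$landscape, ldir)
  L2 <- read_landscape(ldir)
  expect_equal(L2$static_layers$drains, w$landscape$static_layers$drains,
               ignore_attr = TRUE)
  expect_equal(L2$ndvi_dates, w$landscape$ndvi_dates)
  expect_equal(vapply(L2$zones, `[[`, "", "name"),
               vapply(w$landscape$zones, `[[`, "", "name"))
})
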