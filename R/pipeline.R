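#' Configuration for an end-to-end pipeline run
#'
#' @param out_dir output directory (created; one file per stage artifact).
#' @param synth a \code{\link{synth_config}} for synthetic mode, or NULL
#'   to read tracks/landscape from paths.
#' @param tracks_csv,landscape_dir input paths (ignored in synthetic
#'   mode): tracks CSV as written by \code{\link{write_tracks}} and a
#'   landscape directory as written by \code{\link{write_landscape}}.
#' @param ratio available points per used fix.
#' @param percentile home-range percentile for the availability domain.
#' @param families stratum families to fit.
#' @param iter,warmup,chains MCMC settings per model.
#' @param hdpi_mass HDPI mass.
#' @param seed mandatory integer seed; expanded into fixed per-stage
#'   substreams so stages are individually reproducible.
#' @return object of class \code{"run_config"}.
#' @export
run_config <- function(out_dir, synth = NULL, tracks_csv = NULL,
                       landscape_dir = NULL, ratio = 10L, percentile = 1,
                       families = c("zone", "season", "tod", "sex"),
                       iter = 1000L, warmup = 1000L, chains = 2L,
                       hdpi_mass = 0.95, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(synth) && (is.null(tracks_csv) || is.null(landscape_dir)))
    stop("either synthetic mode (synth=) or tracks_csv + landscape_dir")
  structure(list(out_dir = out_dir, synth = synth, tracks_csv = tracks_csv,
                 landscape_dir = landscape_dir, ratio = as.integer(ratio),
                 percentile = percentile, families = families,
                 iter = as.integer(iter), warmup = as.integer(warmup),
                 chains = as.integer(chains), hdpi_mass = hdpi_mass,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full zonal RSF pipeline
#'
#' Stages: (optional) synthetic landscape + tracks, per-individual speed
#' model, ETD surface and percentile home range, 1:ratio use-available
#' sampling with random timestamps, zone assignment, covariate/stratum
#' annotation, the model battery (one hierarchical RSF per spec), and one
#' consistency report per stratum family.  Every artifact is written
#' under \code{out_dir} and declared in the returned JSON manifest.
#'
#' @param config a \code{\link{run_config}}.
#' @param write_rasters also write the ETD surfaces and landscape layers
#'   (ASCII grid; off by default to keep runs light).
#' @return the run manifest (list), invisibly written to
#'   \code{out_dir/manifest.json}.
#' @export
run_pipeline <- function(config, write_rasters = FALSE) {
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  stage <- "synth"
  manifest <- list(package_version = as.character(utils::packageVersion("zonersf")),
                   seed = config$seed, stages = list())
  res <- try({
    if (!is.null(config$synth)) {
      landscape <- generate_landscape(config$synth)
      tracks <- simulate_tracks(config$synth, landscape)
      p <- file.path(config$out_dir, "tracks.csv")
      write_tracks(tracks, p)
      files <- c(files, p, sub("\\.csv$", ".json", p))
      if (write_rasters) {
        write_landscape(landscape, file.path(config$out_dir, "landscape"))
        files <- c(files, file.path(config$out_dir, "landscape"))
      }
    } else {
      tracks <- read_tracks(config$tracks_csv)
      landscape <- read_landscape(config$landscape_dir)
    }
    manifest$stages$synth <- list(n_individuals = length(tracks),
                                  n_fixes = sum(vapply(tracks, function(t)
                                    nrow(t$fixes), 0L)))

    stage <- "homerange"
    set.seed(config$seed + 101L)
    hrs <- lapply(tracks, function(tr) {
      sp <- fit_speed_model(tr)
      etd <- etd_density(tr, landscape$grid, sp)
      percentile_homerange(etd, config$percentile)
    })
    manifest$stages$homerange <- list(
      percentile = config$percentile,
      mean_area_km2 = mean(vapply(hrs, `[[`, 0, "area_km2")))

    stage <- "sampling"
    set.seed(config$seed + 202L)
    obs <- do.call(rbind, lapply(seq_along(tracks), function(i)
      build_observations(tracks[[i]], hrs[[i]], ratio = config$ratio)))
    obs <- assign_zone(obs, landscape$zones)
    manifest$stages$sampling <- list(
      n_used = sum(obs$used == 1L), n_available = sum(obs$used == 0L),
      ratio = config$ratio,
      zone_counts = as.list(table(obs$zone)))

    stage <- "annotate"
    set.seed(config$seed + 303L)
    obs <- annotate_observations(obs, landscape)
    p <- file.path(config$out_dir, "observations.csv")
    write.csv(obs, p, row.names = FALSE)
    files <- c(files, p)
    manifest$stages$annotate <- list(
      n_retained = nrow(obs),
      wet_fraction = mean(obs$season == "wet"),
      day_fraction = mean(obs$tod == "day"))

    stage <- "rsf"
    specs <- model_battery(families = config$families)
    specs <- Filter(function(s) s$zone %in%
                      unique(obs$zone[obs$zone != "outside"]), specs)
    p <- file.path(config$out_dir, "model_specs.yaml")
    write_model_specs(specs, p); files <- c(files, p)
    fits <- fit_battery(obs, specs, iter = config$iter,
                        warmup = config$warmup, chains = config$chains,
                        seed = config$seed + 404L,
                        hdpi_mass = config$hdpi_mass)
    p <- file.path(config$out_dir, "fit_summaries.csv")
    write_fit_summaries(fits, p); files <- c(files, p)
    manifest$stages$rsf <- list(
      n_models = length(fits),
      converged = vapply(fits, `[[`, TRUE, "converged"))

    stage <- "consistency"
    tab <- coefficient_table(fits)
    p <- file.path(config$out_dir, "coefficients.csv")
    write.csv(tab, p, row.names = FALSE); files <- c(files, p)
    cons <- lapply(unique(tab$family), function(fam) {
      r <- consistency_score(tab, family = fam)
      stem <- file.path(config$out_dir, paste0("consistency_", fam))
      write_consistency(r, stem)
      files <<- c(files, paste0(stem, c(".json", "_per_covariate.csv",
                                        "_per_pair.csv")))
      r
    })
    names(cons) <- unique(tab$family)
    manifest$stages$consistency <- lapply(cons, function(r)
      list(overall = r$overall,
           per_zone = if (is.null(r$per_zone)) NULL else
             setNames(as.list(r$per_zone$score), r$per_zone$zone)))
    list(tracks = tracks, homeranges = hrs, observations = obs,
         fits = fits, coefficients = tab, consistency = cons)
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    manifest$failed_stage <- stage
    manifest$error <- as.character(res)
    manifest$files <- files
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    stop("pipeline failed at stage '", stage, "': ", res)
  }
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest$files <- c(files, file.path(config$out_dir, "manifest.json"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  out <- c(manifest, res)
  invisible(out)
}

#' Read a landscape directory written by \code{write_landscape}
#' @param dir directory with per-layer \code{.asc} files and
#'   \code{zones.geojson}.
#' @return a \code{landscape} object.
#' @export
read_landscape <- function(dir) {
  fns <- list.files(dir, pattern = "\\.asc$", full.names = TRUE)
  ndvi_fns <- grep("ndvi_", fns, value = TRUE)
  static_fns <- setdiff(fns, ndvi_fns)
  first <- read_ascii_grid(static_fns[1])
  static <- lapply(static_fns, function(f) read_ascii_grid(f)$values)
  names(static) <- sub("\\.asc$", "", basename(static_fns))
  ndvi_dates <- as.Date(sub("^ndvi_(.*)\\.asc$", "\\1", basename(ndvi_fns)))
  o <- order(ndvi_dates)
  zones <- read_zones_geojson(file.path(dir, "zones.geojson"))
  structure(list(grid = first$grid, static_layers = static,
                 ndvi_dates = ndvi_dates[o],
                 ndvi_layers = lapply(ndvi_fns[o], function(f)
                   read_ascii_grid(f)$values),
                 zones = zones,
                 zone_names = vapply(zones, `[[`, "", "name")),
            class = "landscape")
}
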