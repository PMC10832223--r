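#' Covariate set of a zonal model
#'
#' Nine covariates are shared by all zones (slope, drains, ndvi, the
#' three canopy-cover classes, bare, roads, lodges).  The reserve holds
#' no appreciable settlements and no agriculture, so its model excludes
#' both; the conservancies exclude agriculture only; the unprotected zone
#' includes both.
#'
#' @param zone one of \code{"mara_reserve"}, \code{"conservancies"},
#'   \code{"unprotected"}.
#' @return character vector of covariate names.
#' @export
zonal_covariates <- function(zone = c("mara_reserve", "conservancies",
                                      "unprotected")) {
  zone <- match.arg(zone)
  base <- c("slope", "drains", "ndvi", "cover_lt20", "cover_20_70",
            "cover_gt70", "bare", "roads", "lodges")
  switch(zone,
         mara_reserve = base,
         conservancies = c(base, "settlements"),
         unprotected = c(base, "settlements", "agriculture"))
}

#' Define one zonal/stratified model
#'
#' @param zone management zone the model is restricted to.
#' @param family stratum family: \code{"zone"} (no further restriction),
#'   \code{"season"}, \code{"tod"} or \code{"sex"}.
#' @param level stratum level within the family (e.g. \code{"wet"},
#'   \code{"day"}, \code{"female"}); must be NA for the zone family.
#' @param covariates covariate names (default: the zone's Table of
#'   covariates via \code{\link{zonal_covariates}}).
#' @return object of class \code{"model_spec"}.
#' @export
model_spec <- function(zone, family = "zone", level = NA_character_,
                       covariates = zonal_covariates(zone)) {
  stopifnot(family %in% c("zone", "season", "tod", "sex"))
  if (family == "zone" && !is.na(level)) stop("zone family has no levels")
  if (family != "zone" && is.na(level)) stop("stratified model needs a level")
  name <- if (family == "zone") zone else paste(zone, family, level, sep = "_")
  structure(list(name = name, zone = zone, family = family,
                 level = level, covariates = covariates),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: zone=%s%s, %d covariates\n", x$name, x$zone,
              if (x$family == "zone") "" else
                sprintf(", %s=%s", x$family, x$level),
              length(x$covariates)))
  invisible(x)
}

strata_levels <- c(zone = NA, season = "wet,dry", tod = "day,night",
                   sex = "female,male")

#' The full model battery
#'
#' Three zone-only models plus, per additional stratum family, one model
#' for every zone x level combination (6 each for season, time of day and
#' sex) -- 21 models for the full set of families.
#'
#' @param families which stratum families to include.
#' @param zones zone names.
#' @return named list of \code{\link{model_spec}}s.
#' @export
model_battery <- function(families = c("zone", "season", "tod", "sex"),
                          zones = c("mara_reserve", "conservancies",
                                    "unprotected")) {
  specs <- list()
  for (fam in families) {
    levels <- if (fam == "zone") NA_character_ else
      strsplit(strata_levels[[fam]], ",")[[1]]
    for (zone in zones)
      for (lv in levels)
        specs <- c(specs, list(model_spec(zone, fam, lv)))
  }
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Write / read model specs as YAML
#' @param specs list of \code{model_spec}s.
#' @param path file path.
#' @export
write_model_specs <- function(specs, path) {
  yaml::write_yaml(lapply(specs, function(s)
    list(name = s$name, zone = s$zone, family = s$family,
         level = if (is.na(s$level)) NULL else s$level,
         covariates = as.list(s$covariates))), path)
  invisible(path)
}

#' @rdname write_model_specs
#' @export
read_model_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw, function(s)
    model_spec(s$zone, s$family,
               if (is.null(s$level)) NA_character_ else s$level,
               unlist(s$covariates)))
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Subset the observation table for one model spec
#'
#' Restricts to the spec's zone (and stratum level), keeps the spec's
#' covariates, and applies the min-max + z-score standardization to the
#' continuous covariates over this subset.
#'
#' @param obs annotated observation table.
#' @param spec a \code{\link{model_spec}}.
#' @param drop_constant drop covariates that do not vary within the
#'   subset instead of erroring (the zone-specific model definitions do
#'   exactly this for features absent from a zone).  The dropped names
#'   are recorded in the \code{"dropped"} attribute and the spec carried
#'   by the fit is updated accordingly.
#' @return standardized data.frame ready for \code{\link{rsf}}.
#' @export
model_subset <- function(obs, spec, drop_constant = FALSE) {
  d <- obs[obs$zone == spec$zone, , drop = FALSE]
  if (spec$family != "zone")
    d <- d[d[[spec$family]] == spec$level, , drop = FALSE]
  if (nrow(d) == 0L) stop("empty subset for model ", spec$name)
  covs <- spec$covariates
  dropped <- character(0)
  if (drop_constant) {
    varies <- vapply(covs, function(k) diff(range(d[[k]])) > 0, TRUE)
    dropped <- covs[!varies]
    if (length(dropped))
      message("model ", spec$name, ": dropping non-varying covariate(s) ",
              paste(dropped, collapse = ", "))
    covs <- covs[varies]
  }
  keep <- c("individual_id", "used", covs)
  out <- standardize_covariates(d[, keep, drop = FALSE])
  attr(out, "covariates") <- covs
  attr(out, "dropped") <- dropped
  out
}

#' Fit every model in a battery
#'
#' @param obs annotated observation table (zone, season, tod, sex columns
#'   present as required by the specs).
#' @param specs list of \code{\link{model_spec}}s (default: the full
#'   21-model battery).
#' @param ... passed on to \code{\link{rsf}} (iter, warmup, chains, seed ...).
#' @return named list of \code{rsf} fits (class \code{"rsf_battery"}).
#' @export
fit_battery <- function(obs, specs = model_battery(), ...) {
  fits <- lapply(specs, function(sp) {
    d <- model_subset(obs, sp, drop_constant = TRUE)
    covs <- attr(d, "covariates")
    f <- as.formula(paste("used ~", paste(covs, collapse = " + ")))
    fit <- rsf(f, d, ...)
    sp$covariates <- covs
    sp$dropped <- attr(d, "dropped")
    fit$spec <- sp
    fit
  })
  class(fits) <- "rsf_battery"
  fits
}

#' @export
print.rsf_battery <- function(x, ...) {
  cat(sprintf("<rsf_battery> %d fitted models; %d converged\n", length(x),
              sum(vapply(x, `[[`, TRUE, "converged"))))
  invisible(x)
}

#' Posterior-mean coefficient table of a battery
#'
#' One row per (zone, family, level, covariate): the posterior mean of
#' the group-level coefficient, plus its HDPI.  Covariates a zone's model
#' does not include are genuinely absent (never zero-filled).
#'
#' @param fits an \code{rsf_battery} (or list of \code{rsf} fits with
#'   \code{$spec}).
#' @return data.frame of class \code{"coefficient_table"}.
#' @export
coefficient_table <- function(fits) {
  out <- do.call(rbind, lapply(fits, function(f) {
    s <- summary(f)
    s <- s[startsWith(s$parameter, "mu_") & s$covariate != "(Intercept)", ]
    data.frame(zone = f$spec$zone, family = f$spec$family,
               level = ifelse(is.na(f$spec$level), "all", f$spec$level),
               covariate = s$covariate, estimate = s$mean,
               hdpi_low = s$hdpi_low, hdpi_high = s$hdpi_high,
               converged = f$converged, row.names = NULL)
  }))
  class(out) <- c("coefficient_table", "data.frame")
  out
}

#' Export battery summaries to CSV
#' @param fits an \code{rsf_battery}.
#' @param path CSV path.
#' @export
write_fit_summaries <- function(fits, path) {
  out <- do.call(rbind, lapply(fits, function(f) {
    s <- as.data.frame(summary(f))
    cbind(model = f$spec$name, zone = f$spec$zone, family = f$spec$family,
          level = ifelse(is.na(f$spec$level), "all", f$spec$level), s)
  }))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
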