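#' Ordered intersection of model-spec covariate sets
#'
#' Zonal models have unequal covariate sets (settlements and agriculture
#' are absent from some zones), while the consistency score needs every
#' compared cell populated.  This returns the covariates shared by all
#' supplied specs, in the order of the first spec, with the per-spec
#' exclusions recorded in the \code{"excluded"} attribute.
#'
#' @param specs list of >= 2 \code{\link{model_spec}}s.
#' @return character vector with attribute \code{"excluded"}.
#' @export
covariate_intersection <- function(specs) {
  stopifnot(length(specs) >= 2L)
  sets <- lapply(specs, `[[`, "covariates")
  shared <- Reduce(intersect, sets)
  shared <- sets[[1]][sets[[1]] %in% shared]  # keep first spec's order
  if (length(shared) == 0L) stop("empty covariate intersection")
  excl <- lapply(sets, setdiff, y = shared)
  names(excl) <- vapply(specs, `[[`, "", "name")
  attr(shared, "excluded") <- excl[vapply(excl, length, 0L) > 0]
  shared
}

cell_estimate <- function(tab, zone, level, covariate) {
  v <- tab$estimate[tab$zone == zone & tab$level == level &
                      tab$covariate == covariate]
  if (length(v) != 1L)
    stop("coverage error: covariate '", covariate,
         "' missing in cell (", zone, ", ", level, ")")
  v
}

#' Consistency score of selection coefficients across zones and strata
#'
#' For a covariate k, the score is the mean over all zone pairs and
#' stratum levels of the absolute difference of the (posterior-mean)
#' selection coefficients: with 3 zones and 2 levels that is 6 terms; the
#' zone-only family has a single implicit level (3 terms).  Scores are
#' aggregated by arithmetic mean: per covariate, per zone pair, per zone
#' across levels (the within-zone strata contrast), and overall.  Zero
#' means identical selection; larger values mean stronger
#' differentiation.
#'
#' @param table a \code{\link{coefficient_table}} (or any data.frame with
#'   zone, family, level, covariate, estimate).
#' @param family which stratum family to score (default: the single
#'   family present).
#' @param covariates covariates to include; default: those present in
#'   every compared (zone, level) cell.  A requested covariate missing
#'   from a compared cell is an error, never silently zero-filled.
#' @return object of class \code{"consistency_result"}: list with
#'   \code{per_covariate}, \code{per_zone_pair} (scored on the shared
#'   covariates and, alongside, on each pair's own shared set),
#'   \code{per_zone} (within-zone across-level score; NULL for the
#'   zone-only family), \code{overall}, and metadata.
#' @export
consistency_score <- function(table, family = NULL, covariates = NULL) {
  if (is.null(family)) {
    family <- unique(table$family)
    if (length(family) != 1L)
      stop("several families present; pick one with `family`")
  }
  tab <- table[table$family == family, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no rows for family '", family, "'")
  zones <- unique(tab$zone)
  levels <- unique(tab$level)
  if (length(zones) < 2L) stop("need >= 2 zones to score consistency")
  if (is.null(covariates)) {
    covariates <- Reduce(intersect,
                         lapply(split(tab$covariate,
                                      paste(tab$zone, tab$level)), unique))
    if (length(covariates) == 0L) stop("empty covariate intersection")
  }
  pairs <- combn(zones, 2, simplify = FALSE)

  per_cov <- vapply(covariates, function(k) {
    mean(unlist(lapply(pairs, function(pr)
      vapply(levels, function(l)
        abs(cell_estimate(tab, pr[1], l, k) -
              cell_estimate(tab, pr[2], l, k)), numeric(1)))))
  }, numeric(1))

  pair_score <- function(pr, covs) {
    mean(unlist(lapply(covs, function(k)
      vapply(levels, function(l)
        abs(cell_estimate(tab, pr[1], l, k) -
              cell_estimate(tab, pr[2], l, k)), numeric(1)))))
  }
  per_pair <- do.call(rbind, lapply(pairs, function(pr) {
    sub <- tab[tab$zone %in% pr, , drop = FALSE]
    own <- Reduce(intersect,
                  lapply(split(sub$covariate, paste(sub$zone, sub$level)),
                         unique))
    data.frame(zone_a = pr[1], zone_b = pr[2],
               score = pair_score(pr, covariates),
               score_pair_covariates = pair_score(pr, own),
               row.names = NULL)
  }))

  per_zone <- NULL
  if (length(levels) >= 2L) {
    lv_pairs <- combn(levels, 2, simplify = FALSE)
    per_zone <- data.frame(zone = zones, score = vapply(zones, function(z) {
      mean(unlist(lapply(covariates, function(k)
        vapply(lv_pairs, function(lp)
          abs(cell_estimate(tab, z, lp[1], k) -
                cell_estimate(tab, z, lp[2], k)), numeric(1)))))
    }, numeric(1)), row.names = NULL)
  }

  structure(list(family = family, covariates = covariates,
                 zones = zones, levels = levels,
                 per_covariate = per_cov, per_zone_pair = per_pair,
                 per_zone = per_zone,
                 overall = mean(per_cov)),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf("<consistency_result> family=%s, %d covariates, overall C = %.3f\n",
              x$family, length(x$covariates), x$overall))
  print(transform(x$per_zone_pair, score = round(score, 3),
                  score_pair_covariates = round(score_pair_covariates, 3)),
        row.names = FALSE)
  if (!is.null(x$per_zone)) {
    cat("within-zone (across levels):\n")
    print(transform(x$per_zone, score = round(score, 3)), row.names = FALSE)
  }
  invisible(x)
}

#' Posterior distribution of the overall consistency score
#'
#' Uncertainty-propagated extension of \code{\link{consistency_score}}:
#' the score is recomputed per joint posterior draw of the group-level
#' means, giving a posterior distribution of C rather than a point value
#' on posterior means.
#'
#' @param fits an \code{rsf_battery} restricted to one stratum family.
#' @param ndraws draws to propagate (default 500).
#' @param covariates covariates to include (default: shared set).
#' @param seed optional seed.
#' @return numeric vector of overall-score draws.
#' @export
consistency_draws <- function(fits, ndraws = 500L, covariates = NULL,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fam <- unique(vapply(fits, function(f) f$spec$family, ""))
  if (length(fam) != 1L) stop("fits must share one stratum family")
  S <- min(vapply(fits, function(f) nrow(f$draws$mu), 0L))
  take <- sample.int(S, min(ndraws, S))
  vapply(take, function(s) {
    tab <- do.call(rbind, lapply(fits, function(f) {
      mu <- f$draws$mu[s, ]
      mu <- mu[names(mu) != "(Intercept)"]
      data.frame(zone = f$spec$zone, family = f$spec$family,
                 level = ifelse(is.na(f$spec$level), "all", f$spec$level),
                 covariate = names(mu), estimate = unname(mu))
    }))
    consistency_score(tab, family = fam, covariates = covariates)$overall
  }, numeric(1))
}

#' Export a consistency result as CSV + JSON
#' @param res a \code{consistency_result}.
#' @param stem output path stem (writes \code{<stem>.csv} and
#'   \code{<stem>.json}).
#' @export
write_consistency <- function(res, stem) {
  write.csv(data.frame(covariate = names(res$per_covariate),
                       score = unname(res$per_covariate)),
            paste0(stem, "_per_covariate.csv"), row.names = FALSE)
  write.csv(res$per_zone_pair, paste0(stem, "_per_pair.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(family = res$family, overall = res$overall,
         per_covariate = as.list(res$per_covariate),
         per_zone_pair = res$per_zone_pair,
         per_zone = res$per_zone),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
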