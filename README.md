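# zonersf

Zonal resource selection functions for GPS telemetry.

Wildlife such as savanna elephants range across contiguous land parcels
under very different management — a formally protected reserve, community
conservancies, unprotected farm and range land — and their habitat
selection can shift, weaken or flip between those parcels. `zonersf` is
an R package for quantifying that differentiation from GPS collar data.
It is aimed at movement ecologists who have per-individual GPS
trajectories, raster covariates and zone polygons, and want per-zone,
per-stratum selection coefficients plus a single score of how strongly
selection differs across zones and strata.

The pipeline:

1. **Home ranges** — elliptical time-density (ETD) surfaces per
   individual: each consecutive fix pair weights the cells it could have
   traversed by the Weibull density of the speed required,
   `v(c) = (|p1 − c| + |c − p2|) / Δt`, truncated at `vmax`; the
   100th-percentile isopleth is the availability domain.
2. **Use–available sampling** — 10 random available points per used fix,
   uniform over the home range, each with an independent random
   timestamp inside the tracking period.
3. **Annotation** — static rasters at the containing cell,
   nearest-in-time 16-day NDVI, wet/dry season labels from a
   two-component Gaussian mixture on scene-mean NDVI (higher mean ⇒
   wet), day/night from NOAA solar elevation, zone by point-in-polygon.
4. **Hierarchical Bayesian RSF** — Bernoulli likelihood with logistic
   link, `logit(θ) = β₀ᵢ + Σₖ βᵢₖ xₖ`, every coefficient
   individual-level with Gaussian group-level distributions
   `βᵢₖ ~ N(μₖ, σₖ²)`, priors `μₖ ~ N(0, 100)` and
   `σₖ ~ half-Normal(5)`; posterior draws from an adaptive
   Metropolis-within-Gibbs sampler with a compiled core; 95%
   highest-density intervals, split-R̂, effective sample sizes and
   posterior predictive checks. A battery of 21 models: 3 zonal + 6
   season + 6 time-of-day + 6 sex.
5. **Consistency score** — for covariate k, the mean absolute difference
   of posterior-mean coefficients over all zone pairs × stratum levels
   (6 terms for 3 zones × 2 levels):
   `Cₖ = mean |p_{i₁ l k} − p_{i₂ l k}|`, aggregated by arithmetic mean
   per covariate, per zone pair, per zone and overall. Zero means
   identical selection; larger means stronger differentiation.

A synthetic-data module (`synth_config()`, `generate_landscape()`,
`simulate_tracks()`) generates autocorrelated landscapes, three
management-zone strips and tracks drawn from an RSF point process with
known individual coefficients, so the whole pipeline is testable and the
estimator's recovery of truth is verifiable without any field data.

## Worked example

Simulate a small study system, fit the three zonal models, and score
cross-zone differentiation:

```r
library(zonersf)

cfg <- synth_config(extent = c(18000, 12000), cell_size = 250,
                    n_individuals = 8, fixes_per_individual = 1460,
                    fix_interval = 21600, hr_radius = 3500, seed = 1)
land   <- generate_landscape(cfg)
tracks <- simulate_tracks(cfg, land)

obs <- do.call(rbind, lapply(tracks, function(tr) {
  speed <- fit_speed_model(tr)
  hr <- percentile_homerange(etd_density(tr, land$grid, speed), 1)
  build_observations(tr, hr, ratio = 10)
}))
obs <- assign_zone(obs, land$zones)
obs <- annotate_observations(obs, land)

fits <- fit_battery(obs, model_battery("zone"),
                    iter = 500, warmup = 500, chains = 2, seed = 1)
summary(fits$conservancies)
consistency_score(coefficient_table(fits), "zone")
```

The summary prints one row per group-level parameter (posterior mean,
sd, 95% HDPI, split-R̂, effective sample size):

```
Posterior summaries (95% HDPI); converged: yes
         parameter   covariate   mean    sd hdpi_low hdpi_high  rhat      ess
    mu_(Intercept) (Intercept) -3.280 0.238   -3.766    -2.815 1.008  228.497
          mu_slope       slope -0.480 0.359   -1.239     0.186 1.001 1000.000
         mu_drains      drains  0.441 0.210    0.027     0.826 1.001  864.401
           mu_ndvi        ndvi -0.007 0.019   -0.043     0.031 1.004  305.320
     mu_cover_lt20  cover_lt20 -0.855 0.233   -1.292    -0.388 1.008  260.960
    mu_cover_20_70 cover_20_70  0.590 0.203    0.212     1.006 1.007  243.161
     mu_cover_gt70  cover_gt70  1.121 0.422    0.296     1.956 1.003  713.706
...
 sigma_settlements settlements  0.860 0.351    0.374     1.512 1.000  459.274
```

`mu_cover_lt20 ≈ −0.86` is the group-level standardized selection
coefficient: these simulated animals avoid open grassland (the generator
truth was −0.9) and select closed canopy (`mu_cover_gt70 ≈ 1.12`, truth
1.5 with a wide interval at 8 individuals); both 95% HDPIs exclude zero.
The `sigma_` rows quantify between-individual spread. The consistency
result

```
<consistency_result> family=zone, 9 covariates, overall C = 0.437
        zone_a        zone_b score score_pair_covariates
  mara_reserve conservancies 0.357                 0.357
  mara_reserve   unprotected 0.528                 0.528
 conservancies   unprotected 0.426                 0.384
```

says selection coefficients differ across zones by ~0.44 on average
under this generator (which draws every zone from the same group means —
the residual score is the estimation-noise floor at this reduced problem
size; a generator with zone-dependent means scores far higher, which is
exactly the contrast the acceptance script measures).

Forest plots of the fitted coefficients come from `plot(fit)`;
`posterior_predictive_check(fit)` and `random_effect_spread(fit)` cover
model criticism, and `run_pipeline(run_config(...))` orchestrates all
stages end to end, writing per-stage CSV/GeoJSON/ASCII-grid artifacts
and a JSON manifest.

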