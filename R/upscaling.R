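# Zone-stratified upscaling: season models, pre-generated rate pools,
# Monte Carlo assignment of rates to water bodies, the main-channel
# transect procedure, fixed-rate upscaling, C yields and the spring-flood
# scenario.

#' Fit an ice-free season model
#'
#' Least-squares line of ice-free season length (days) on latitude
#' (degrees N), the standard way station observations are turned into a
#' region-wide season predictor.
#'
#' @param latitude Latitudes, degrees N (>= 3 distinct values).
#' @param days Ice-free season lengths, days.
#' @param body_class Optional label (`"river"`/`"lake"`) carried in the
#'   result.
#' @return List of class `"season_model"` with `intercept`, `slope`,
#'   `r_squared`, `body_class`.
#' @export
#' @examples
#' m <- fit_season_model(c(56, 60, 64, 68), 603 - 7 * c(56, 60, 64, 68))
#' c(m$intercept, m$slope)
fit_season_model <- function(latitude, days, body_class = NA_character_) {
  if (length(unique(latitude)) < 3L) {
    stop("need at least 3 distinct latitudes to fit a season model",
         call. = FALSE)
  }
  if (length(latitude) != length(days)) {
    stop("latitude and days must have equal length", call. = FALSE)
  }
  fit <- stats::lm(days ~ latitude)
  # R2 computed directly; summary.lm warns on zero-residual fits
  ss_tot <- sum((days - mean(days))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::resid(fit)^2) / ss_tot
  structure(
    list(intercept = unname(stats::coef(fit)[1]),
         slope = unname(stats::coef(fit)[2]),
         r_squared = r2,
         body_class = body_class),
    class = "season_model"
  )
}

#' Season model from known coefficients
#'
#' @param intercept Days at latitude zero.
#' @param slope Days per degree N (typically negative).
#' @param body_class Optional label.
#' @return List of class `"season_model"`.
#' @export
season_model <- function(intercept, slope, body_class = NA_character_) {
  check_number(intercept, "intercept")
  check_number(slope, "slope")
  structure(list(intercept = intercept, slope = slope, r_squared = NA_real_,
                 body_class = body_class),
            class = "season_model")
}

#' Predicted ice-free season length
#'
#' @param model `"season_model"` object.
#' @param latitude Latitudes, degrees N.
#' @return Predicted season lengths in days; an error is raised if any
#'   prediction is non-positive (the model is then invalid over the
#'   requested band).
#' @export
season_length <- function(model, latitude) {
  stopifnot(inherits(model, "season_model"))
  s <- model$intercept + model$slope * latitude
  if (any(s <= 0)) {
    stop("season model predicts non-positive season length within the ",
         "requested latitude band", call. = FALSE)
  }
  s
}

#' Pre-generated per-zone rate pools
#'
#' Draws `pool_size` normal deviates per system class and permafrost
#' zone from the configured mean/s.d. Rates are later assigned to water
#' bodies by subsampling these fixed pools (rather than fresh normal
#' draws), preserving the resampling structure of the upscaling
#' procedure. Negative deviates are retained: negative emission rates
#' represent net uptake.
#'
#' @param cfg [landscape_config()] supplying `cfg$rates` and
#'   `cfg$pool_size`.
#' @param seed Seed; defaults to `cfg$seed`.
#' @return Nested list `pools[[class]][[zone]]`, each a numeric vector of
#'   length `cfg$pool_size`, with the class CH4 fractions attached as
#'   attribute `"ch4_fraction"`.
#' @export
#' @examples
#' pools <- rate_pools(landscape_config())
#' length(pools$river$absent)
rate_pools <- function(cfg, seed = cfg$seed) {
  validate_landscape_config(cfg)
  with_seed(seed, {
    pools <- lapply(cfg$rates, function(pars) {
      stats::setNames(lapply(zone_levels(), function(z) {
        stats::rnorm(cfg$pool_size, pars$mean[[z]], pars$sd[[z]])
      }), zone_levels())
    })
    attr(pools, "ch4_fraction") <- vapply(cfg$rates, `[[`, numeric(1),
                                          "ch4_fraction")
    pools
  })
}

#' Upscale a water-body inventory to annual per-zone C emission
#'
#' For each body: draw a daily rate from its zone- and class-specific
#' pool, add the class CH4 share, multiply by the class season length at
#' the body's latitude and by its surface area, and sum by zone and
#' class. Deterministic under a fixed seed.
#'
#' @param bodies Inventory `data.frame` as from [generate_inventory()]
#'   (columns `body_class`, `zone`, `surface_area_km2`, `latitude`).
#' @param pools Rate pools from [rate_pools()]; must contain every
#'   `body_class` present.
#' @param season_models Named list of `"season_model"`s per body class.
#' @param seed Seed for the pool subsampling.
#' @param detail Attach per-body annual emissions (g C yr-1) as
#'   attribute `"body_emission"`? Default `FALSE`.
#' @return `data.frame` with one row per zone x class: `zone`,
#'   `body_class`, `area_km2`, `emission_PgC_yr`.
#' @export
#' @examples
#' cfg <- landscape_config(scale = 0.002)
#' inv <- generate_inventory(cfg)
#' inv <- inv[inv$body_class %in% c("river", "lake"), ]
#' sm <- list(river = season_model(603, -7), lake = season_model(540, -6.2))
#' upscale_inventory(inv, rate_pools(cfg), sm, seed = 2)
upscale_inventory <- function(bodies, pools, season_models, seed = NULL,
                              detail = FALSE) {
  classes <- unique(as.character(bodies$body_class))
  missing_cls <- setdiff(classes, names(pools))
  if (length(missing_cls) > 0L) {
    stop("no rate distribution for class(es): ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  missing_sm <- setdiff(classes, names(season_models))
  if (length(missing_sm) > 0L) {
    stop("no season model for class(es): ",
         paste(missing_sm, collapse = ", "), call. = FALSE)
  }
  ch4 <- attr(pools, "ch4_fraction")
  zone <- as.character(normalize_zone(bodies$zone))
  with_seed(seed, {
    rate <- numeric(nrow(bodies))
    season <- numeric(nrow(bodies))
    for (cl in classes) {
      sel_cl <- bodies$body_class == cl
      season[sel_cl] <- season_length(season_models[[cl]],
                                      bodies$latitude[sel_cl])
      for (z in unique(zone[sel_cl])) {
        sel <- sel_cl & zone == z
        pool <- pools[[cl]][[z]]
        if (is.null(pool)) {
          stop(sprintf("no rate distribution for zone '%s' (class '%s')",
                       z, cl), call. = FALSE)
        }
        rate[sel] <- pool[sample.int(length(pool), sum(sel),
                                     replace = TRUE)]
      }
      f <- if (!is.null(ch4) && cl %in% names(ch4)) ch4[[cl]] else 0
      if (f > 0) rate[sel_cl] <- add_ch4(rate[sel_cl], f)
    }
    body_em <- rate * season * bodies$surface_area_km2 * .M2_PER_KM2
    agg <- stats::aggregate(
      cbind(area_km2 = bodies$surface_area_km2,
            emission_g = body_em),
      by = list(zone = zone, body_class = as.character(bodies$body_class)),
      FUN = sum
    )
    out <- data.frame(
      zone = normalize_zone(agg$zone),
      body_class = agg$body_class,
      area_km2 = agg$area_km2,
      emission_PgC_yr = agg$emission_g / .G_PER_PG
    )
    out <- out[order(out$body_class, out$zone), ]
    rownames(out) <- NULL
    if (detail) {
      attr(out, "body_emission") <- data.frame(
        zone = normalize_zone(zone),
        body_class = bodies$body_class,
        emission_gC_yr = body_em,
        rate_gC_m2_d = rate,
        season_days = season
      )
    }
    out
  })
}

#' Upscale the main-channel transect by Monte Carlo resampling
#'
#' For each permafrost zone, resamples the transect observations of
#' summer pCO2, temperature and pH `n_draws` times, applies the spring
#' adjustment to the assigned pCO2, evaluates the gas-exchange flux with
#' the median transfer coefficient and chemical enhancement, adds the
#' CH4 share, and multiplies the mean daily rate by zone water area and
#' ice-free season length. Zones with area but no samples are filled
#' from the nearest sampled zone to the south (the continuous zone from
#' the discontinuous one).
#'
#' @param samples Transect `data.frame` as from [generate_transect()].
#' @param areas_km2 Named per-zone main-channel areas (km2).
#' @param params [exchange_params()].
#' @param model Season model used for the channel (a river-type model).
#' @param zones Zone table supplying per-zone representative latitudes.
#' @param n_draws Monte Carlo draws per zone (default 100000).
#' @param seed Seed.
#' @return `data.frame` per zone: `zone`, `area_km2`, `season_days`,
#'   `rate_gC_m2_d` (mean daily C rate), `rate_mc_se` (Monte Carlo
#'   standard error of that mean), `emission_PgC_yr`.
#' @export
upscale_transect <- function(samples, areas_km2,
                             params = exchange_params(),
                             model = season_model(603, -7, "river"),
                             zones = permafrost_zones(),
                             n_draws = 100000L, seed = NULL) {
  stopifnot(inherits(params, "exchange_params"))
  zl <- zone_levels()
  szone <- as.character(normalize_zone(samples$zone))
  mid_lat <- zone_mid_latitude(zones)
  with_seed(seed, {
    rows <- list()
    for (zi in seq_along(zl)) {
      z <- zl[zi]
      area <- areas_km2[[z]]
      if (is.null(area) || is.na(area) || area <= 0) next
      src <- z
      j <- zi
      while (sum(szone == src) == 0L && j > 1L) {
        j <- j - 1L
        src <- zl[j]
      }
      if (sum(szone == src) == 0L) {
        stop(sprintf(
          "zone '%s' has water area but no transect samples and no %s",
          z, "sampled zone to the south to fill from"), call. = FALSE)
      }
      sub <- samples[szone == src, ]
      idx <- sample.int(nrow(sub), n_draws, replace = TRUE)
      flux <- co2_emission_rate(spring_adjust(sub$pco2_uatm[idx]),
                                sub$temp_c[idx], sub$ph[idx], params)
      flux <- add_ch4(flux, params$ch4_fraction)
      season <- season_length(model, mid_lat[[z]])
      rows[[z]] <- data.frame(
        zone = z, area_km2 = area, season_days = season,
        rate_gC_m2_d = mean(flux),
        rate_mc_se = stats::sd(flux) / sqrt(n_draws),
        emission_PgC_yr = mean(flux) * area * .M2_PER_KM2 * season /
          .G_PER_PG
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out$zone <- normalize_zone(out$zone)
    out
  })
}

#' Fixed-rate upscaling
#'
#' Annual emission from a constant daily areal rate:
#' `area (m2) x rate x season / 1e15`.
#'
#' @param area_km2 Surface area, km2.
#' @param rate_gC_m2_d Daily C emission rate, g C m-2 d-1.
#' @param season_days Ice-free season length, days.
#' @return Annual emission in Pg C yr-1.
#' @export
#' @examples
#' upscale_fixed_rate(13639, 5.67, 180.6)
upscale_fixed_rate <- function(area_km2, rate_gC_m2_d, season_days) {
  check_number(area_km2, "area_km2", lower = 0)
  check_number(rate_gC_m2_d, "rate_gC_m2_d", lower = 0)
  check_number(season_days, "season_days", lower = 0)
  area_km2 * .M2_PER_KM2 * rate_gC_m2_d * season_days / .G_PER_PG
}

#' Carbon yield
#'
#' Inland-water C emission normalised to the land area of the
#' contributing region.
#'
#' @param emission_PgC_yr Emission, Pg C yr-1.
#' @param land_area_km2 Land area, km2 (> 0).
#' @return Yield in g C per m2 of land per year.
#' @export
#' @examples
#' c_yield(0.001, 100000) # 10
c_yield <- function(emission_PgC_yr, land_area_km2) {
  if (any(land_area_km2 <= 0)) {
    stop("land area must be strictly positive", call. = FALSE)
  }
  emission_PgC_yr * .G_PER_PG / (land_area_km2 * .M2_PER_KM2)
}

#' Spring-flood scenario
#'
#' Additional emission if water area increases by `area_increase` for
#' `flood_days` days: each component contributes
#' `emission * area_increase * flood_days / season`, i.e. its daily rate
#' over the enlarged area for the flood window.
#'
#' @param components `data.frame` with columns `emission_PgC_yr` and
#'   `season_days` (one row per zone/class component).
#' @param area_increase Fractional area increase during the flood
#'   (default 0.85).
#' @param flood_days Flood duration in days (default 30); must not
#'   exceed any component's season.
#' @return List with `extra_PgC_yr` and `percent_increase`.
#' @export
#' @examples
#' floodplain_scenario(data.frame(emission_PgC_yr = 0.05,
#'                                season_days = 180.6))
floodplain_scenario <- function(components, area_increase = 0.85,
                                flood_days = 30) {
  check_number(area_increase, "area_increase", lower = 0)
  check_number(flood_days, "flood_days", lower = 0)
  if (any(flood_days > components$season_days)) {
    stop("flood duration exceeds a component's ice-free season",
         call. = FALSE)
  }
  base <- sum(components$emission_PgC_yr)
  extra <- sum(components$emission_PgC_yr * area_increase * flood_days /
                 components$season_days)
  list(extra_PgC_yr = extra,
       percent_increase = if (base == 0) 0 else 100 * extra / base)
}
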