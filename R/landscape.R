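# Synthetic landscape generator: water-body inventories, a main-channel
# gas transect, per-zone emission-rate observations, ice-free-season
# observations, and a gridded daily NEE field, all with the statistical
# structure the upscaling assumes, so the full pipeline runs without
# external geodata.

#' Configuration of the synthetic landscape
#'
#' Returns the calibrated default configuration. River widths and lake
#' areas follow truncated Pareto laws (shapes 0.93 and 1.19); per-zone
#' target surface areas, emission-rate means/s.d. and season-model
#' coefficients are calibration constants chosen so that zone and class
#' aggregates of the generated landscape reproduce the regional
#' inventory (per-zone rate parameters are calibrated, not measured).
#' All extensive quantities (target areas, land areas, grid cell count)
#' scale with `scale`, so reduced-size landscapes remain internally
#' consistent.
#'
#' @param scale Multiplier on all extensive quantities (default 1).
#' @param seed Default seed recorded in the config and used by the
#'   generators when no explicit seed is passed.
#' @param zones Zone table as from [permafrost_zones()].
#' @return List of class `"landscape_config"`.
#' @export
#' @examples
#' cfg <- landscape_config(scale = 0.01)
#' sum(cfg$lake$area_km2)
landscape_config <- function(scale = 1, seed = 1L,
                             zones = permafrost_zones()) {
  check_number(scale, "scale", lower = 1e-9)
  zl <- zone_levels()
  zones$land_area_km2 <- zones$land_area_km2 * scale
  cfg <- list(
    seed = seed,
    scale = scale,
    zones = zones,
    # lotic widths: Pareto tail of the regional river inventory; the upper
    # truncation is the widest main-stem reach and also bounds the
    # width-density area integral used for stream extrapolation
    river = list(
      shape = 0.93, width_min_m = 90, width_max_m = 4200,
      area_km2 = stats::setNames(
        c(6718, 1421, 1421, 1680, 1679) * scale, zl),
      length_meanlog = log(700) - 0.125, length_sdlog = 0.5
    ),
    stream = list(
      count = stats::setNames(rep(0L, 5L), zl),
      width_min_m = 0.32, fixed_rate = 5.67, season_days = 180.6
    ),
    # lentic areas: Pareto above the 0.01 km2 inventory cutoff; the
    # permafrost-free (absent) zone holds the southern lake district
    lake = list(
      shape = 1.19, area_min_km2 = 0.01, area_max_km2 = 1000,
      area_km2 = stats::setNames(
        c(74940, 17296, 21140, 33631, 24022) * scale, zl)
    ),
    pond = list(
      count = stats::setNames(rep(0L, 5L), zl),
      area_min_km2 = 0.000115,
      rate_permafrost = 1.12, rate_free = 0.6
    ),
    main_channel = list(
      area_km2 = stats::setNames(
        6831 * c(0.35, 0.25, 0.15, 0.15, 0.10) * scale, zl),
      width_m = 2000
    ),
    # per-zone daily rate distributions (g C m-2 d-1); river rates are
    # CO2-only (CH4 added as a share), lake rates are total C
    rates = list(
      river = list(
        mean = stats::setNames(c(4.5, 6.8, 7.3, 6.2, 5.0), zl),
        sd = stats::setNames(c(2.5, 3.5, 3.5, 3.0, 2.5), zl),
        ch4_fraction = 0.0119
      ),
      lake = list(
        mean = stats::setNames(c(0.6, 1.0, 1.4, 2.4, 2.0), zl),
        sd = stats::setNames(c(0.3, 0.6, 0.8, 1.2, 1.0), zl),
        ch4_fraction = 0
      )
    ),
    pool_size = 10000L,
    # ice-free season length (days) as a linear function of latitude
    season = list(
      river = c(intercept = 603, slope = -7),
      lake = c(intercept = 540, slope = -6.2)
    ),
    season_obs = list(n_river = 116L, n_lake = 228L,
                      noise_sd_river = 4, noise_sd_lake = 5),
    # main-channel transect: summer pCO2 log-normal (positivity) with
    # moments matched to the campaign mean/s.d.; no samples reach the
    # continuous zone (the route ends before the river mouth)
    transect = list(
      n_per_zone = stats::setNames(c(1516L, 1982L, 431L, 467L, 0L), zl),
      pco2_mean = 1546, pco2_sd = 882,
      ph_mean = stats::setNames(c(7.4, 7.2, 7.0, 6.9, 6.9), zl),
      ph_sd = 0.3, ph_max = 8,
      temp_mean = 22, temp_sd = 1.5,
      pressure_kpa = 101.3
    ),
    # daily 9 x 9 km NEE field with winter respiration and a summer
    # uptake pulse; calibrated to a regional net sink of realistic order
    nee = list(
      n_cells = as.integer(round(71280 * scale)), cell_area_km2 = 81,
      resp_mean = 0.3, resp_sd = 0.05,
      uptake_mean = 1.275, uptake_sd = 0.2,
      peak_day = 196, width_days = 45, noise_sd = 0.1
    )
  )
  class(cfg) <- "landscape_config"
  validate_landscape_config(cfg)
  cfg
}

#' Validate a landscape configuration
#'
#' Checks positivity of scale parameters, Pareto shapes and counts.
#' Called by [landscape_config()] and again by the generators, so
#' hand-edited configs fail early with a named reason.
#'
#' @param cfg `"landscape_config"` list.
#' @return `cfg`, invisibly.
#' @export
validate_landscape_config <- function(cfg) {
  stopifnot(inherits(cfg, "landscape_config"))
  if (cfg$river$shape <= 0 || cfg$lake$shape <= 0) {
    stop("Pareto shapes must be positive", call. = FALSE)
  }
  if (any(cfg$river$area_km2 < 0) || any(cfg$lake$area_km2 < 0) ||
      any(cfg$main_channel$area_km2 < 0)) {
    stop("target areas must be non-negative", call. = FALSE)
  }
  if (any(cfg$stream$count < 0) || any(cfg$pond$count < 0)) {
    stop("body counts must be non-negative", call. = FALSE)
  }
  if (any(cfg$zones$land_area_km2 <= 0)) {
    stop("land areas must be strictly positive", call. = FALSE)
  }
  if (cfg$transect$pco2_mean <= 0 || cfg$transect$pco2_sd < 0) {
    stop("transect pCO2 mean must be positive and s.d. non-negative",
         call. = FALSE)
  }
  with(cfg$rates, {
    if (length(river$mean) != 5L || length(river$sd) != 5L ||
        length(lake$mean) != 5L || length(lake$sd) != 5L) {
      stop("rate parameters require one mean/sd pair per zone",
           call. = FALSE)
    }
    if (any(river$sd < 0) || any(lake$sd < 0)) {
      stop("rate standard deviations must be non-negative", call. = FALSE)
    }
  })
  if (cfg$nee$n_cells <= 0) {
    stop("NEE grid must contain at least one cell", call. = FALSE)
  }
  invisible(cfg)
}

# uniform latitude inside the zone's configured band
.zone_latitudes <- function(n, zone, zones) {
  i <- match(zone, as.character(zones$zone))
  stats::runif(n, zones$lat_min[i], zones$lat_max[i])
}

#' Generate a synthetic water-body inventory
#'
#' One row per surface unit: main-channel reaches (one per zone, fixed
#' calibrated area), river segments (Pareto widths times log-normal
#' lengths, counts set so per-zone areas hit the configured targets),
#' lakes (Pareto areas), and optionally explicit streams and ponds when
#' their counts are positive (by default both are handled by
#' extrapolation instead). Class size boundaries (90 m, 0.32 m,
#' 0.01 km2, 0.000115 km2) hold by construction.
#'
#' @param cfg [landscape_config()] object.
#' @param seed Seed; defaults to `cfg$seed`.
#' @return `data.frame` with columns `id`, `body_class`, `zone`,
#'   `surface_area_km2`, `width_m` (NA for lentic bodies), `latitude`.
#' @export
#' @examples
#' inv <- generate_inventory(landscape_config(scale = 0.005))
#' table(inv$body_class)
generate_inventory <- function(cfg, seed = cfg$seed) {
  validate_landscape_config(cfg)
  zl <- zone_levels()
  with_seed(seed, {
    parts <- list()
    # main channel: one reach per zone at its configured area
    mc_area <- cfg$main_channel$area_km2
    parts$main_channel <- data.frame(
      body_class = "main_channel", zone = zl,
      surface_area_km2 = as.numeric(mc_area),
      width_m = cfg$main_channel$width_m,
      latitude = as.numeric(zone_mid_latitude(cfg$zones))
    )
    # rivers: counts from target area / expected segment area
    rv <- cfg$river
    seg_area_km2 <- tpareto_mean(rv$shape, rv$width_min_m, rv$width_max_m) *
      exp(rv$length_meanlog + rv$length_sdlog^2 / 2) / .M2_PER_KM2
    for (z in zl) {
      n <- round(rv$area_km2[[z]] / seg_area_km2)
      if (n < 1) next
      w <- rpareto(n, rv$shape, rv$width_min_m, rv$width_max_m)
      len <- stats::rlnorm(n, rv$length_meanlog, rv$length_sdlog)
      parts[[paste0("river_", z)]] <- data.frame(
        body_class = "river", zone = z,
        surface_area_km2 = w * len / .M2_PER_KM2,
        width_m = w, latitude = .zone_latitudes(n, z, cfg$zones)
      )
    }
    # lakes: counts from target area / expected lake area
    lk <- cfg$lake
    mean_lake <- tpareto_mean(lk$shape, lk$area_min_km2, lk$area_max_km2)
    for (z in zl) {
      n <- round(lk$area_km2[[z]] / mean_lake)
      if (n < 1) next
      a <- rpareto(n, lk$shape, lk$area_min_km2, lk$area_max_km2)
      parts[[paste0("lake_", z)]] <- data.frame(
        body_class = "lake", zone = z,
        surface_area_km2 = a, width_m = NA_real_,
        latitude = .zone_latitudes(n, z, cfg$zones)
      )
    }
    # explicit streams/ponds only when requested
    for (z in zl) {
      ns <- cfg$stream$count[[z]]
      if (ns >= 1) {
        w <- rpareto(ns, rv$shape, cfg$stream$width_min_m, rv$width_min_m)
        len <- stats::rlnorm(ns, rv$length_meanlog, rv$length_sdlog)
        parts[[paste0("stream_", z)]] <- data.frame(
          body_class = "stream", zone = z,
          surface_area_km2 = w * len / .M2_PER_KM2,
          width_m = w, latitude = .zone_latitudes(ns, z, cfg$zones)
        )
      }
      np <- cfg$pond$count[[z]]
      if (np >= 1) {
        a <- rpareto(np, lk$shape, cfg$pond$area_min_km2, lk$area_min_km2)
        parts[[paste0("pond_", z)]] <- data.frame(
          body_class = "pond", zone = z,
          surface_area_km2 = a, width_m = NA_real_,
          latitude = .zone_latitudes(np, z, cfg$zones)
        )
      }
    }
    inv <- do.call(rbind, parts)
    rownames(inv) <- NULL
    inv$zone <- normalize_zone(inv$zone)
    data.frame(id = sprintf("wb%07d", seq_len(nrow(inv))), inv)
  })
}

#' Generate a synthetic main-channel gas transect
#'
#' Ordered pCO2/temperature/pH series along the main channel, south to
#' north. Summer pCO2 is log-normal with moments matched to the
#' configured mean and s.d.; pH is normal truncated below the configured
#' maximum (8); the continuous zone carries no samples, exercising the
#' fill-from-adjacent-zone rule downstream.
#'
#' @param cfg [landscape_config()] object.
#' @param seed Seed; defaults to `cfg$seed`.
#' @return `data.frame` with columns `sample_id`, `zone`, `pco2_uatm`,
#'   `temp_c`, `pressure_kpa`, `ph`, ordered along the route.
#' @export
#' @examples
#' tr <- generate_transect(landscape_config())
#' c(mean(tr$pco2_uatm), max(tr$ph))
generate_transect <- function(cfg, seed = cfg$seed) {
  validate_landscape_config(cfg)
  tc <- cfg$transect
  with_seed(seed, {
    out <- list()
    for (z in zone_levels()) {
      n <- tc$n_per_zone[[z]]
      if (n < 1) next
      if (tc$pco2_sd == 0) {
        pco2 <- rep(tc$pco2_mean, n)
      } else {
        sdlog2 <- log(1 + (tc$pco2_sd / tc$pco2_mean)^2)
        pco2 <- stats::rlnorm(n, log(tc$pco2_mean) - sdlog2 / 2,
                              sqrt(sdlog2))
      }
      # truncated-normal pH via rejection; observed river pH never
      # exceeds 8
      ph <- stats::rnorm(n, tc$ph_mean[[z]], tc$ph_sd)
      while (any(ph >= tc$ph_max)) {
        i <- ph >= tc$ph_max
        ph[i] <- stats::rnorm(sum(i), tc$ph_mean[[z]], tc$ph_sd)
      }
      out[[z]] <- data.frame(
        zone = z,
        pco2_uatm = pco2,
        temp_c = pmin(pmax(stats::rnorm(n, tc$temp_mean, tc$temp_sd),
                           0), 35),
        pressure_kpa = tc$pressure_kpa,
        ph = ph
      )
    }
    tr <- do.call(rbind, out)
    rownames(tr) <- NULL
    tr$zone <- normalize_zone(tr$zone)
    data.frame(sample_id = seq_len(nrow(tr)), tr)
  })
}

#' Generate per-zone emission-rate observations
#'
#' Normal samples for each system class and permafrost zone with the
#' configured mean and s.d., emulating the field campaigns that the
#' zone-specific rate distributions summarise.
#'
#' @param cfg [landscape_config()] object.
#' @param n_per_zone Observations per class-zone pair (default 50).
#' @param seed Seed; defaults to `cfg$seed`.
#' @return `data.frame` with columns `body_class`, `zone`,
#'   `rate_gC_m2_d`.
#' @export
#' @examples
#' head(generate_rate_observations(landscape_config(), n_per_zone = 5))
generate_rate_observations <- function(cfg, n_per_zone = 50L,
                                       seed = cfg$seed) {
  validate_landscape_config(cfg)
  check_number(n_per_zone, "n_per_zone", lower = 1)
  with_seed(seed, {
    out <- list()
    for (cl in c("river", "lake")) {
      pars <- cfg$rates[[cl]]
      for (z in zone_levels()) {
        if (is.na(pars$mean[[z]]) || is.na(pars$sd[[z]])) {
          stop(sprintf("missing rate parameters for %s / %s", cl, z),
               call. = FALSE)
        }
        out[[paste(cl, z)]] <- data.frame(
          body_class = cl, zone = z,
          rate_gC_m2_d = stats::rnorm(n_per_zone, pars$mean[[z]],
                                      pars$sd[[z]])
        )
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res$zone <- normalize_zone(res$zone)
    res
  })
}

#' Generate ice-free-season observations
#'
#' Latitude/season-length pairs around the configured linear models for
#' rivers and lakes, with small normal noise, for fitting season models
#' the way the real campaigns did.
#'
#' @param cfg [landscape_config()] object.
#' @param seed Seed; defaults to `cfg$seed`.
#' @return `data.frame` with columns `body_class`, `latitude`, `days`.
#' @export
generate_season_observations <- function(cfg, seed = cfg$seed) {
  validate_landscape_config(cfg)
  so <- cfg$season_obs
  with_seed(seed, {
    lat_r <- stats::runif(so$n_river, min(cfg$zones$lat_min),
                          max(cfg$zones$lat_max))
    lat_l <- stats::runif(so$n_lake, min(cfg$zones$lat_min),
                          max(cfg$zones$lat_max))
    rbind(
      data.frame(body_class = "river", latitude = lat_r,
                 days = cfg$season$river[["intercept"]] +
                   cfg$season$river[["slope"]] * lat_r +
                   stats::rnorm(so$n_river, 0, so$noise_sd_river)),
      data.frame(body_class = "lake", latitude = lat_l,
                 days = cfg$season$lake[["intercept"]] +
                   cfg$season$lake[["slope"]] * lat_l +
                   stats::rnorm(so$n_lake, 0, so$noise_sd_lake))
    )
  })
}

#' Generate a gridded daily NEE field
#'
#' Daily net-ecosystem-exchange rates (g C m-2 d-1, negative = uptake)
#' for `n_cells` grid cells over 365 days: per-cell baseline respiration
#' minus a Gaussian summer uptake pulse, plus daily noise. The calibrated
#' default yields a regional annual net sink.
#'
#' @param cfg [landscape_config()] object.
#' @param seed Seed; defaults to `cfg$seed`.
#' @return List of class `"nee_grid"` with elements `rates` (cells x 365
#'   matrix), `cell_area_km2` (per-cell resolution) and `days` (1-365).
#' @export
#' @examples
#' g <- generate_nee_grid(landscape_config(scale = 0.001))
#' dim(g$rates)
generate_nee_grid <- function(cfg, seed = cfg$seed) {
  validate_landscape_config(cfg)
  p <- cfg$nee
  with_seed(seed, {
    days <- seq_len(365L)
    pulse <- exp(-((days - p$peak_day)^2) / (2 * p$width_days^2))
    resp <- stats::rnorm(p$n_cells, p$resp_mean, p$resp_sd)
    uptake <- stats::rnorm(p$n_cells, p$uptake_mean, p$uptake_sd)
    rates <- outer(resp, rep(1, 365L)) - outer(uptake, pulse) +
      matrix(stats::rnorm(p$n_cells * 365L, 0, p$noise_sd),
             nrow = p$n_cells)
    structure(
      list(rates = rates,
           cell_area_km2 = rep(p$cell_area_km2, p$n_cells),
           days = days),
      class = "nee_grid"
    )
  })
}
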