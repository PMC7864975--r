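# Season models, Monte Carlo upscaling, fixed-rate upscaling, yields
# and the flood scenario.

test_that("season model fitting recovers a noiseless line exactly and
          reports high R2 on noisy data", {
  lat <- seq(56, 72, by = 2)
  m <- fit_season_model(lat, 600 - 7 * lat)
  expect_equal(m$intercept, 600)
  expect_equal(m$slope, -7)
  expect_equal(m$r_squared, 1)
  set.seed(6)
  m2 <- fit_season_model(lat, 600 - 7 * lat + rnorm(length(lat), 0, 4))
  expect_gt(m2$r_squared, 0.95)
  expect_error(fit_season_model(rep(60, 10), rnorm(10)), "distinct")
})

test_that("median predicted river season matches the regional median
          under calibrated defaults", {
  cfg <- small_config(scale = 0.05)
  inv <- generate_inventory(cfg, seed = 23)
  sm <- config_season_models(cfg)
  riv_lat <- inv$latitude[inv$body_class == "river"]
  expect_equal(median(season_length(sm$river, riv_lat)), 180.6,
               tolerance = 0.02)
})

test_that("inventory upscaling is linear in area, zero for zero rates,
          and conserves totals across partitions", {
  cfg <- small_config(scale = 0.005)
  inv <- generate_inventory(cfg, seed = 3)
  rl <- inv[inv$body_class %in% c("river", "lake"), ]
  sm <- config_season_models(cfg)
  pools <- rate_pools(cfg, seed = 5)
  res <- upscale_inventory(rl, pools, sm, seed = 7)
  # conservation: zone x class cells sum identically to any regrouping
  expect_equal(sum(res$emission_PgC_yr),
               sum(tapply(res$emission_PgC_yr, res$zone, sum)))
  expect_equal(sum(res$emission_PgC_yr),
               sum(tapply(res$emission_PgC_yr, res$body_class, sum)))
  # doubling every area with the same seed doubles every emission
  rl2 <- rl
  rl2$surface_area_km2 <- 2 * rl2$surface_area_km2
  res2 <- upscale_inventory(rl2, pools, sm, seed = 7)
  expect_equal(res2$emission_PgC_yr, 2 * res$emission_PgC_yr)
  # zero rates give zero emission
  cfg0 <- landscape_config()
  cfg0$rates$river$mean[] <- 0
  cfg0$rates$river$sd[] <- 0
  cfg0$rates$lake$mean[] <- 0
  cfg0$rates$lake$sd[] <- 0
  res0 <- upscale_inventory(rl, rate_pools(cfg0, seed = 1), sm, seed = 7)
  expect_true(all(res0$emission_PgC_yr == 0))
  # unknown class is reported by name
  bad <- rl
  bad$body_class[1] <- "pond"
  expect_error(upscale_inventory(bad, pools, sm, seed = 1), "pond")
})

test_that("Monte Carlo upscaling is unbiased against the closed-form
          pool mean", {
  cfg <- small_config(scale = 0.01)
  inv <- generate_inventory(cfg, seed = 13)
  rl <- inv[inv$body_class %in% c("river", "lake"), ]
  sm <- config_season_models(cfg)
  pools <- rate_pools(cfg, seed = 5)
  ch4 <- attr(pools, "ch4_fraction")
  # closed form: per-body pool mean x season x area
  expected <- 0
  for (cl in c("river", "lake")) {
    sel <- rl$body_class == cl
    pm <- vapply(pools[[cl]], mean, numeric(1))[as.character(rl$zone[sel])]
    expected <- expected + sum(
      add_ch4(pm, ch4[[cl]]) * season_length(sm[[cl]], rl$latitude[sel]) *
        rl$surface_area_km2[sel] * 1e6) / 1e15
  }
  totals <- vapply(1:12, function(s) {
    sum(upscale_inventory(rl, pools, sm, seed = s)$emission_PgC_yr)
  }, numeric(1))
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - expected), 3 * se)
})

test_that("transect upscaling: equilibrium water emits nothing, seeds
          agree within Monte Carlo error, continuous zone fills from
          the discontinuous zone", {
  cfg <- landscape_config()
  tr <- generate_transect(cfg, seed = 2)
  areas <- cfg$main_channel$area_km2
  # at atmospheric equilibrium (and no spring excess) flux is ~0; build
  # an equilibrium series whose spring-adjusted pCO2 equals 390
  tr0 <- tr
  tr0$pco2_uatm <- 390 / 1.5
  r0 <- upscale_transect(tr0, areas, n_draws = 2000L, seed = 1)
  expect_equal(sum(r0$emission_PgC_yr), 0, tolerance = 1e-12)
  r1 <- upscale_transect(tr, areas, n_draws = 20000L, seed = 1)
  # all five zones receive emission although 'continuous' is unsampled
  expect_setequal(as.character(r1$zone), zone_levels())
  # the filled zone reuses the discontinuous sample pool
  expect_equal(r1$rate_gC_m2_d[r1$zone == "continuous"],
               r1$rate_gC_m2_d[r1$zone == "discontinuous"],
               tolerance = 0.05)
  r2 <- upscale_transect(tr, areas, n_draws = 20000L, seed = 99)
  mc_se <- sqrt(sum((r1$rate_mc_se * r1$area_km2 * 1e6 *
                       r1$season_days / 1e15)^2))
  expect_lt(abs(sum(r1$emission_PgC_yr) - sum(r2$emission_PgC_yr)),
            3 * sqrt(2) * mc_se)
  # a zone with area but no fallback samples errors informatively
  tr_north_only <- tr[tr$zone == "discontinuous", ]
  only_south <- c(absent = 100, isolated = 0, sporadic = 0,
                  discontinuous = 0, continuous = 0)
  expect_error(upscale_transect(tr_north_only, only_south, seed = 1),
               "no transect samples")
})

test_that("fixed-rate upscaling arithmetic and the units audit", {
  # regional stream product: 13,639 km2 x 5.67 g C m-2 d-1 x 180.6 d
  expect_equal(upscale_fixed_rate(13639, 5.67, 180.6), 0.0140,
               tolerance = 0.005)
  # 1 g C m-2 d-1 over 1 km2 for 1 day is exactly 1e-9 Pg
  expect_identical(upscale_fixed_rate(1, 1, 1), 1e-9)
  expect_equal(upscale_fixed_rate(0, 5, 100), 0)
  expect_equal(upscale_fixed_rate(100, 2, 50),
               upscale_fixed_rate(100, 2, 100) / 2)
  expect_error(upscale_fixed_rate(-1, 5, 100), "outside")
})

test_that("C yield normalises emission to land area", {
  expect_equal(c_yield(0.001, 100000), 10)
  expect_equal(c_yield(0, 100000), 0)
  expect_error(c_yield(0.001, 0), "positive")
})

test_that("flood scenario: zero increase changes nothing; a uniform
          season gives the closed form; over-long floods error", {
  comp <- data.frame(emission_PgC_yr = c(0.02, 0.03),
                     season_days = c(180.6, 180.6))
  expect_equal(floodplain_scenario(comp, area_increase = 0)$percent_increase,
               0)
  fs <- floodplain_scenario(comp)
  expect_equal(fs$percent_increase, 100 * 0.85 * 30 / 180.6,
               tolerance = 1e-12)  # 14.12%
  expect_error(floodplain_scenario(
    data.frame(emission_PgC_yr = 0.1, season_days = 20)), "exceeds")
})
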