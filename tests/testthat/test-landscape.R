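# The synthetic landscape generator: determinism, class boundaries,
# tail recovery, and transect statistics.

test_that("generators are bit-identical under a fixed seed", {
  cfg <- small_config()
  expect_identical(generate_inventory(cfg, seed = 3),
                   generate_inventory(cfg, seed = 3))
  expect_identical(generate_transect(cfg, seed = 3),
                   generate_transect(cfg, seed = 3))
  expect_false(identical(generate_inventory(cfg, seed = 3),
                         generate_inventory(cfg, seed = 4)))
})

test_that("generated bodies never violate class size boundaries", {
  cfg <- small_config(scale = 0.02)
  # also request explicit streams and ponds to exercise their bounds
  cfg$stream$count[] <- 200L
  cfg$pond$count[] <- 200L
  inv <- generate_inventory(cfg, seed = 9)
  riv <- inv[inv$body_class == "river", ]
  expect_true(all(riv$width_m >= 90))
  stre <- inv[inv$body_class == "stream", ]
  expect_true(all(stre$width_m >= 0.32 & stre$width_m < 90))
  lk <- inv[inv$body_class == "lake", ]
  expect_true(all(lk$surface_area_km2 >= 0.01))
  pd <- inv[inv$body_class == "pond", ]
  expect_true(all(pd$surface_area_km2 >= 0.000115 &
                    pd$surface_area_km2 < 0.01))
  expect_true(all(inv$surface_area_km2 > 0))
  expect_true(all(inv$latitude >= 55 & inv$latitude <= 73))
})

test_that("zero stream/pond counts leave only bodies above the cutoffs", {
  inv <- generate_inventory(small_config(), seed = 2)
  expect_setequal(unique(inv$body_class),
                  c("main_channel", "river", "lake"))
})

test_that("lake areas carry the configured Pareto tail index", {
  cfg <- landscape_config()
  set.seed(21)
  a <- rpareto(10000, cfg$lake$shape, cfg$lake$area_min_km2,
               cfg$lake$area_max_km2)
  refit <- fit_pareto_tail(a, cfg$lake$area_min_km2,
                           upper = cfg$lake$area_max_km2)
  expect_equal(refit$shape, 1.19, tolerance = 0.05 / 1.19)
  # and the generated inventory itself passes the same recovery test
  inv <- generate_inventory(small_config(scale = 0.005), seed = 5)
  lk <- inv$surface_area_km2[inv$body_class == "lake"]
  fit <- fit_pareto_tail(lk, cfg$lake$area_min_km2,
                         upper = cfg$lake$area_max_km2)
  expect_lt(abs(fit$shape - 1.19), 0.08)
})

test_that("calibrated default reproduces the regional lake area", {
  cfg <- small_config(scale = 0.05)
  inv <- generate_inventory(cfg, seed = 31)
  lake_total <- sum(inv$surface_area_km2[inv$body_class == "lake"])
  expect_equal(lake_total, 171029 * 0.05, tolerance = 0.10)
  river_total <- sum(inv$surface_area_km2[inv$body_class == "river"])
  expect_equal(river_total, 12919 * 0.05, tolerance = 0.10)
  expect_equal(sum(inv$surface_area_km2[inv$body_class == "main_channel"]),
               6831 * 0.05, tolerance = 1e-6)
})

test_that("transect pCO2 matches the campaign moments, pH stays below 8,
          and the continuous zone is unsampled", {
  cfg <- landscape_config()
  tr <- generate_transect(cfg, seed = 12)
  expect_equal(nrow(tr), 4396)
  se <- 882 / sqrt(nrow(tr))
  expect_lt(abs(mean(tr$pco2_uatm) - 1546), 3 * se)
  expect_equal(sd(tr$pco2_uatm), 882, tolerance = 0.1)
  expect_true(all(tr$ph < 8))
  expect_true(all(tr$pco2_uatm > 0))
  expect_false("continuous" %in% as.character(tr$zone))
  expect_equal(as.integer(table(tr$zone)[c("absent", "isolated",
                                           "sporadic", "discontinuous")]),
               c(1516L, 1982L, 431L, 467L))
})

test_that("zero pCO2 spread produces a constant series", {
  cfg <- landscape_config()
  cfg$transect$pco2_sd <- 0
  tr <- generate_transect(cfg, seed = 4)
  expect_true(all(tr$pco2_uatm == 1546))
})

test_that("rate observations follow the configured zone parameters", {
  cfg <- landscape_config()
  obs <- generate_rate_observations(cfg, n_per_zone = 10000L, seed = 8)
  riv_abs <- obs$rate_gC_m2_d[obs$body_class == "river" &
                                obs$zone == "absent"]
  m <- cfg$rates$river$mean[["absent"]]
  s <- cfg$rates$river$sd[["absent"]]
  expect_lt(abs(mean(riv_abs) - m), 3 * s / sqrt(10000))
  # degenerate parameters give an all-zero sample
  cfg0 <- landscape_config()
  cfg0$rates$river$mean[] <- 0
  cfg0$rates$river$sd[] <- 0
  obs0 <- generate_rate_observations(cfg0, n_per_zone = 5L, seed = 1)
  expect_true(all(obs0$rate_gC_m2_d[obs0$body_class == "river"] == 0))
})

test_that("river rate calibration implies the regional area-weighted
          annual rate", {
  cfg <- landscape_config()
  sm <- config_season_models(cfg)
  mid <- (cfg$zones$lat_min + cfg$zones$lat_max) / 2
  season <- season_length(sm$river, mid)
  w <- cfg$river$area_km2 / sum(cfg$river$area_km2)
  annual_kg <- sum(w * cfg$rates$river$mean * season) / 1000
  expect_equal(annual_kg, 0.9, tolerance = 0.15)
})

test_that("NEE generator produces a seasonal net sink", {
  cfg <- small_config(scale = 0.01)
  g <- generate_nee_grid(cfg, seed = 14)
  expect_equal(dim(g$rates), c(cfg$nee$n_cells, 365L))
  ann <- aggregate_nee(g)
  expect_lt(ann$value, 0)
  # summer (day 196) is net uptake, mid-winter is net release
  expect_lt(mean(g$rates[, 196]), 0)
  expect_gt(mean(g$rates[, 15]), 0)
})

test_that("invalid configurations are rejected", {
  cfg <- landscape_config()
  cfg$lake$shape <- -1
  expect_error(validate_landscape_config(cfg), "shapes")
  cfg2 <- landscape_config()
  cfg2$stream$count[1] <- -5L
  expect_error(validate_landscape_config(cfg2), "counts")
  cfg3 <- landscape_config()
  cfg3$nee$n_cells <- 0L
  expect_error(validate_landscape_config(cfg3), "at least one cell")
  cfg4 <- landscape_config()
  cfg4$rates$river$mean <- cfg4$rates$river$mean[1:3]
  expect_error(validate_landscape_config(cfg4), "per zone")
})
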