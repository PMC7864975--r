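# Pareto tail fitting and below-cutoff extrapolation.

test_that("maximum-likelihood tail fit recovers a known shape", {
  set.seed(11)
  x <- rpareto(10000, 1.19, 0.01)
  fit <- fit_pareto_tail(x, 0.01)
  expect_lt(abs(fit$shape - 1.19), 0.05)
  expect_equal(fit$n_obs, 10000L)
  # truncated variant corrects the Hill bias of a bounded sample
  set.seed(12)
  w <- rpareto(10000, 0.93, 90, 4200)
  expect_lt(abs(fit_pareto_tail(w, 90, upper = 4200)$shape - 0.93), 0.05)
  expect_gt(fit_pareto_tail(w, 90)$shape, 0.98)  # untruncated is biased
})

test_that("tail fitting rejects degenerate or inadequate samples", {
  expect_error(fit_pareto_tail(rep(2, 100), 2), "degenerate")
  expect_error(fit_pareto_tail(rpareto(10, 1.2, 1), 1), ">= 30")
  expect_error(fit_pareto_tail(c(-1, rep(2, 50)), 1), "positive")
})

test_that("fitted shape is invariant under rescaling all sizes", {
  set.seed(3)
  x <- rpareto(5000, 1.19, 0.01)
  f1 <- fit_pareto_tail(x, 0.01)
  f2 <- fit_pareto_tail(x * 1000, 10)
  expect_equal(f1$shape, f2$shape, tolerance = 1e-12)
})

test_that("closed-form extrapolation equals numerical quadrature and
          vanishes on an empty interval", {
  for (shape in c(0.7, 1.19)) {  # both tail regimes
    fit <- pareto_tail(shape, 0.01, 500)
    spec <- extrapolation_spec(0.000115, 0.01)
    got <- extrapolate_below_cutoff(fit, spec)
    dens <- function(x) {
      fit$n_obs * shape * 0.01^shape * x^(-shape - 1)
    }
    num_area <- stats::integrate(function(x) x * dens(x), 0.000115, 0.01,
                                 rel.tol = 1e-10)$value
    num_count <- stats::integrate(dens, 0.000115, 0.01,
                                  rel.tol = 1e-10)$value
    expect_equal(got$total_size, num_area, tolerance = 1e-6)
    expect_equal(got$count, num_count, tolerance = 1e-6)
  }
  empty <- extrapolate_below_cutoff(pareto_tail(1.19, 0.01, 500),
                                    extrapolation_spec(0.01, 0.01))
  expect_equal(empty$count, 0)
  expect_equal(empty$total_size, 0)
})

test_that("extrapolated count and area are non-increasing in the
          physical minimum", {
  fit <- pareto_tail(1.19, 0.01, 1000)
  mins <- c(0.000115, 0.0005, 0.002, 0.008, 0.01)
  areas <- vapply(mins, function(a) {
    extrapolate_below_cutoff(fit, extrapolation_spec(a, 0.01))$total_size
  }, numeric(1))
  counts <- vapply(mins, function(a) {
    extrapolate_below_cutoff(fit, extrapolation_spec(a, 0.01))$count
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
  expect_true(all(diff(counts) <= 0))
})

test_that("simulate -> fit -> extrapolate recovers the true
          below-cutoff area of an uncensored population", {
  set.seed(42)
  pop <- rpareto(2.03e6, 1.19, 0.000115, 1000)
  obs <- pop[pop >= 0.01]
  expect_gt(length(obs), 9000)  # ~10,000 observed above the cutoff
  fit <- fit_pareto_tail(obs, 0.01)
  est <- extrapolate_below_cutoff(
    pareto_tail(fit$shape, 0.01, length(obs)),
    extrapolation_spec(0.000115, 0.01))$total_size
  true_area <- sum(pop[pop < 0.01])
  expect_lt(abs(est / true_area - 1), 0.10)
})

test_that("pond extrapolation reproduces the regional pond/lake area
          ratio under the calibrated defaults", {
  cfg <- small_config(scale = 0.05)
  inv <- generate_inventory(cfg, seed = 17)
  lk <- inv$surface_area_km2[inv$body_class == "lake"]
  fit <- fit_pareto_tail(lk, cfg$lake$area_min_km2,
                         upper = cfg$lake$area_max_km2)
  ponds <- extrapolate_below_cutoff(
    pareto_tail(fit$shape, cfg$lake$area_min_km2, length(lk)),
    extrapolation_spec(cfg$pond$area_min_km2, cfg$lake$area_min_km2))
  # extrapolated pond area ~1.49x the observed lake area
  expect_equal(ponds$total_size / sum(lk), 1.49, tolerance = 0.10)
})

test_that("stream area scales the width-density integral to the
          observed river tail", {
  fit <- pareto_tail(0.93, 90, 1000, upper = 4200)
  spec <- extrapolation_spec(0.32, 90, upper = 4200)
  # calibrated default reproduces the regional stream area
  expect_equal(stream_area_from_widths(fit, spec, 12919), 13639,
               tolerance = 0.10)
  # proportional in the observed tail area
  expect_equal(stream_area_from_widths(fit, spec, 2 * 12919),
               2 * stream_area_from_widths(fit, spec, 12919))
  # empty extrapolation interval -> zero
  spec0 <- extrapolation_spec(90, 90, upper = 4200)
  expect_equal(stream_area_from_widths(fit, spec0, 12919), 0)
  expect_error(stream_area_from_widths(fit, spec, 0), "zero")
})

test_that("land-fraction pond areas use 2.9%/0.62% by zone group", {
  z <- permafrost_zones(rep(100000, 5))
  pa <- pond_area_from_land_fraction(z)
  expect_equal(pa$pond_area_km2[pa$zone == "sporadic"], 2900)
  expect_equal(pa$pond_area_km2[pa$zone == "continuous"], 620)
  # zero land -> zero ponds (via near-zero land area)
  z2 <- permafrost_zones(c(1e-9, rep(100000, 4)))
  expect_equal(pond_area_from_land_fraction(z2)$pond_area_km2[1], 0,
               tolerance = 1e-9)
  # calibrated default: Pareto pond area ~3.4-fold the land-fraction area
  cfg <- landscape_config()
  alt <- sum(pond_area_from_land_fraction(cfg$zones)$pond_area_km2)
  expect_equal(254956 / alt, 3.4, tolerance = 0.10)
})
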