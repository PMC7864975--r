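# Pareto tail models for water-body size distributions and the
# extrapolation of counts and areas below observation cutoffs.

#' Random draws from a (truncated) Pareto distribution
#'
#' Inverse-CDF sampling from the power law with survival
#' `P(X > x) = (lower/x)^shape`, optionally truncated at `upper`.
#'
#' @param n Number of draws.
#' @param shape Tail exponent (> 0).
#' @param lower Lower bound (> 0); the scale of the power law.
#' @param upper Optional upper truncation (> lower); `Inf` for none.
#' @return Numeric vector of draws in `[lower, upper]`.
#' @export
#' @examples
#' summary(rpareto(1000, 1.19, 0.01, 1000))
rpareto <- function(n, shape, lower, upper = Inf) {
  check_number(shape, "shape", lower = 1e-12)
  check_number(lower, "lower", lower = 1e-300)
  if (upper <= lower) stop("'upper' must exceed 'lower'", call. = FALSE)
  u <- stats::runif(n)
  qtail <- if (is.finite(upper)) 1 - (lower / upper)^shape else 1
  lower * (1 - u * qtail)^(-1 / shape)
}

# mean of the truncated Pareto on [lower, upper]; used to convert target
# areas into body counts in the landscape generator
tpareto_mean <- function(shape, lower, upper) {
  frac <- 1 - (lower / upper)^shape
  if (abs(shape - 1) < 1e-12) {
    shape * lower^shape * log(upper / lower) / frac
  } else {
    shape * lower^shape * (upper^(1 - shape) - lower^(1 - shape)) /
      ((1 - shape) * frac)
  }
}

#' Extrapolation interval for unobserved small systems
#'
#' Pairs the smallest physically occurring system size with the
#' observation cutoff of the source inventory, plus an optional upper
#' bound of the observed size range (needed for width-based area
#' integrals whose tail integral diverges for shape < 1).
#'
#' @param physical_minimum Smallest real system size: 0.32 m width for
#'   streams, 0.000115 km2 area for ponds.
#' @param cutoff Observation limit of the inventory: 90 m width for
#'   rivers, 0.01 km2 for lakes.
#' @param upper Optional largest observed size, same units.
#' @return List of class `"extrapolation_spec"`.
#' @export
#' @examples
#' extrapolation_spec(0.000115, 0.01)
extrapolation_spec <- function(physical_minimum, cutoff, upper = Inf) {
  check_number(physical_minimum, "physical_minimum", lower = 1e-300)
  check_number(cutoff, "cutoff", lower = 1e-300)
  if (physical_minimum > cutoff) {
    stop("'physical_minimum' must not exceed 'cutoff'", call. = FALSE)
  }
  if (upper < cutoff) stop("'upper' must be >= 'cutoff'", call. = FALSE)
  structure(list(physical_minimum = physical_minimum, cutoff = cutoff,
                 upper = upper),
            class = "extrapolation_spec")
}

#' Fit a Pareto tail to observed sizes
#'
#' Maximum-likelihood tail-index estimate on observations at or above the
#' cutoff. Without an upper bound this is the Hill estimator
#' `shape = n / sum(log(x/cutoff))`; with a finite `upper` the estimate
#' solves the truncated-Pareto score equation. The fitted scale ties the
#' model exceedance count at the cutoff to the observed count.
#'
#' @param sizes Numeric vector of observed sizes (positive).
#' @param cutoff Observation cutoff; only `sizes >= cutoff` enter the fit
#'   (at least 30 required).
#' @param upper Optional upper truncation of the observed range.
#' @return List of class `"pareto_fit"` with elements `shape`,
#'   `xmin_observed`, `upper`, `n_obs` (observed exceedance count) and
#'   `scale` (the exceedance normalisation `n_obs * cutoff^shape`).
#' @export
#' @examples
#' x <- rpareto(5000, 1.19, 0.01)
#' fit_pareto_tail(x, 0.01)$shape
fit_pareto_tail <- function(sizes, cutoff, upper = Inf) {
  if (any(!is.finite(sizes)) || any(sizes <= 0)) {
    stop("sizes must be positive and finite", call. = FALSE)
  }
  check_number(cutoff, "cutoff", lower = 1e-300)
  x <- sizes[sizes >= cutoff]
  n <- length(x)
  if (n < 30L) {
    stop(sprintf("only %d observations at or above the cutoff; >= 30 required",
                 n), call. = FALSE)
  }
  s <- mean(log(x / cutoff))
  if (s < 1e-12) {
    stop("degenerate sample: all sizes equal to the cutoff", call. = FALSE)
  }
  shape <- if (is.finite(upper)) {
    lr <- log(upper / cutoff)
    score <- function(b) {
      q <- (cutoff / upper)^b
      1 / b - s - lr * q / (1 - q)
    }
    stats::uniroot(score, interval = c(1e-6, 1e3), tol = 1e-12)$root
  } else {
    1 / s
  }
  structure(
    list(shape = shape, xmin_observed = cutoff, upper = upper,
         n_obs = n, scale = n * cutoff^shape),
    class = "pareto_fit"
  )
}

#' Manually specified Pareto tail
#'
#' Builds a `"pareto_fit"` from a published shape parameter and an
#' observed exceedance count, for use where the tail index is taken from
#' prior inventories rather than refitted.
#'
#' @param shape Tail exponent (> 0).
#' @param cutoff Size at which `n_obs` systems are observed.
#' @param n_obs Observed count of systems `>= cutoff`.
#' @param upper Optional upper truncation of the observed range.
#' @return List of class `"pareto_fit"`.
#' @export
#' @examples
#' pareto_tail(1.19, 0.01, 973780)
pareto_tail <- function(shape, cutoff, n_obs, upper = Inf) {
  check_number(shape, "shape", lower = 1e-12)
  check_number(cutoff, "cutoff", lower = 1e-300)
  check_number(n_obs, "n_obs", lower = 1)
  structure(
    list(shape = shape, xmin_observed = cutoff, upper = upper,
         n_obs = n_obs, scale = n_obs * cutoff^shape),
    class = "pareto_fit"
  )
}

#' Extrapolate counts and total size below the observation cutoff
#'
#' Extends the fitted power law below the cutoff down to the physical
#' minimum and integrates the number density in closed form:
#' count `= n_obs * ((cutoff/a)^shape - 1)` and total size
#' `= n_obs * shape * cutoff^shape * (a^(1-shape) - cutoff^(1-shape)) / (shape-1)`
#' on `[a, cutoff)` (log form at shape = 1). Both vanish as the physical
#' minimum approaches the cutoff.
#'
#' @param fit `"pareto_fit"` object.
#' @param spec [extrapolation_spec()] in the same units.
#' @return List with `count` and `total_size` (same units as the sizes;
#'   km2 of surface area when sizes are areas).
#' @export
#' @examples
#' extrapolate_below_cutoff(pareto_tail(1.19, 0.01, 1000),
#'                          extrapolation_spec(0.000115, 0.01))
extrapolate_below_cutoff <- function(fit, spec) {
  stopifnot(inherits(fit, "pareto_fit"), inherits(spec, "extrapolation_spec"))
  a <- spec$physical_minimum
  cf <- spec$cutoff
  if (a > cf) stop("physical minimum exceeds the cutoff", call. = FALSE)
  b <- fit$shape
  count <- fit$n_obs * ((cf / a)^b - 1)
  total <- if (abs(b - 1) < 1e-12) {
    fit$n_obs * b * cf^b * log(cf / a)
  } else {
    fit$n_obs * b * cf^b * (a^(1 - b) - cf^(1 - b)) / (b - 1)
  }
  list(count = count, total_size = total)
}

#' Stream surface area from the river width distribution
#'
#' Surface area of streams narrower than the observation cutoff, obtained
#' by scaling the width-density area integral to the observed river area:
#' with number density `f(w) ~ w^-(shape+1)`, area per width class is
#' proportional to `w * f(w) ~ w^-shape`, so
#' `stream_area = observed_area * I(a, cutoff) / I(cutoff, upper)` with
#' `I(p, q) = integral of w^-shape`. For shape < 1 the tail integral
#' diverges, hence the finite `upper` bound of the observed widths in the
#' spec.
#'
#' @param fit `"pareto_fit"` of the width distribution.
#' @param spec [extrapolation_spec()] in metres; `spec$upper` (or
#'   `fit$upper`) bounds the observed width range.
#' @param observed_river_area_km2 Total surface area (km2) of the
#'   observed river tail (widths >= cutoff).
#' @return Extrapolated stream surface area in km2.
#' @export
#' @examples
#' stream_area_from_widths(pareto_tail(0.93, 90, 1000, upper = 4200),
#'                         extrapolation_spec(0.32, 90, upper = 4200),
#'                         12919)
stream_area_from_widths <- function(fit, spec, observed_river_area_km2) {
  stopifnot(inherits(fit, "pareto_fit"), inherits(spec, "extrapolation_spec"))
  check_number(observed_river_area_km2, "observed_river_area_km2",
               lower = 0)
  if (observed_river_area_km2 == 0) {
    stop("observed river tail area is zero; nothing to scale against",
         call. = FALSE)
  }
  upper <- if (is.finite(spec$upper)) spec$upper else fit$upper
  if (!is.finite(upper)) {
    stop("a finite upper width bound is required (tail area integral ",
         "diverges for shape < 1)", call. = FALSE)
  }
  b <- fit$shape
  wint <- function(p, q) {
    if (abs(b - 1) < 1e-12) log(q / p) else (q^(1 - b) - p^(1 - b)) / (1 - b)
  }
  below <- wint(spec$physical_minimum, spec$cutoff)
  above <- wint(spec$cutoff, upper)
  observed_river_area_km2 * below / above
}

#' Pond area from per-zone land-cover fractions
#'
#' Alternative to the Pareto extrapolation: ponds as a fixed fraction of
#' zone land area, from satellite inventories of representative sites.
#' The southern zones (absent, isolated, sporadic) use 2.9% of land, the
#' northern zones (discontinuous, continuous) 0.62%.
#'
#' @param zones Zone table as from [permafrost_zones()].
#' @return `data.frame` with columns `zone` and `pond_area_km2`.
#' @export
#' @examples
#' pond_area_from_land_fraction(permafrost_zones())
pond_area_from_land_fraction <- function(zones = permafrost_zones()) {
  z <- normalize_zone(zones$zone)
  if (any(is.na(z))) stop("zone codes must not be NA", call. = FALSE)
  if (any(!is.finite(zones$land_area_km2)) || any(zones$land_area_km2 < 0)) {
    stop("land areas must be non-negative", call. = FALSE)
  }
  frac <- ifelse(z %in% c("absent", "isolated", "sporadic"), 0.029, 0.0062)
  data.frame(zone = z, pond_area_km2 = zones$land_area_km2 * frac)
}
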